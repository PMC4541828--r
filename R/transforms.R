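#' Rigid transform in 3D
#'
#' A proper rigid motion `x -> R x + t` with `R` a rotation matrix
#' (orthonormal, determinant +1) and `t` a translation vector.
#'
#' @param rotation 3x3 rotation matrix.
#' @param translation numeric length-3 translation.
#' @return An object of class `rigid_transform` with elements `R` and `t`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  R <- as.matrix(rotation)
  t <- as.numeric(translation)
  stopifnot(all(dim(R) == c(3L, 3L)), length(t) == 3L)
  if (max(abs(R %*% t(R) - diag(3))) > 1e-9)
    stop("rotation is not orthonormal within 1e-9")
  if (abs(det(R) - 1) > 1e-9)
    stop("rotation must be proper (det = +1)")
  structure(list(R = R, t = t), class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("Rigid transform: rotation angle",
      sprintf("%.3f rad,", rotation_angle(x$R)),
      "translation", sprintf("(%.4g, %.4g, %.4g)\n", x$t[1], x$t[2], x$t[3]))
  invisible(x)
}

identity_transform <- function() rigid_transform()

#' Compose two rigid transforms
#'
#' Returns the transform equivalent to applying `b` first, then `a`.
#'
#' @param a,b `rigid_transform` objects.
#' @return A `rigid_transform`.
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(a$R %*% b$R, as.numeric(a$R %*% b$t) + a$t)
}

#' Invert a rigid transform
#' @param tf A `rigid_transform`.
#' @return The inverse `rigid_transform`.
#' @export
invert_transform <- function(tf) {
  rigid_transform(t(tf$R), as.numeric(-t(tf$R) %*% tf$t))
}

transform_points <- function(pts, tf) {
  sweep(pts %*% t(tf$R), 2L, tf$t, "+")
}

#' Apply a rigid transform to a labeled point set
#'
#' Transforms every coordinate; labels and visibility flags are untouched.
#'
#' @param points A `labeled_point_set` (or bare n x 3 matrix).
#' @param tf A `rigid_transform`.
#' @return Same type as `points`.
#' @export
apply_rigid <- function(points, tf) {
  if (is.matrix(points)) return(transform_points(points, tf))
  ps <- as_labeled_point_set(points)
  ps$points <- transform_points(ps$points, tf)
  ps
}

#' Rotation matrix from axis and angle
#'
#' Rodrigues' formula. The axis is normalised internally.
#'
#' @param axis numeric length-3, not all zero.
#' @param angle rotation angle in radians.
#' @return 3x3 rotation matrix.
#' @export
rot_axis_angle <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Rotation angle of a rotation matrix
#' @param R 3x3 rotation matrix.
#' @return Angle in radians, in \[0, pi\].
#' @export
rotation_angle <- function(R) {
  acos(max(-1, min(1, (sum(diag(R)) - 1) / 2)))
}

# Fractional power of a rotation: scale its axis-angle representation by s.
rotation_fraction <- function(R, s) {
  ang <- rotation_angle(R)
  if (ang < 1e-12) return(diag(3))
  # axis from the skew-symmetric part; near pi fall back to eigenvector
  if (ang < pi - 1e-6) {
    ax <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) / (2 * sin(ang))
  } else {
    ev <- eigen(R)
    k <- which.min(abs(Re(ev$values) - 1))
    ax <- Re(ev$vectors[, k])
    ax <- ax / sqrt(sum(ax^2))
  }
  rot_axis_angle(ax, s * ang)
}

#' Least-squares rigid (or similarity) alignment
#'
#' Closed-form Procrustes fit of `R s_i + t` to paired targets via SVD,
#' constrained to a proper rotation. With `allow_scale = TRUE` an isotropic
#' scale factor is estimated as well (used once, during shape
#' initialization); pose estimation always uses the pure rigid form.
#' With fewer than 3 points the fit degrades to a translation of centroids
#' and a warning is recorded on the result (`attr(, "warning")`).
#'
#' @param source n x 3 matrix of source points.
#' @param target n x 3 matrix of paired target points.
#' @param weights optional nonnegative per-pair weights.
#' @param allow_scale estimate an isotropic scale? Default `FALSE`.
#' @return A `rigid_transform`; if `allow_scale`, the scale is folded into the
#'   rotation block's magnitude and also stored as `attr(, "scale")`.
#' @export
rigid_fit <- function(source, target, weights = NULL, allow_scale = FALSE) {
  source <- as.matrix(source); target <- as.matrix(target)
  n <- nrow(source)
  stopifnot(nrow(target) == n)
  if (is.null(weights)) weights <- rep(1, n)
  w <- weights / sum(weights)
  warn <- NULL
  mu_s <- colSums(source * w)
  mu_t <- colSums(target * w)
  if (n < 3L) {
    warn <- "fewer than 3 correspondences: translation-only fit"
    out <- rigid_transform(diag(3), mu_t - mu_s)
    attr(out, "warning") <- warn
    return(out)
  }
  S <- sweep(source, 2L, mu_s)
  T_ <- sweep(target, 2L, mu_t)
  H <- t(S * w) %*% T_
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  s <- 1
  if (allow_scale) {
    denom <- sum(w * rowSums(S^2))
    if (denom > 0) s <- sum(diag(D) * sv$d) / denom
  }
  if (allow_scale) {
    # scale folded into the linear block; bypasses the det=+1 validator
    out <- structure(list(R = s * R, t = as.numeric(mu_t - s * R %*% mu_s)),
                     class = "rigid_transform")
    attr(out, "scale") <- s
  } else {
    out <- rigid_transform(R, as.numeric(mu_t - R %*% mu_s))
  }
  if (!is.null(warn)) attr(out, "warning") <- warn
  out
}
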