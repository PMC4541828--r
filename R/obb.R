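#' Fit an oriented bounding box to a point set
#'
#' Approximate minimum-volume OBB: the box is initialised on the principal
#' axes, then refined by an exhaustive search over rotations about each
#' current axis on a 10-degree grid, swept repeatedly until the volume
#' stops improving. Degenerate directions get a floor half-extent of `1e-6` so the
#' volume stays well-defined. The box always contains every input point.
#'
#' @param points n x 3 matrix or `labeled_point_set` (n >= 1).
#' @param grid_deg grid step of the rotation search, degrees.
#' @return Object of class `oriented_box`: `center`, orthonormal `axes`
#'   (columns), `half_extents`, `volume` (product of full extents) and
#'   `height` (largest full extent).
#' @export
fit_obb <- function(points, grid_deg = 10) {
  X <- pts_of(points)
  n <- nrow(X)
  if (n < 1L) stop("need at least one point")
  ctr0 <- colMeans(X)
  Xc <- sweep(X, 2L, ctr0)
  axes <- if (n >= 3L) svd(Xc, nu = 0)$v else diag(3)
  if (ncol(axes) < 3L) axes <- cbind(axes, diag(3)[, seq_len(3 - ncol(axes))])
  if (det(axes) < 0) axes[, 3] <- -axes[, 3]

  box_volume <- function(A) {
    prj <- Xc %*% A
    ext <- apply(prj, 2L, range)
    prod(pmax(ext[2, ] - ext[1, ], 2e-6))
  }
  best <- axes
  best_v <- box_volume(axes)
  angles <- seq(grid_deg, 90 - grid_deg, by = grid_deg) * pi / 180
  # sweep the per-axis rotation grid until no sweep improves the volume
  for (sweep_i in 1:5) {
    improved <- FALSE
    for (k in 1:3) {
      for (ang in angles) {
        A <- best %*% rot_axis_angle(diag(3)[, k], ang)
        v <- box_volume(A)
        if (v < best_v * (1 - 1e-9)) { best_v <- v; best <- A; improved <- TRUE }
      }
    }
    if (!improved) break
  }
  prj <- Xc %*% best
  ext <- apply(prj, 2L, range)
  half <- pmax((ext[2, ] - ext[1, ]) / 2, 1e-6)
  mid <- (ext[2, ] + ext[1, ]) / 2
  center <- ctr0 + as.numeric(best %*% mid)
  structure(list(center = center, axes = best, half_extents = half,
                 volume = prod(2 * half), height = max(2 * half)),
            class = "oriented_box")
}

#' @export
print.oriented_box <- function(x, ...) {
  cat(sprintf("OBB: extents %.4g x %.4g x %.4g, volume %.4g\n",
              2 * x$half_extents[1], 2 * x$half_extents[2],
              2 * x$half_extents[3], x$volume))
  invisible(x)
}

#' Test points for membership in an oriented box
#'
#' @param points n x 3 matrix or `labeled_point_set`.
#' @param box an `oriented_box`.
#' @param tol boundary tolerance (default 1e-9).
#' @return Logical vector.
#' @export
points_in_obb <- function(points, box, tol = 1e-9) {
  X <- pts_of(points)
  prj <- sweep(X, 2L, box$center) %*% box$axes
  rowSums(sweep(abs(prj), 2L, box$half_extents + tol, "<=")) == 3L
}
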