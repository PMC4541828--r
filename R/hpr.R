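#' Camera model
#'
#' Pinhole camera: world position, focal lengths and principal point in
#' pixels, image size. Looks down -z in its own frame by default (points in
#' front of the camera have smaller z than the camera in world coordinates
#' when `look` is the default).
#'
#' @param position world camera centre (length 3).
#' @param fx,fy focal lengths in pixels (> 0).
#' @param cx,cy principal point in pixels.
#' @param width,height image size in pixels.
#' @return Object of class `camera_model`.
#' @export
camera_model <- function(position = c(0, 0, 0), fx = 200, fy = 200,
                         cx = 88, cy = 72, width = 176, height = 144) {
  if (fx <= 0 || fy <= 0) stop("focal lengths must be > 0")
  structure(list(position = as.numeric(position), fx = fx, fy = fy,
                 cx = cx, cy = cy, width = as.integer(width),
                 height = as.integer(height)),
            class = "camera_model")
}

#' @export
print.camera_model <- function(x, ...) {
  cat(sprintf("Camera at (%.3g, %.3g, %.3g), f = (%g, %g), %d x %d px\n",
              x$position[1], x$position[2], x$position[3],
              x$fx, x$fy, x$width, x$height))
  invisible(x)
}

#' Spherical flipping of a point set about the viewpoint origin
#'
#' Inverts each point radially with respect to a sphere of radius `R`
#' centred at the origin: `a_hat = a + 2 (R - ||a||) a / ||a||`. Points on
#' the sphere are fixed; nearer points map farther out.
#'
#' @param points n x 3 matrix in the camera frame (origin = viewpoint).
#' @param R sphere radius; must be at least the largest point norm.
#' @return n x 3 matrix of flipped points.
#' @export
spherical_flip <- function(points, R) {
  A <- pts_of(points)
  nrm <- sqrt(rowSums(A^2))
  if (any(nrm == 0)) stop("a point coincides with the viewpoint")
  if (R < max(nrm)) stop("R must include all points (R >= max norm)")
  A + A * (2 * (R - nrm) / nrm)
}

#' Hidden point removal: extract camera-visible points
#'
#' Translates the cloud into the camera frame, spherically flips it with
#' `R = 10^r_exp * max||a_i||`, builds the convex hull of the flipped set
#' plus the origin, and marks a point visible iff its flipped image is a
#' vertex of that hull. Degenerate (coplanar) clouds fall back to a 2D hull
#' in the best-fitting plane.
#'
#' @param points `labeled_point_set` or n x 3 matrix (world frame).
#' @param camera a [camera_model()] (only the position is used).
#' @param r_exp exponent of the flip-radius factor: `R = 10^r_exp * max norm`
#'   (default 2; visibility is sensitive to this radius: small exponents resolve fine structure, very large ones mark concavities visible).
#' @return Object of class `hpr_result`: logical `visible_mask`, radius `R`,
#'   flipped points `flipped`, and the input as `points`.
#' @export
extract_visible <- function(points, camera, r_exp = 2) {
  ps <- as_labeled_point_set(points)
  A <- sweep(ps$points, 2L, camera$position)
  nrm <- sqrt(rowSums(A^2))
  if (any(nrm == 0)) stop("a point coincides with the camera position")
  n <- nrow(A)
  R <- 10^r_exp * max(nrm)
  flipped <- spherical_flip(A, R)
  S <- rbind(flipped, c(0, 0, 0))  # origin = viewpoint
  vid <- hull3d_vertices(S)
  if (length(vid) == 0L) {
    # coplanar scene: 2D hull in the plane spanned by the top PCs
    ctr <- colMeans(S)
    pc <- svd(sweep(S, 2L, ctr), nu = 0)$v[, 1:2, drop = FALSE]
    proj <- sweep(S, 2L, ctr) %*% pc
    vid <- chull(proj[, 1], proj[, 2])
  }
  mask <- logical(n)
  mask[vid[vid <= n]] <- TRUE
  structure(list(visible_mask = mask, R = R, flipped = flipped, points = ps),
            class = "hpr_result")
}

#' @export
print.hpr_result <- function(x, ...) {
  cat(sprintf("HPR visibility: %d of %d points visible (R = %.4g)\n",
              sum(x$visible_mask), length(x$visible_mask), x$R))
  invisible(x)
}

# Visible subset of a labeled point set, with the visible flag filled in.
visible_subset <- function(ps, camera, r_exp = 2) {
  hp <- extract_visible(ps, camera, r_exp)
  out <- subset_points(ps, which(hp$visible_mask))
  out$visible <- rep(TRUE, nrow(out$points))
  attr(out, "visible_mask") <- hp$visible_mask
  out
}
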