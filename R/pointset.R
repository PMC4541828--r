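#' Labeled 3D point set
#'
#' The shared container for templates, targets and rendered frames: an n x 3
#' coordinate matrix (meters by convention) with optional per-point segment
#' labels (integers in `0..P-1`) and visibility flags. An all-zero posterior
#' column in label propagation yields the sentinel label `NA_integer_`
#' ("unassigned").
#'
#' @param points n x 3 numeric matrix (or coercible).
#' @param labels optional integer vector of per-point segment ids, length n.
#' @param visible optional logical vector, length n.
#' @param n_segments optional segment count `P`; when given, labels are
#'   checked against it.
#' @return An object of class `labeled_point_set`.
#' @export
labeled_point_set <- function(points, labels = NULL, visible = NULL,
                              n_segments = NULL) {
  pts <- as.matrix(points)
  if (ncol(pts) != 3L) stop("points must be n x 3")
  storage.mode(pts) <- "double"
  dimnames(pts) <- NULL
  if (!all(is.finite(pts))) stop("all coordinates must be finite")
  n <- nrow(pts)
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != n) stop("labels length must match point count")
    if (!is.null(n_segments) && any(labels >= n_segments, na.rm = TRUE))
      stop("every label must be < n_segments")
  }
  if (!is.null(visible)) {
    visible <- as.logical(visible)
    if (length(visible) != n) stop("visible length must match point count")
  }
  structure(list(points = pts, labels = labels, visible = visible,
                 n_segments = n_segments),
            class = "labeled_point_set")
}

#' @export
print.labeled_point_set <- function(x, ...) {
  cat("Labeled point set:", nrow(x$points), "points")
  if (!is.null(x$labels))
    cat(",", length(unique(x$labels[!is.na(x$labels)])), "segments labeled")
  if (!is.null(x$visible))
    cat(",", sum(x$visible), "visible")
  cat("\n")
  invisible(x)
}

#' Coerce to a labeled point set
#' @param x matrix, data frame or `labeled_point_set`.
#' @param ... passed to [labeled_point_set()].
#' @return A `labeled_point_set`.
#' @export
as_labeled_point_set <- function(x, ...) {
  if (inherits(x, "labeled_point_set")) return(x)
  labeled_point_set(as.matrix(x), ...)
}

# Convenience: coordinates of a point-set-like object as a matrix.
pts_of <- function(x) {
  if (inherits(x, "labeled_point_set")) x$points else as.matrix(x)
}

#' Subset a labeled point set
#'
#' Keeps labels and visibility flags aligned with the retained rows.
#' @param ps a `labeled_point_set`.
#' @param idx integer row indices to keep.
#' @return A `labeled_point_set`.
#' @export
subset_points <- function(ps, idx) {
  labeled_point_set(ps$points[idx, , drop = FALSE],
                    labels = if (!is.null(ps$labels)) ps$labels[idx],
                    visible = if (!is.null(ps$visible)) ps$visible[idx],
                    n_segments = ps$n_segments)
}

# Squared Euclidean cross-distance matrix (m x n) between row sets.
cross_dist2 <- function(A, B) {
  a2 <- rowSums(A^2)
  b2 <- rowSums(B^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  d2
}

# Index of nearest row of B for each row of A.
nearest_index <- function(A, B) {
  max.col(-cross_dist2(A, B), ties.method = "first")
}
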