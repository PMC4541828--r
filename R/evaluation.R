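#' Mean joint position error against markers
#'
#' `e = 1/(Nf Nj) * sum_k sum_i ||J_i^k - M_i^k - O_i||`: the average over
#' frames and joints of the Euclidean distance between estimated joint and
#' marker after removing the constant per-joint offset `O_i` (template
#' joints and marker placements differ by a fixed amount along the bone).
#'
#' @param J estimated joints: Nf x Nj x 3 array, or list of Nj x 3 matrices.
#' @param M marker positions, same shape as `J`.
#' @param O per-joint offsets (Nj x 3 matrix), default zero.
#' @return Mean error (same length units as the input).
#' @export
joint_error <- function(J, M, O = NULL) {
  J <- as_joint_array(J); M <- as_joint_array(M)
  if (!all(dim(J) == dim(M))) stop("J and M must have the same shape")
  Nj <- dim(J)[2]
  if (is.null(O)) O <- matrix(0, Nj, 3)
  O <- as.matrix(O)
  if (nrow(O) != Nj) stop("one offset per joint required")
  d <- J - M - aperm(array(O, c(Nj, 3, dim(J)[1])), c(3, 1, 2))
  mean(sqrt(apply(d^2, c(1, 2), sum)))
}

as_joint_array <- function(x) {
  if (is.array(x) && length(dim(x)) == 3L) return(x)
  if (is.list(x)) {
    arr <- array(0, c(length(x), nrow(x[[1]]), 3))
    for (k in seq_along(x)) arr[k, , ] <- as.matrix(x[[k]])
    return(arr)
  }
  if (is.matrix(x)) return(array(x, c(1, nrow(x), ncol(x))))
  stop("cannot interpret joint positions")
}

#' Calibrate per-joint marker offsets
#'
#' Averages `J - M` over the calibration frames and projects each joint's
#' offset onto its local bone axis (offsets are defined along the segment).
#' The bone axis of joint i comes from the skeleton when given (proximal ->
#' distal of the segment the joint terminates), otherwise from the mean
#' joint estimates of the calibration frames.
#'
#' @param J,M estimated joints and markers (Nf x Nj x 3 arrays or lists of
#'   matrices).
#' @param calib_frames indices of calibration frames (default the first 20,
#'   or all frames if fewer).
#' @param skeleton optional `skeleton_model` supplying bone directions.
#' @return Nj x 3 matrix of offsets, with `attr(, "calib_frames")`.
#' @export
calibrate_offsets <- function(J, M, calib_frames = NULL, skeleton = NULL) {
  J <- as_joint_array(J); M <- as_joint_array(M)
  Nf <- dim(J)[1]; Nj <- dim(J)[2]
  if (is.null(calib_frames)) calib_frames <- seq_len(min(20L, Nf))
  if (length(calib_frames) < 1L) stop("need at least one calibration frame")
  D <- apply(J[calib_frames, , , drop = FALSE] -
             M[calib_frames, , , drop = FALSE], c(2, 3), mean)
  axes <- joint_bone_axes(J, calib_frames, skeleton)
  O <- matrix(0, Nj, 3)
  for (i in seq_len(Nj)) {
    a <- axes[i, ]
    if (sum(a^2) == 0) { O[i, ] <- D[i, ]; next }
    a <- a / sqrt(sum(a^2))
    O[i, ] <- sum(D[i, ] * a) * a  # axial component only
  }
  attr(O, "calib_frames") <- calib_frames
  O
}

# Per-joint bone direction: from the skeleton's segment table when
# available, else from mean calibration-frame joints along the parent edge.
joint_bone_axes <- function(J, calib_frames, skeleton = NULL) {
  Nj <- dim(J)[2]
  axes <- matrix(0, Nj, 3)
  if (!is.null(skeleton)) {
    mj <- apply(J[calib_frames, , , drop = FALSE], c(2, 3), mean)
    for (p in seq_len(skeleton$P)) {
      a <- skeleton$segment_joint[p, 1] + 1L
      b <- skeleton$segment_joint[p, 2] + 1L
      v <- mj[b, ] - mj[a, ]
      axes[b, ] <- v
      if (all(axes[a, ] == 0)) axes[a, ] <- v
    }
  } else {
    mj <- apply(J[calib_frames, , , drop = FALSE], c(2, 3), mean)
    for (i in seq_len(Nj)) {
      d2 <- rowSums(sweep(mj, 2L, mj[i, ])^2)
      d2[i] <- Inf
      axes[i, ] <- mj[which.min(d2), ] - mj[i, ]
    }
  }
  axes
}

#' Segment labeling accuracy
#'
#' Fraction of points whose predicted segment label equals the ground
#' truth, over all points with both labels defined (unassigned sentinels
#' are excluded from the denominator).
#'
#' @param predicted,truth integer label vectors of equal length (`NA` =
#'   unassigned).
#' @return Scalar in `[0, 1]`.
#' @export
labeling_accuracy <- function(predicted, truth) {
  if (length(predicted) != length(truth)) stop("label vectors must match")
  ok <- !is.na(predicted) & !is.na(truth)
  if (!any(ok)) return(NA_real_)
  mean(predicted[ok] == truth[ok])
}

#' Reconstruct ground-truth joints in a new pose by LLE weights
#'
#' For index-registered point sets (the same point identities across
#' poses): each joint is expressed in the reference pose as a sum-to-one
#' weighted combination of nearby surface points balanced between its two
#' adjacent segments; applying the same weights to the same-index points of
#' the target pose reconstructs the joint there. Sum-to-one weights are
#' equivariant under rigid and affine maps, so rigidly moved poses
#' reproduce rigidly moved joints.
#'
#' @param ref_points reference-pose points (matrix or `labeled_point_set`
#'   with labels).
#' @param ref_joints J x 3 reference joint positions.
#' @param target_points target-pose points, same indexing as `ref_points`.
#' @param skeleton a `skeleton_model` (adjacent segments per joint);
#'   `ref_points` labels are used when the point set carries none.
#' @param n_neighbors points used per joint (split evenly between the two
#'   adjacent segments when labels allow). Default 16.
#' @return J x 3 matrix of reconstructed target joints.
#' @export
lle_ground_truth_joints <- function(ref_points, ref_joints, target_points,
                                    skeleton, n_neighbors = 16) {
  ref <- as_labeled_point_set(ref_points)
  tgt <- pts_of(target_points)
  if (nrow(tgt) != nrow(ref$points))
    stop("reference and target must be index-registered")
  labels <- ref$labels
  J <- nrow(ref_joints)
  out <- matrix(0, J, 3)
  for (j in seq_len(J)) {
    segs <- joint_adjacent_segments(skeleton, j - 1L)
    idx <- select_joint_neighbors(ref$points, labels, ref_joints[j, ],
                                  segs - 1L, n_neighbors)
    if (length(idx) < 4L)
      stop("fewer than 4 neighbour points for joint ", j - 1L)
    w <- sum_to_one_weights(ref$points[idx, , drop = FALSE], ref_joints[j, ])
    out[j, ] <- as.numeric(t(w) %*% tgt[idx, , drop = FALSE])
  }
  out
}

# Nearest points around a joint, balanced between its adjacent segments
# when labels are available.
select_joint_neighbors <- function(points, labels, joint, segs, n_neighbors) {
  d2 <- rowSums(sweep(points, 2L, joint)^2)
  if (is.null(labels) || length(segs) < 2L) {
    return(order(d2)[seq_len(min(n_neighbors, length(d2)))])
  }
  per <- max(1L, n_neighbors %/% length(segs))
  idx <- integer()
  for (s in segs) {
    cand <- which(labels == s)
    if (length(cand))
      idx <- c(idx, cand[order(d2[cand])][seq_len(min(per, length(cand)))])
  }
  unique(idx)
}

# Sum-to-one reconstruction weights of a point from a neighbour set: the
# minimum-norm exact minimiser of ||sum_i w_i n_i - x|| subject to
# sum w = 1 (solved in the constraint's null space via the pseudo-inverse,
# so a joint inside the neighbours' affine span is reproduced exactly).
sum_to_one_weights <- function(nbrs, x) {
  K <- nrow(nbrs)
  A <- t(sweep(nbrs, 2L, x))          # 3 x K; rows of Aw = residual
  wbar <- rep(1 / K, K)
  N <- qr.Q(qr(cbind(rep(1, K))), complete = TRUE)[, -1, drop = FALSE]
  AN <- A %*% N
  sv <- svd(AN)
  tol <- max(dim(AN)) * max(sv$d, 0) * .Machine$double.eps
  pos <- sv$d > tol
  v <- if (any(pos)) {
    -sv$v[, pos, drop = FALSE] %*%
      ((t(sv$u[, pos, drop = FALSE]) %*% (A %*% wbar)) / sv$d[pos])
  } else matrix(0, ncol(N), 1)
  as.numeric(wbar + N %*% v)
}

#' Pre-process a depth image into a cleaned point cloud
#'
#' Back-projects depth pixels (millimeters) through the camera intrinsics,
#' keeps depths inside `[near, far]` (body subtraction by thresholding),
#' denoises by a simplified locally-optimal-projection scheme (`lop_iter`
#' rounds of attraction toward the density-weighted local mean within
#' radius `h`, default 3 x median nearest-neighbour spacing), and removes
#' isolated points whose nearest-neighbour distance exceeds `d_max`.
#'
#' @param depth numeric matrix of depth values in millimeters (rows = image
#'   rows); 0 or NA = no return.
#' @param camera a [camera_model()] with pixel intrinsics.
#' @param near,far depth window in meters.
#' @param d_max maximum allowed nearest-neighbour distance (meters).
#' @param lop_iter denoising iterations (0 disables).
#' @param h attraction radius (meters); default `3 x` median NN spacing.
#' @return A `labeled_point_set` (unlabeled) in camera coordinates (camera
#'   at the origin looking down -z); empty frames return a zero-row set
#'   with `attr(, "empty") = TRUE`.
#' @export
preprocess_depth <- function(depth, camera, near = 0.5, far = 4,
                             d_max = 0.1, lop_iter = 3, h = NULL) {
  z_m <- depth / 1000
  keep <- which(is.finite(z_m) & z_m >= near & z_m <= far, arr.ind = TRUE)
  if (nrow(keep) == 0L) {
    out <- labeled_point_set(matrix(0, 0, 3))
    attr(out, "empty") <- TRUE
    return(out)
  }
  v <- keep[, 1]; u <- keep[, 2]
  z <- z_m[keep]
  X <- cbind((u - camera$cx) * z / camera$fx,
             (v - camera$cy) * z / camera$fy,
             -z)
  stages <- nrow(X)
  if (lop_iter > 0 && nrow(X) > 3L) {
    d2 <- cross_dist2(X, X)
    diag(d2) <- Inf
    nn <- sqrt(apply(d2, 1L, min))
    if (is.null(h)) h <- 3 * median(nn)
    for (iter in seq_len(lop_iter)) {
      d2 <- cross_dist2(X, X)
      Wm <- exp(-d2 / (h / 2)^2)
      diag(Wm) <- 0
      sw <- rowSums(Wm)
      sw[sw == 0] <- 1
      target <- (Wm %*% X) / sw
      X <- 0.5 * X + 0.5 * target  # attraction toward local weighted mean
    }
  }
  d2 <- cross_dist2(X, X)
  diag(d2) <- Inf
  nn <- sqrt(apply(d2, 1L, min))
  X <- X[nn <= d_max, , drop = FALSE]
  out <- labeled_point_set(X)
  attr(out, "empty") <- nrow(X) == 0L
  attr(out, "stage_counts") <- c(thresholded = stages,
                                 denoised = stages,
                                 filtered = nrow(X))
  out
}
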