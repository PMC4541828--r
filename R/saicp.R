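#' SAICP configuration
#'
#' Controls the segment-aware articulated ICP: iteration caps, the
#' convergence tolerance (as a fraction of body height on the mean point
#' residual), label-restricted correspondence search, and the optional
#' temporal-continuity and non-overlap constraints used in tracking.
#'
#' @param max_outer_iter limb-refinement sweeps (>= 1).
#' @param max_local_iter ICP iterations inside one body-part fit (>= 1).
#' @param tol relative mean-residual change tolerance (fraction of body
#'   height).
#' @param use_labels_in_search restrict nearest-neighbour search to target
#'   points whose label belongs to the body part being fitted.
#' @param max_joint_step per-joint rotation clamp between consecutive
#'   frames, radians (temporal continuity; default 30 degrees).
#' @param overlap_constraint enable the non-overlap physical constraint.
#' @param overlap_ratio OBB point-overlap bound between non-adjacent
#'   segments (reuses the overlap-metric threshold 0.3).
#' @return List of class `saicp_config`.
#' @export
saicp_config <- function(max_outer_iter = 10, max_local_iter = 10,
                         tol = 1e-4, use_labels_in_search = TRUE,
                         max_joint_step = 30 * pi / 180,
                         overlap_constraint = FALSE, overlap_ratio = 0.3) {
  stopifnot(max_outer_iter >= 1, max_local_iter >= 1)
  structure(list(max_outer_iter = as.integer(max_outer_iter),
                 max_local_iter = as.integer(max_local_iter),
                 tol = tol, use_labels_in_search = use_labels_in_search,
                 max_joint_step = max_joint_step,
                 overlap_constraint = overlap_constraint,
                 overlap_ratio = overlap_ratio),
            class = "saicp_config")
}

# Rotation-only Procrustes: R minimizing sum ||R a_i - b_i||^2 (no
# centering; used for pivot-anchored segment fits).
rotation_fit <- function(A, B, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, nrow(A))
  H <- crossprod(A * weights, B)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
}

# Body parts of the four limbs as ordered segment-id pairs (upper, lower):
# arms before legs, left before right.
limb_parts <- function() {
  list(l_arm = c(2L, 3L), r_arm = c(4L, 5L),
       l_leg = c(6L, 7L), r_leg = c(8L, 9L))
}

# The minimal-depth segment of a connected part (its kinematic root).
part_root <- function(skeleton, part) {
  depth <- function(p) {
    d <- 0L; k <- p + 1L
    while (skeleton$segment_parent[k] != -1L) {
      d <- d + 1L; k <- skeleton$segment_parent[k] + 1L
    }
    d
  }
  part[which.min(vapply(part, depth, integer(1)))]
}

# Posed coordinates of the subject's points under per-segment world
# transforms.
pose_points <- function(subject, world) {
  pts <- subject$points$points
  lab <- subject$points$labels
  out <- pts
  for (p in seq_len(subject$skeleton$P)) {
    idx <- which(lab == p - 1L)
    if (length(idx))
      out[idx, ] <- transform_points(pts[idx, , drop = FALSE], world[[p]])
  }
  out
}

#' Local ICP for one body part
#'
#' Fits the rigid motion of a connected set of segments to the labeled
#' target: alternates (a) nearest-neighbour correspondence search,
#' restricted to target points whose propagated label lies in the part when
#' labels are used, and (b) a closed-form fit — full rigid for a part
#' containing the body root, otherwise a rotation anchored at the part's
#' proximal joint (so the part stays attached to its parent). Updates are
#' returned as a modified local-transform list. With no target points
#' carrying the part's labels the part is left at its initialisation and
#' flagged unconstrained.
#'
#' @param part integer segment ids (0-based) forming a connected body part.
#' @param subject a `subject_model` in its reference pose.
#' @param local current list of per-segment local transforms.
#' @param target labeled target `labeled_point_set`.
#' @param config a [saicp_config()].
#' @param correspondences optional fixed index vector (length = subject
#'   points) into target rows; `NA` allowed outside the part.
#' @return List: updated `local`, logical `unconstrained`, final part
#'   residual `rss`.
#' @export
local_icp <- function(part, subject, local, target, config = saicp_config(),
                      correspondences = NULL) {
  skel <- subject$skeleton
  lab <- subject$points$labels
  idx <- which(lab %in% part)
  if (length(idx) == 0L)
    return(list(local = local, unconstrained = TRUE, rss = NA_real_))
  root_seg <- which(skel$segment_parent == -1L) - 1L
  q <- part_root(skel, part)            # 0-based part root
  q1 <- q + 1L
  has_root <- root_seg %in% part

  tl <- target$labels
  cand <- if (config$use_labels_in_search && !is.null(tl)) {
    which(tl %in% part)
  } else {
    if (is.null(tl)) seq_len(nrow(target$points)) else which(!is.na(tl))
  }
  if (length(cand) == 0L && is.null(correspondences))
    return(list(local = local, unconstrained = TRUE, rss = NA_real_))

  fixed <- !is.null(correspondences)
  Tpts <- target$points
  prev_rss <- Inf
  rss <- Inf
  for (it in seq_len(config$max_local_iter)) {
    world <- forward_kinematics(skel, local)$world
    src0 <- subject$points$points[idx, , drop = FALSE]
    posed <- src0
    for (p in part) {
      k <- which(lab[idx] == p)
      if (length(k))
        posed[k, ] <- transform_points(src0[k, , drop = FALSE],
                                       world[[p + 1L]])
    }
    tgt <- if (fixed) {
      ok <- !is.na(correspondences[idx])
      if (!any(ok)) return(list(local = local, unconstrained = TRUE,
                                rss = NA_real_))
      Tpts[correspondences[idx[ok]], , drop = FALSE]
    } else {
      Tc <- Tpts[cand, , drop = FALSE]
      Tc[nearest_index(posed, Tc), , drop = FALSE]
    }
    src <- if (fixed) posed[which(!is.na(correspondences[idx])), , drop = FALSE]
           else posed
    rss <- mean(rowSums((src - tgt)^2))

    if (has_root) {
      dT <- rigid_fit(src, tgt)
      local[[root_seg + 1L]] <- compose_transforms(dT, local[[root_seg + 1L]])
    } else {
      par <- skel$segment_parent[q1] + 1L
      j0 <- skel$joint_positions[skel$segment_joint[q1, 1] + 1L, ]
      wpar <- world[[par]]
      j1 <- as.numeric(wpar$R %*% j0 + wpar$t)
      dR <- rotation_fit(sweep(src, 2L, j1), sweep(tgt, 2L, j1))
      Rl <- t(wpar$R) %*% dR %*% wpar$R %*% local[[q1]]$R
      local[[q1]] <- rigid_transform(Rl, as.numeric(j0 - Rl %*% j0))
    }
    if (is.finite(prev_rss) &&
        abs(prev_rss - rss) < (config$tol * 0.01)^2) break
    prev_rss <- rss
  }
  list(local = local, unconstrained = FALSE, rss = rss)
}

#' Segment-aware articulated ICP pose estimation
#'
#' Refines correspondences into a skeletal pose of the subject model:
#' first the torso (full rigid), then the head and every remaining segment
#' root-to-leaf (rotations about their proximal joints), then repeated
#' refinement sweeps over the four limbs in upper / lower / whole-limb
#' passes, until the mean point residual stabilises. Per-segment maps are
#' rigid, so bone lengths are conserved exactly. Invisible segments keep
#' their initial (previous-frame) local rotation and deform along with
#' their parents; invisible *points* of visible segments are co-transformed
#' with their segment. With a previous pose in `config` the
#' temporal-continuity clamp and (optionally) the non-overlap constraint
#' are applied.
#'
#' @param subject a `subject_model` in its reference pose.
#' @param target labeled target (`labeled_point_set` with labels).
#' @param correspondences initial correspondences: a `correspondence_matrix`
#'   / M x N posterior matrix (virtual-point initialisation), a list
#'   `list(P = , rows = )` when the posteriors cover only a subset of the
#'   subject's points (partial template), an integer index vector (exact),
#'   or `NULL` (pure nearest-neighbour).
#' @param config a [saicp_config()].
#' @param init_pose optional `articulated_pose` initialisation (tracking).
#' @param previous_pose optional previous-frame `articulated_pose` for the
#'   constraints.
#' @param invisible_segments 0-based ids excluded from fitting.
#' @return Object of class `saicp`: `pose` (`articulated_pose`), `deformed`
#'   (posed `subject_model`), `joints` (posed joint matrix), `residual`
#'   (mean point residual), `trace`, `unconstrained` segment ids.
#' @export
saicp <- function(subject, target, correspondences = NULL,
                  config = saicp_config(), init_pose = NULL,
                  previous_pose = NULL, invisible_segments = integer()) {
  skel <- subject$skeleton
  P <- skel$P
  target <- as_labeled_point_set(target)
  height <- diff(range(subject$points$points[, 2]))

  corr_idx <- NULL
  virt_target <- target
  virt_corr <- NULL
  if (!is.null(correspondences)) {
    is_post <- inherits(correspondences, "correspondence_matrix") ||
      is.matrix(correspondences) ||
      (is.list(correspondences) && !is.null(correspondences$P))
    if (is_post) {
      rows <- seq_len(nrow(subject$points$points))
      Pm <- if (is.matrix(correspondences)) correspondences
            else correspondences$P
      if (inherits(Pm, "correspondence_matrix")) Pm <- Pm$P
      if (is.list(correspondences) && !is.null(correspondences$rows))
        rows <- correspondences$rows
      if (nrow(Pm) != length(rows))
        stop("posterior rows must match the (subset of) subject points")
      rs <- rowSums(Pm)
      # rows with no posterior mass (unmatched / occluded template points)
      # carry no information and would drag the rigid fits to the origin
      valid <- rs > 1e-3
      rs[!valid] <- 1
      virt <- (Pm %*% target$points) / rs
      # virtual targets carry the labels of the template rows they cover
      virt_target <- labeled_point_set(virt[valid, , drop = FALSE],
                                       labels = subject$points$labels[rows][valid],
                                       n_segments = P)
      virt_corr <- rep(NA_integer_, nrow(subject$points$points))
      virt_corr[rows[valid]] <- seq_len(sum(valid))
    } else {
      corr_idx <- as.integer(correspondences)
    }
  }

  local <- if (is.null(init_pose)) identity_pose(skel)$local else init_pose$local
  fit_order <- segments_root_first(skel)
  skip <- function(p) p %in% invisible_segments
  unconstrained <- integer()

  have_virtual <- !is.null(virt_corr)
  run_part <- function(part, local, fixed_first = FALSE) {
    part <- setdiff(part, invisible_segments)
    if (length(part) == 0L) return(local)
    if (fixed_first && have_virtual) {
      # GLTP initialisation: template row i corresponds to virtual point
      # virt_corr[i] (NA where the partial template had no posterior row)
      res <- local_icp(part, subject, local, virt_target, config,
                       correspondences = virt_corr)
    } else {
      res <- local_icp(part, subject, local, target, config,
                       correspondences = corr_idx)
    }
    if (res$unconstrained)
      unconstrained <<- union(unconstrained, part)
    res$local
  }

  # initial sweep: torso, head, then remaining segments root to leaf;
  # the first sweep consumes the GLTP-initialised correspondences
  for (p in fit_order) local <- run_part(p, local, fixed_first = TRUE)

  # limb refinement: upper, lower, whole for each of the four limbs
  prev_res <- Inf
  trace <- numeric()
  for (outer in seq_len(config$max_outer_iter)) {
    for (limb in limb_parts()) {
      local <- run_part(limb[1], local)
      local <- run_part(limb[2], local)
      local <- run_part(limb, local)
    }
    world <- forward_kinematics(skel, local)$world
    posed <- pose_points(subject, world)
    ok <- !is.null(target$labels)
    cand <- if (ok) which(!is.na(target$labels)) else seq_len(nrow(target$points))
    d2 <- cross_dist2(posed, target$points[cand, , drop = FALSE])
    res <- mean(sqrt(apply(d2, 1L, min)))
    trace <- c(trace, res)
    if (!is.finite(res)) stop("non-finite SAICP residual at sweep ", outer)
    if (abs(prev_res - res) < config$tol * height) break
    prev_res <- res
  }

  pose <- forward_kinematics(skel, local)
  if (!is.null(previous_pose)) {
    pose <- enforce_constraints(pose, previous_pose, subject, config)
  }
  world <- pose$world
  posed <- pose_points(subject, world)
  deformed <- subject_model(labeled_point_set(posed,
                                              labels = subject$points$labels,
                                              n_segments = P),
                            local_skeleton_posed(skel, pose),
                            source_template = subject$source_template)
  structure(list(pose = pose, deformed = deformed,
                 joints = posed_joints(pose, skel),
                 residual = tail(trace, 1), trace = trace,
                 unconstrained = sort(unconstrained),
                 config = config),
            class = "saicp")
}

# Skeleton with joints moved to their posed positions (topology unchanged).
local_skeleton_posed <- function(skel, pose) {
  jp <- posed_joints(pose, skel)
  skeleton_model(jp, skel$parent, skel$segment_of_point, skel$segment_joint,
                 skel$segment_parent, skel$joint_names)
}

#' @export
print.saicp <- function(x, ...) {
  cat(sprintf("SAICP pose fit: %d segments, %d refinement sweeps, mean residual %.4g\n",
              length(x$pose$local), length(x$trace), x$residual))
  if (length(x$unconstrained))
    cat("  unconstrained segments:", paste(x$unconstrained, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.saicp <- function(object, ...) {
  angs <- vapply(object$pose$local, function(tf) rotation_angle(tf$R),
                 numeric(1)) * 180 / pi
  out <- list(residual = object$residual, sweeps = length(object$trace),
              angles_deg = angs, unconstrained = object$unconstrained)
  class(out) <- "summary.saicp"
  out
}

#' @export
print.summary.saicp <- function(x, ...) {
  cat(sprintf("SAICP fit: %d sweeps, mean residual %.4g\n", x$sweeps,
              x$residual))
  cat("  local rotation angles (deg):",
      paste(round(x$angles_deg, 1), collapse = " "), "\n")
  invisible(x)
}

#' Temporal and physical constraints on an articulated pose
#'
#' Clamps every segment's local-rotation change relative to the previous
#' frame to `max_joint_step` (axis preserved, angle truncated). If the
#' overlap constraint is enabled, oriented-bounding-box point overlap
#' between non-adjacent segments above `overlap_ratio` causes the deeper
#' segment's step to be halved toward the previous pose, up to 5 times;
#' halvings are recorded in `attr(, "halvings")`.
#'
#' @param pose the candidate `articulated_pose`.
#' @param previous the previous-frame `articulated_pose`.
#' @param subject a `subject_model` (geometry for the overlap check).
#' @param config a [saicp_config()].
#' @return A constrained `articulated_pose`.
#' @export
enforce_constraints <- function(pose, previous, subject,
                                config = saicp_config()) {
  skel <- subject$skeleton
  P <- skel$P
  local <- pose$local
  for (p in seq_len(P)) {
    Rp <- previous$local[[p]]$R
    rel <- t(Rp) %*% local[[p]]$R
    ang <- rotation_angle(rel)
    if (ang > config$max_joint_step + 1e-12) {
      Rn <- Rp %*% rotation_fraction(rel, config$max_joint_step / ang)
      j0 <- skel$joint_positions[skel$segment_joint[p, 1] + 1L, ]
      if (skel$segment_parent[p] == -1L) {
        # root keeps its fitted translation, clamps rotation about its joint
        tr <- local[[p]]$t + as.numeric((local[[p]]$R - Rn) %*% j0)
        local[[p]] <- rigid_transform(Rn, tr)
      } else {
        local[[p]] <- rigid_transform(Rn, as.numeric(j0 - Rn %*% j0))
      }
    }
  }
  out <- forward_kinematics(skel, local)
  halvings <- 0L
  if (config$overlap_constraint) {
    adjacent <- function(i, j) {
      skel$segment_parent[i] == j - 1L || skel$segment_parent[j] == i - 1L
    }
    depth_of <- function(p) {
      d <- 0L; k <- p
      while (skel$segment_parent[k] != -1L) {
        d <- d + 1L; k <- skel$segment_parent[k] + 1L
      }
      d
    }
    for (rep in seq_len(5L)) {
      posed <- pose_points(subject, out$world)
      lab <- subject$points$labels
      segs <- segment_split(posed, lab, P)
      boxes <- lapply(segs, function(s) if (nrow(s) > 0) fit_obb(s) else NULL)
      worst <- NULL; worst_frac <- config$overlap_ratio
      for (i in seq_len(P)) for (j in seq_len(P)) {
        if (i == j || adjacent(i, j)) next
        if (is.null(boxes[[j]]) || nrow(segs[[i]]) == 0L) next
        frac <- mean(points_in_obb(segs[[i]], boxes[[j]]))
        if (frac > worst_frac) { worst_frac <- frac; worst <- c(i, j) }
      }
      if (is.null(worst)) break
      offender <- worst[which.max(vapply(worst, depth_of, integer(1)))]
      Rp <- previous$local[[offender]]$R
      rel <- t(Rp) %*% local[[offender]]$R
      Rn <- Rp %*% rotation_fraction(rel, 0.5)
      j0 <- skel$joint_positions[skel$segment_joint[offender, 1] + 1L, ]
      local[[offender]] <- rigid_transform(Rn, as.numeric(j0 - Rn %*% j0))
      out <- forward_kinematics(skel, local)
      halvings <- halvings + 1L
    }
  }
  attr(out, "halvings") <- halvings
  out
}
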