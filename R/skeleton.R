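#' Skeleton model of an articulated body
#'
#' Joints connected by a single-rooted tree, plus the assignment of template
#' points and joints to body segments. Segment ids are `0..P-1`; the root
#' segment (torso by convention) has parent sentinel `-1` in the per-segment
#' parent array derived from the joint tree.
#'
#' @param joint_positions J x 3 matrix of joint coordinates.
#' @param parent integer length-J vector of parent joint indices (0-based),
#'   root has `-1`.
#' @param segment_of_point integer vector mapping template points to segment
#'   ids (0-based); may be `NULL` for a bare skeleton.
#' @param segment_joint P x 2 integer matrix, row p = (proximal joint, distal
#'   joint) of segment p (0-based joint indices).
#' @param segment_parent integer length-P vector of parent segment ids
#'   (0-based, root = -1).
#' @param joint_names optional character vector of joint names.
#' @return An object of class `skeleton_model`.
#' @export
skeleton_model <- function(joint_positions, parent, segment_of_point = NULL,
                           segment_joint, segment_parent, joint_names = NULL) {
  J <- nrow(joint_positions)
  parent <- as.integer(parent)
  stopifnot(length(parent) == J)
  if (sum(parent == -1L) != 1L) stop("parent tree must have exactly one root")
  # cycle check: walk each joint to the root
  for (j in seq_len(J)) {
    seen <- logical(J); k <- j
    while (parent[k] != -1L) {
      if (seen[k]) stop("parent array encodes a cycle")
      seen[k] <- TRUE
      k <- parent[k] + 1L
    }
  }
  segment_joint <- as.matrix(segment_joint)
  P <- nrow(segment_joint)
  segment_parent <- as.integer(segment_parent)
  stopifnot(length(segment_parent) == P, sum(segment_parent == -1L) == 1L)
  for (p in seq_len(P)) {
    seen <- logical(P); k <- p
    while (segment_parent[k] != -1L) {
      if (seen[k]) stop("segment_parent encodes a cycle")
      seen[k] <- TRUE
      k <- segment_parent[k] + 1L
    }
  }
  if (!is.null(segment_of_point)) {
    segment_of_point <- as.integer(segment_of_point)
    if (any(segment_of_point < 0L | segment_of_point >= P))
      stop("segment_of_point ids must be in 0..P-1")
  }
  structure(list(joint_positions = as.matrix(joint_positions),
                 parent = parent,
                 segment_of_point = segment_of_point,
                 segment_joint = segment_joint,
                 segment_parent = segment_parent,
                 P = P, joint_names = joint_names),
            class = "skeleton_model")
}

#' @export
print.skeleton_model <- function(x, ...) {
  cat("Skeleton:", nrow(x$joint_positions), "joints,", x$P, "segments")
  if (!is.null(x$segment_of_point))
    cat(",", length(x$segment_of_point), "template points assigned")
  cat("\n")
  invisible(x)
}

#' Bone lengths of a skeleton
#'
#' Distance between the proximal and distal joint of each segment.
#' @param skeleton A `skeleton_model`.
#' @return Numeric length-P vector.
#' @export
bone_lengths <- function(skeleton) {
  jp <- skeleton$joint_positions
  apply(skeleton$segment_joint, 1L, function(sj) {
    sqrt(sum((jp[sj[1] + 1L, ] - jp[sj[2] + 1L, ])^2))
  })
}

# Segments ordered so parents precede children.
segments_root_first <- function(skeleton) {
  P <- skeleton$P
  depth <- integer(P)
  for (p in seq_len(P)) {
    k <- p; d <- 0L
    while (skeleton$segment_parent[k] != -1L) {
      d <- d + 1L; k <- skeleton$segment_parent[k] + 1L
    }
    depth[p] <- d
  }
  order(depth, seq_len(P)) - 1L  # 0-based ids, deterministic tie-break
}

#' Articulated pose: local and world per-segment rigid transforms
#'
#' World transforms are the chain product of local transforms from the root
#' segment down the tree: `world[p] = world[parent(p)] o local[p]`.
#'
#' @param local list of P `rigid_transform`s, indexed by segment id + 1.
#' @param skeleton A `skeleton_model`.
#' @return Object of class `articulated_pose` with `local` and `world` lists.
#' @export
forward_kinematics <- function(skeleton, local) {
  P <- skeleton$P
  if (length(local) != P) stop("need one local transform per segment")
  world <- vector("list", P)
  for (p0 in segments_root_first(skeleton)) {
    p <- p0 + 1L
    par <- skeleton$segment_parent[p]
    world[[p]] <- if (par == -1L) local[[p]]
                  else compose_transforms(world[[par + 1L]], local[[p]])
  }
  structure(list(local = local, world = world, skeleton = skeleton),
            class = "articulated_pose")
}

#' @export
print.articulated_pose <- function(x, ...) {
  angs <- vapply(x$local, function(tf) rotation_angle(tf$R), numeric(1))
  cat("Articulated pose over", length(x$local), "segments; local rotation",
      sprintf("angles (deg): %s\n", paste(round(angs * 180 / pi, 1), collapse = " ")))
  invisible(x)
}

#' Identity pose of a skeleton
#' @param skeleton a `skeleton_model`.
#' @return An `articulated_pose` with every transform the identity.
#' @export
identity_pose <- function(skeleton) {
  forward_kinematics(skeleton, replicate(skeleton$P, identity_transform(),
                                         simplify = FALSE))
}

#' Posed joint positions under an articulated pose
#'
#' Each joint is mapped by the world transform of the segment for which it is
#' distal; the root joint by the root segment's transform. (Local transforms
#' act in reference-pose coordinates, so world transforms map reference
#' joints to posed joints directly.)
#'
#' @param pose An `articulated_pose`.
#' @param skeleton A `skeleton_model` in the reference pose.
#' @return J x 3 matrix of posed joint positions.
#' @export
posed_joints <- function(pose, skeleton = pose$skeleton) {
  jp <- skeleton$joint_positions
  J <- nrow(jp)
  out <- jp
  owner <- rep(NA_integer_, J)  # segment (1-based) whose world transform moves the joint
  root_seg <- which(skeleton$segment_parent == -1L)
  for (p in seq_len(skeleton$P)) owner[skeleton$segment_joint[p, 2] + 1L] <- p
  for (j in seq_len(J)) {
    p <- owner[j]
    if (is.na(p)) {
      # proximal-only joints (e.g. root) belong to the segment that lists
      # them as proximal, preferring the root segment
      cand <- which(skeleton$segment_joint[, 1] == j - 1L)
      p <- if (root_seg %in% cand || length(cand) == 0L) root_seg else cand[1]
    }
    out[j, ] <- transform_points(jp[j, , drop = FALSE], pose$world[[p]])
  }
  out
}

#' Propagate template segment labels to target points
#'
#' Target point n receives the label of the template point with the largest
#' posterior `P[m, n]`; ties break to the smallest template index. Columns
#' that are entirely zero get the sentinel `NA_integer_` (unassigned).
#'
#' @param P M x N nonnegative correspondence/posterior matrix (or a
#'   `correspondence_matrix`).
#' @param template_labels integer length-M template segment ids.
#' @return Integer length-N vector of target labels (with `NA` sentinels).
#' @export
propagate_labels <- function(P, template_labels) {
  if (inherits(P, "correspondence_matrix")) P <- P$P
  P <- as.matrix(P)
  if (any(P < 0)) stop("posterior entries must be nonnegative")
  if (length(template_labels) != nrow(P))
    stop("template_labels length must equal nrow(P)")
  best <- max.col(t(P), ties.method = "first")
  lab <- as.integer(template_labels)[best]
  lab[colSums(P) == 0] <- NA_integer_
  lab
}
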