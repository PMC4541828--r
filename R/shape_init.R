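#' Subject-specific articulated model
#'
#' Labeled body geometry with a baked-in skeleton: the template adapted to a
#' subject's shape and size. Produced by [generate_body()] (synthetic) or
#' [learn_subject_model()] (from an initial scan).
#'
#' @param points fully labeled `labeled_point_set`.
#' @param skeleton a `skeleton_model` whose `segment_of_point` matches.
#' @param source_template optional reference to the template it was learned
#'   from.
#' @return Object of class `subject_model`.
#' @export
subject_model <- function(points, skeleton, source_template = NULL) {
  if (is.null(points$labels) || anyNA(points$labels))
    stop("every subject-model point must be labeled")
  counts <- tabulate(points$labels + 1L, nbins = skeleton$P)
  if (any(counts == 0L))
    warning("segments with no points: ",
            paste(which(counts == 0L) - 1L, collapse = ", "))
  skeleton$segment_of_point <- points$labels
  structure(list(points = points, skeleton = skeleton,
                 source_template = source_template),
            class = "subject_model")
}

#' @export
print.subject_model <- function(x, ...) {
  cat("Subject model:", nrow(x$points$points), "labeled points,",
      x$skeleton$P, "segments,", nrow(x$skeleton$joint_positions),
      "joints\n")
  invisible(x)
}

# Segments adjacent to a joint: those listing it as proximal or distal,
# plus the parent of any segment whose pivot it is (the joint is carried by
# the parent's motion; pivot-invariance makes either map agree).
joint_adjacent_segments <- function(skeleton, j0) {
  sj <- skeleton$segment_joint
  segs <- which(sj[, 1] == j0 | sj[, 2] == j0)
  prox <- segs[sj[segs, 1] == j0]
  pars <- skeleton$segment_parent[prox]
  pars <- pars[pars != -1L] + 1L
  sort(unique(c(segs, pars)))
}

#' Learn a subject-specific articulated model from an initial scan
#'
#' Two-step shape initialization: (1) coherent point drift registers the
#' T-pose template onto the initial stretched-pose scan `Z`; (2) for every
#' segment, a similarity transform (rotation, translation and one isotropic
#' scale — size adaptation happens here and only here) is fitted from the
#' template's segment points to their posterior-weighted virtual targets,
#' and the skeleton joints are mapped accordingly, a joint shared by two
#' segments taking the average of both maps. Segment labels transfer to `Z`
#' by posterior argmax; with a partial (single-view) scan the template is
#' first restricted to its camera-visible points and the invisible points
#' are co-transformed with their segment to complete the model.
#'
#' @param template a `subject_model` holding the labeled T-pose template and
#'   its skeleton.
#' @param Z initial target scan (`labeled_point_set` or matrix), in a pose
#'   similar to the template's.
#' @param config a [gltp_config()] for the CPD step.
#' @param camera optional [camera_model()]: treat `Z` as a single-view scan.
#' @param r_exp HPR flip-radius exponent for the visibility step.
#' @return A `subject_model` for the subject, with `fit` (the CPD fit),
#'   `segment_transforms` and a `residual` diagnostic attached as
#'   attributes.
#' @export
learn_subject_model <- function(template, Z, config = gltp_config(),
                                camera = NULL, r_exp = 2) {
  Z <- as_labeled_point_set(Z)
  skel <- template$skeleton
  P <- skel$P
  full <- template$points
  Yv <- if (!is.null(camera)) visible_subset(full, camera, r_exp) else full

  fit <- cpd(Yv, Z, config)
  Pm <- fit$P$P
  rs <- rowSums(Pm)
  rs[rs == 0] <- .Machine$double.eps
  virt <- (Pm %*% Z$points) / rs  # posterior-weighted virtual targets

  tfs <- vector("list", P)
  for (p in seq_len(P)) {
    idx <- which(Yv$labels == p - 1L)
    if (length(idx) == 0L) { tfs[[p]] <- identity_transform(); next }
    tfs[[p]] <- rigid_fit(Yv$points[idx, , drop = FALSE],
                          virt[idx, , drop = FALSE],
                          weights = rs[idx], allow_scale = TRUE)
  }

  jp <- skel$joint_positions
  new_jp <- jp
  for (j in seq_len(nrow(jp))) {
    segs <- joint_adjacent_segments(skel, j - 1L)
    if (length(segs) == 0L) next
    maps <- vapply(segs, function(p)
      transform_points(jp[j, , drop = FALSE], tfs[[p]]), numeric(3))
    new_jp[j, ] <- rowMeans(matrix(maps, nrow = 3))
  }

  z_labels <- propagate_labels(Pm, Yv$labels)
  if (anyNA(z_labels)) {
    # unassigned sentinel columns: label by nearest deformed template point
    na_i <- which(is.na(z_labels))
    ni <- nearest_index(Z$points[na_i, , drop = FALSE], fit$TY)
    z_labels[na_i] <- Yv$labels[ni]
  }
  pts <- Z$points
  labs <- z_labels
  if (!is.null(camera)) {
    # complete the model: co-transform the template's invisible points
    invis <- which(!attr(Yv, "visible_mask"))
    if (length(invis)) {
      ip <- full$points[invis, , drop = FALSE]
      il <- full$labels[invis]
      for (p in seq_len(P)) {
        k <- which(il == p - 1L)
        if (length(k))
          ip[k, ] <- transform_points(ip[k, , drop = FALSE], tfs[[p]])
      }
      pts <- rbind(pts, ip)
      labs <- c(labs, il)
    }
  }

  skel_new <- skeleton_model(new_jp, skel$parent, labs, skel$segment_joint,
                             skel$segment_parent, skel$joint_names)
  out <- subject_model(labeled_point_set(pts, labels = labs, n_segments = P),
                       skel_new, source_template = template)
  attr(out, "fit") <- fit
  attr(out, "segment_transforms") <- tfs
  attr(out, "residual") <- mean(residuals(fit))
  out
}
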