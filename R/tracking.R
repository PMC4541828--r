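#' Tracker state for sequential pose estimation
#'
#' Created by [tracker_init()], advanced by [process_frame()]. Holds the
#' current GLTP template (the previous frame's posed subject model), the
#' previous pose, and the validation history.
#'
#' @param subject a `subject_model` from shape initialization.
#' @param camera a [camera_model()] (ignored in full-scan mode).
#' @param gltp_cfg a [gltp_config()].
#' @param saicp_cfg a [saicp_config()].
#' @param thresholds a [validation_thresholds()] list.
#' @param tracking use the previous frame's model as template (`TRUE`) or
#'   the T-pose template every frame (`FALSE`, independent mode).
#' @param full_scan input frames are complete scans: visibility extraction
#'   and volume validation are bypassed.
#' @param r_exp HPR flip-radius exponent.
#' @return Object of class `tracker_state`.
#' @export
tracker_init <- function(subject, camera = NULL,
                         gltp_cfg = gltp_config(),
                         saicp_cfg = saicp_config(),
                         thresholds = validation_thresholds(),
                         tracking = TRUE, full_scan = FALSE, r_exp = 2) {
  if (!full_scan && is.null(camera))
    stop("depth-frame mode needs a camera model")
  structure(list(frame = 0L,
                 subject = subject,          # reference (T-pose) model
                 template = subject,         # current posed model Z_t
                 previous_pose = NULL,
                 camera = camera, r_exp = r_exp,
                 gltp_cfg = gltp_cfg, saicp_cfg = saicp_cfg,
                 thresholds = thresholds,
                 tracking = isTRUE(tracking), full_scan = isTRUE(full_scan),
                 reports = list(), gltp_iterations = integer()),
            class = "tracker_state")
}

#' @export
print.tracker_state <- function(x, ...) {
  cat(sprintf("Tracker at frame %d (%s, %s mode), %d GLTP iterations so far\n",
              x$frame, if (x$tracking) "tracking" else "independent",
              if (x$full_scan) "full-scan" else "depth",
              sum(x$gltp_iterations)))
  invisible(x)
}

# GLTP template for the current frame: visible points of the previous posed
# model (tracking) or of the T-pose template (independent mode), minus any
# excluded segments.
frame_template <- function(state, exclude = integer()) {
  base <- if (state$tracking) state$template else state$subject
  ps <- base$points
  rows <- seq_len(nrow(ps$points))
  if (length(exclude)) {
    rows <- which(!(ps$labels %in% exclude))
    ps <- subset_points(ps, rows)
  }
  if (!state$full_scan) {
    vs <- visible_subset(ps, state$camera, state$r_exp)
    rows <- rows[attr(vs, "visible_mask")]
    ps <- vs
  }
  attr(ps, "subject_rows") <- rows
  ps
}

#' Process one frame through the tracking pipeline
#'
#' Runs the per-frame loop: visible-point extraction of the current
#' template, GLTP correspondence estimation, label propagation, segment
#' volume validation with at most two remedial re-initialisations
#' (vanished-segment rerun, then T-pose rerun; the massive-occlusion case
#' skips straight to constrained articulated registration), SAICP pose
#' estimation with invisible-point co-transform, and the template update.
#' In full-scan mode visibility and validation are bypassed.
#'
#' @param state a `tracker_state`.
#' @param X_t target frame (`labeled_point_set` or matrix).
#' @return List: updated `state`, `pose` (`articulated_pose`), `joints`,
#'   `report` (`validation_report` or `NULL`), `fit` (the final `saicp`),
#'   `failed` flag.
#' @export
process_frame <- function(state, X_t) {
  X_t <- as_labeled_point_set(X_t)
  state$frame <- state$frame + 1L
  exclude <- integer()
  tpose_rerun <- FALSE
  report <- NULL
  gltp_iters <- 0L
  saicp_cfg <- state$saicp_cfg
  constrained_only <- FALSE
  failed <- FALSE

  for (attempt in 1:3) {  # initial run + at most 2 remedial reruns
    tpl <- if (tpose_rerun) {
      st2 <- state; st2$tracking <- FALSE
      frame_template(st2, exclude = integer())
    } else frame_template(state, exclude = exclude)
    # tracking mode warm-starts the variance from the local alignment of
    # the pose-adapted template; independent mode uses the global formula
    warm <- state$tracking && !tpose_rerun && state$frame > 1L
    s2i <- if (warm) {
      nm_y <- colMeans(tpl$points); nm_x <- colMeans(X_t$points)
      sc_y <- sqrt(mean(rowSums(sweep(tpl$points, 2L, nm_y)^2)))
      sc_x <- sqrt(mean(rowSums(sweep(X_t$points, 2L, nm_x)^2)))
      nn_sigma2(sweep(tpl$points, 2L, nm_y) / max(sc_y, 1e-12),
                sweep(X_t$points, 2L, nm_x) / max(sc_x, 1e-12))
    } else NULL
    fit <- gltp(tpl, X_t, state$gltp_cfg, sigma2_init = s2i)
    gltp_iters <- gltp_iters + fit$n_iter
    labels <- propagate_labels(fit$P, tpl$labels)
    Xhat <- labeled_point_set(X_t$points, labels = labels,
                              n_segments = state$subject$skeleton$P)
    if (state$full_scan) { report <- NULL; break }
    report <- validate_segments(Xhat, state$subject,
                                thresholds = state$thresholds)
    if (!state$tracking || report$case == "PASS") break
    act <- remedy(report)
    if (attempt == 3L) { failed <- TRUE; break }
    if (act$action == "RERUN_GLTP_WITHOUT_SEGMENTS") {
      exclude <- union(exclude, act$segments)
    } else if (act$action == "RERUN_GLTP_TPOSE") {
      tpose_rerun <- TRUE
    } else {  # CONSTRAINED_SAICP_ONLY
      constrained_only <- TRUE
      break
    }
  }

  if (failed && !is.null(state$previous_pose)) {
    # carry the previous pose forward, flagged
    pose <- state$previous_pose
    sfit <- NULL
  } else {
    if (constrained_only) {
      saicp_cfg$overlap_constraint <- TRUE
      corr <- NULL  # no reliable correspondences: pure constrained NN ICP
      invis <- report$invisible_segments
    } else {
      corr <- list(P = fit$P$P, rows = attr(tpl, "subject_rows"))
      invis <- exclude
    }
    sfit <- saicp(state$subject, Xhat, correspondences = corr,
                  config = saicp_cfg,
                  init_pose = state$previous_pose,
                  previous_pose = state$previous_pose,
                  invisible_segments = invis)
    pose <- sfit$pose
  }

  state$previous_pose <- pose
  posed <- pose_points(state$subject, pose$world)
  state$template <- subject_model(
    labeled_point_set(posed, labels = state$subject$points$labels,
                      n_segments = state$subject$skeleton$P),
    local_skeleton_posed(state$subject$skeleton, pose),
    source_template = state$subject)
  state$reports <- c(state$reports, list(report))
  state$gltp_iterations <- c(state$gltp_iterations, gltp_iters)

  list(state = state, pose = pose,
       joints = posed_joints(pose, state$subject$skeleton),
       report = report, fit = sfit, failed = failed)
}

#' Track a sequence of frames
#'
#' Maps [process_frame()] over an ordered frame list. Unreadable or failing
#' frames carry the previous pose forward and are flagged; the output
#' always has one pose per input frame. Identical inputs give identical
#' outputs (there is no randomised step).
#'
#' @param frames list of frames (`labeled_point_set`s / matrices) or paths
#'   to PLY/XYZ files.
#' @param subject a `subject_model`.
#' @param ... passed to [tracker_init()] (camera, configs, `tracking`,
#'   `full_scan`).
#' @return Object of class `track_result`: `poses`, `joints` (list of J x 3
#'   matrices), `joints_df` (long data frame: frame, joint, x, y, z),
#'   `reports`, `failed` (logical vector), `gltp_iterations`, final
#'   `state`.
#' @export
track_sequence <- function(frames, subject, ...) {
  state <- tracker_init(subject, ...)
  n <- length(frames)
  poses <- vector("list", n)
  joints <- vector("list", n)
  failed <- logical(n)
  for (t in seq_len(n)) {
    fr <- frames[[t]]
    if (is.character(fr)) {
      fr <- tryCatch(suppressWarnings(read_point_set(fr)), error = function(e) {
        message("skipping unreadable frame ", t, ": ", conditionMessage(e))
        NULL
      })
      if (is.null(fr)) {
        failed[t] <- TRUE
        poses[[t]] <- state$previous_pose
        joints[[t]] <- if (!is.null(state$previous_pose))
          posed_joints(state$previous_pose, subject$skeleton)
        else subject$skeleton$joint_positions
        next
      }
    }
    step <- process_frame(state, fr)
    state <- step$state
    poses[[t]] <- step$pose
    joints[[t]] <- step$joints
    failed[t] <- step$failed
  }
  jn <- subject$skeleton$joint_names
  if (is.null(jn)) jn <- paste0("j", seq_len(nrow(subject$skeleton$joint_positions)) - 1L)
  joints_df <- do.call(rbind, lapply(seq_len(n), function(t)
    data.frame(frame = t, joint = jn,
               x = joints[[t]][, 1], y = joints[[t]][, 2],
               z = joints[[t]][, 3])))
  structure(list(poses = poses, joints = joints, joints_df = joints_df,
                 reports = state$reports, failed = failed,
                 gltp_iterations = state$gltp_iterations, state = state),
            class = "track_result")
}

#' @export
print.track_result <- function(x, ...) {
  n <- length(x$poses)
  pass <- vapply(x$reports, function(r) is.null(r) || r$case == "PASS",
                 logical(1))
  cat(sprintf("Tracked %d frames: %d passed validation, %d failed frames, %d total GLTP iterations\n",
              n, sum(pass), sum(x$failed), sum(x$gltp_iterations)))
  invisible(x)
}
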