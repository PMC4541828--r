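#' Default segment-volume validation thresholds
#'
#' The operating thresholds of the volume validator: overlap `m1 = 0.3`,
#' volume-deformation `m2 = 10`, torso height ratio `torso_m2 = 1.4`, and
#' the minimum fraction of expected points a segment may keep,
#' `min_point_frac = 0.25`.
#'
#' @param m1,m2,torso_m2,min_point_frac positive scalars.
#' @param case3_frac fraction of segments that must fail for the
#'   "most segments invalid" case (default > 0.5).
#' @return Named list of thresholds.
#' @export
validation_thresholds <- function(m1 = 0.3, m2 = 10, torso_m2 = 1.4,
                                  min_point_frac = 0.25, case3_frac = 0.5) {
  stopifnot(m1 > 0, m2 > 0, torso_m2 > 0, min_point_frac > 0)
  list(m1 = m1, m2 = m2, torso_m2 = torso_m2,
       min_point_frac = min_point_frac, case3_frac = case3_frac)
}

# Split a labeled point set into per-segment coordinate matrices.
segment_split <- function(points, labels, P) {
  lapply(seq_len(P) - 1L, function(p) points[which(labels == p), , drop = FALSE])
}

#' Segment overlap metric
#'
#' For each segment i, the largest fraction of its points that also fall
#' inside another segment's oriented bounding box:
#' `M1(S_i) = max_{j != i} |S_i inside B(S_j)| / |S_i|`. Values near 1 mean
#' the segment's points have collapsed into another segment. Empty segments
#' get `NA` (treated as failing by the validator).
#'
#' @param points n x 3 matrix of labeled target points.
#' @param labels integer segment ids (0-based, `NA` allowed).
#' @param P number of segments.
#' @param boxes optional precomputed list of `oriented_box`es.
#' @return Numeric length-P vector in `[0, 1]` (or `NA`).
#' @export
m1_overlap <- function(points, labels, P, boxes = NULL) {
  segs <- segment_split(pts_of(points), labels, P)
  if (is.null(boxes))
    boxes <- lapply(segs, function(s) if (nrow(s) > 0) fit_obb(s) else NULL)
  out <- rep(NA_real_, P)
  for (i in seq_len(P)) {
    if (nrow(segs[[i]]) == 0L) next
    best <- 0
    for (j in seq_len(P)) {
      if (j == i || is.null(boxes[[j]])) next
      frac <- mean(points_in_obb(segs[[i]], boxes[[j]]))
      if (frac > best) best <- frac
    }
    out[i] <- best
  }
  out
}

#' Segment volume-deformation metric
#'
#' Ratio of the target segment's OBB volume to the template segment's OBB
#' volume; for the torso, the ratio of OBB heights is used instead (the
#' torso's volume is stable, its height is the sensitive quantity).
#'
#' @param target_seg,template_seg point matrices of the same segment.
#' @param is_torso logical.
#' @return Positive scalar, or `NA` if either segment is empty / the
#'   template volume is zero.
#' @export
m2_deformation <- function(target_seg, template_seg, is_torso = FALSE) {
  target_seg <- pts_of(target_seg); template_seg <- pts_of(template_seg)
  if (nrow(target_seg) == 0L || nrow(template_seg) == 0L) return(NA_real_)
  bt <- fit_obb(target_seg); bs <- fit_obb(template_seg)
  if (is_torso) return(bt$height / bs$height)
  if (bs$volume <= 0) return(NA_real_)
  bt$volume / bs$volume
}

#' Validate segment volumes of a labeled target frame
#'
#' Computes per-segment overlap (M1) and volume-deformation (M2) metrics of
#' the labeled target against the subject template and classifies the frame:
#'
#' * `CASE_I` — some segment has `M1` above threshold or has kept fewer than
#'   `min_point_frac` of its expected points (segment vanished from view);
#' * `CASE_II` — one segment fails `M1` while a *different* segment fails
#'   `M2` (a reappearing limb merged into another segment, inflating it);
#' * `CASE_III` — more than `case3_frac` of segments fail either metric
#'   (massive self-occlusion); takes precedence over II, which takes
#'   precedence over I;
#' * `PASS` otherwise.
#'
#' @param target labeled target: `labeled_point_set` with labels, or matrix.
#' @param labels target labels if `target` is a bare matrix.
#' @param subject a [subject_model()] (template geometry + labels).
#' @param thresholds a [validation_thresholds()] list.
#' @return Object of class `validation_report`: `M1`, `M2`, per-segment
#'   verdicts, `case`, `failing_segments`, `invisible_segments`.
#' @export
validate_segments <- function(target, subject, labels = NULL,
                              thresholds = validation_thresholds()) {
  ps <- if (inherits(target, "labeled_point_set")) target
        else labeled_point_set(target, labels = labels)
  if (is.null(ps$labels)) stop("target must carry segment labels")
  P <- subject$skeleton$P
  tpl <- subject$points
  Xs <- segment_split(ps$points, ps$labels, P)
  Ts <- segment_split(tpl$points, tpl$labels, P)
  torso <- which(subject$skeleton$segment_parent == -1L)

  m1 <- m1_overlap(ps$points, ps$labels, P)
  m2 <- vapply(seq_len(P), function(i)
    m2_deformation(Xs[[i]], Ts[[i]], is_torso = (i == torso)), numeric(1))

  exp_frac <- vapply(seq_len(P), function(i) {
    ne <- nrow(Ts[[i]])
    if (ne == 0L) return(NA_real_)
    # expected share of target points, proportional to template share
    (nrow(Xs[[i]]) / nrow(ps$points)) / (ne / nrow(tpl$points))
  }, numeric(1))

  th <- thresholds
  m2_lim <- ifelse(seq_len(P) == torso, th$torso_m2, th$m2)
  fail_m1 <- is.na(m1) | m1 > th$m1
  fail_m2 <- is.na(m2) | m2 > m2_lim
  warn_m2_small <- !is.na(m2) & m2 < 1 / m2_lim  # missing parts: warn only
  fail_count <- is.na(exp_frac) | exp_frac < th$min_point_frac
  fail_any <- fail_m1 | fail_m2 | fail_count

  # Case II needs an M1-failing segment and a *different* M2-failing segment
  i1 <- which(fail_m1); i2 <- which(fail_m2)
  distinct_pair <- length(i1) > 0 && length(i2) > 0 &&
    !(length(i1) == 1L && length(i2) == 1L && i1 == i2)
  case <- "PASS"
  if (mean(fail_m1 | fail_m2) > th$case3_frac) {
    case <- "CASE_III"
  } else if (distinct_pair) {
    case <- "CASE_II"
  } else if (any(fail_m1 | fail_count)) {
    case <- "CASE_I"
  }

  structure(list(M1 = m1, M2 = m2,
                 fail_m1 = fail_m1, fail_m2 = fail_m2,
                 fail_count = fail_count, warn_m2_small = warn_m2_small,
                 point_frac = exp_frac,
                 case = case,
                 failing_segments = which(fail_any) - 1L,
                 invisible_segments = which(fail_m1 | fail_count) - 1L,
                 thresholds = th),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Segment volume validation:", x$case, "\n")
  df <- data.frame(segment = seq_along(x$M1) - 1L,
                   M1 = round(x$M1, 3), M2 = round(x$M2, 3),
                   point_frac = round(x$point_frac, 3),
                   fails = x$fail_m1 | x$fail_m2 | x$fail_count)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Remedy action for a failed validation
#'
#' Maps the detected failure case to the corrective action of the tracking
#' pipeline: vanished segments are dropped from the GLTP template
#' (`RERUN_GLTP_WITHOUT_SEGMENTS`), reappearing segments trigger
#' re-initialization from the T-pose template (`RERUN_GLTP_TPOSE`), and the
#' massive-occlusion case falls back to constrained articulated registration
#' with pose continuity (`CONSTRAINED_SAICP_ONLY`).
#'
#' @param report a `validation_report` with `case != "PASS"`.
#' @return List with `action` and, for the first case, the 0-based
#'   `segments` to exclude.
#' @export
remedy <- function(report) {
  switch(report$case,
    PASS = list(action = "NONE", segments = integer()),
    CASE_I = list(action = "RERUN_GLTP_WITHOUT_SEGMENTS",
                  segments = report$invisible_segments),
    CASE_II = list(action = "RERUN_GLTP_TPOSE", segments = integer()),
    CASE_III = list(action = "CONSTRAINED_SAICP_ONLY", segments = integer()))
}
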