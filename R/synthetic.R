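# Synthetic articulated bodies: a 10-segment capsule body (torso, head,
# upper/lower arms, upper/lower legs) sampled to labeled surface points with
# an exact skeleton, posed by rigid per-segment kinematics so ground truth
# is exact. Emulates full-body laser-scan style clouds (complete surfaces,
# large articulation) and single-view depth frames (partial view, noise,
# outliers) at desk scale.

#' Body specification for the synthetic generator
#'
#' Segment lengths and radii of a 10-segment body in a T-pose (arms
#' stretched horizontally), about `height` tall. Units are meters; the
#' default 1.7 m body makes centimeter thresholds directly meaningful.
#'
#' @param height body height in meters.
#' @param density surface sampling density, points per square meter.
#' @param radii named numeric overrides of segment radii (names among
#'   `torso, head, upper_arm, lower_arm, upper_leg, lower_leg`).
#' @param limb_scale multiplies all limb (arm and leg) segment lengths,
#'   e.g. 1.1 for a subject with 10% longer limbs.
#' @return Object of class `body_spec`.
#' @export
body_spec <- function(height = 1.7, density = 300, radii = NULL,
                      limb_scale = 1) {
  r <- c(torso = 0.14, head = 0.10, upper_arm = 0.05, lower_arm = 0.04,
         upper_leg = 0.06, lower_leg = 0.05)
  if (!is.null(radii)) r[names(radii)] <- radii
  if (any(r <= 0) || height <= 0 || density <= 0 || limb_scale <= 0)
    stop("all body dimensions must be > 0")
  structure(list(height = height, density = density, radii = r,
                 limb_scale = limb_scale),
            class = "body_spec")
}

#' Segment names of the synthetic body
#' @return Character vector of 10 segment names (id = position - 1).
#' @export
segment_names <- function() {
  c("torso", "head", "l_upper_arm", "l_lower_arm", "r_upper_arm",
    "r_lower_arm", "l_upper_leg", "l_lower_leg", "r_upper_leg",
    "r_lower_leg")
}

# The T-pose skeleton of the synthetic body: 15 joints, 10 segments.
tpose_skeleton <- function(spec = body_spec()) {
  s <- spec$height / 1.7  # global scale
  ls <- spec$limb_scale
  arm <- 0.28 * s * ls    # upper-arm = lower-arm length
  ulg <- 0.42 * s * ls    # upper-leg = lower-leg length
  shx <- 0.20 * s; shy <- 1.40 * s
  hx <- 0.13 * s   # feet-apart calibration stance: thighs clearly separated
  jp <- rbind(
    pelvis     = c(0,           0.92 * s, 0),
    neck       = c(0,           1.45 * s, 0),
    head_top   = c(0,           1.70 * s, 0),
    l_shoulder = c(shx,         shy, 0),
    l_elbow    = c(shx + arm,   shy, 0),
    l_wrist    = c(shx + 2*arm, shy, 0),
    r_shoulder = c(-shx,         shy, 0),
    r_elbow    = c(-shx - arm,   shy, 0),
    r_wrist    = c(-shx - 2*arm, shy, 0),
    l_hip      = c(hx,  0.92 * s, 0),
    l_knee     = c(hx,  0.92 * s - ulg, 0),
    l_ankle    = c(hx,  0.92 * s - 2 * ulg, 0),
    r_hip      = c(-hx, 0.92 * s, 0),
    r_knee     = c(-hx, 0.92 * s - ulg, 0),
    r_ankle    = c(-hx, 0.92 * s - 2 * ulg, 0))
  parent <- c(-1L, 0L, 1L, 1L, 3L, 4L, 1L, 6L, 7L, 0L, 9L, 10L, 0L, 12L, 13L)
  segment_joint <- rbind(
    c(0L, 1L),   # torso: pelvis -> neck
    c(1L, 2L),   # head
    c(3L, 4L), c(4L, 5L),    # left arm
    c(6L, 7L), c(7L, 8L),    # right arm
    c(9L, 10L), c(10L, 11L), # left leg
    c(12L, 13L), c(13L, 14L))
  segment_parent <- c(-1L, 0L, 0L, 2L, 0L, 4L, 0L, 6L, 0L, 8L)
  skeleton_model(jp, parent, segment_of_point = NULL,
                 segment_joint = segment_joint,
                 segment_parent = segment_parent,
                 joint_names = rownames(jp))
}

# Uniform points on a capsule from a to b with radius r; count n.
# Hemispherical caps are sampled only where requested: interior segment
# ends are left open so adjacent segments do not engulf each other past
# their shared joint. Deterministic given the RNG state.
sample_capsule <- function(a, b, r, n, cap_a = FALSE, cap_b = FALSE) {
  ax <- b - a
  L <- sqrt(sum(ax^2))
  u <- ax / L
  # orthonormal frame around u
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * u) * u; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2], u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  a_cyl <- 2 * pi * r * L
  a_cap <- (cap_a + cap_b) * 2 * pi * r^2
  on_cyl <- runif(n) < a_cyl / (a_cyl + a_cap)
  th <- runif(n, 0, 2 * pi)
  h <- runif(n, 0, L)
  # cylinder side
  circ <- outer(cos(th), e1) + outer(sin(th), e2)
  pts <- matrix(rep(a, each = n), n, 3) + outer(h, u) + r * circ
  # caps: uniform on the requested hemisphere(s)
  idx <- which(!on_cyl)
  if (length(idx) && (cap_a || cap_b)) {
    z <- runif(length(idx), -1, 1)
    phi <- runif(length(idx), 0, 2 * pi)
    rho <- sqrt(1 - z^2)
    sph <- cbind(rho * cos(phi), rho * sin(phi), z)
    d3 <- sph %*% rbind(e1, e2, u)  # world-frame unit vectors
    along <- as.numeric(d3 %*% u)
    if (cap_a && cap_b) {
      centre <- ifelse(along >= 0, 1, 0)
    } else if (cap_b) {
      d3 <- d3 - 2 * outer(pmin(along, 0), u)  # fold onto the +u hemisphere
      centre <- rep(1, length(idx))
    } else {
      d3 <- d3 - 2 * outer(pmax(along, 0), u)
      centre <- rep(0, length(idx))
    }
    base <- matrix(rep(a, each = length(idx)), ncol = 3) + outer(centre, ax)
    pts[idx, ] <- base + r * d3
  }
  pts
}

#' Generate a synthetic labeled body in T-pose
#'
#' Samples each segment's capsule surface with a point count proportional to
#' its area, labels points exactly by construction (seam points belong to
#' the segment that generated them, i.e. the proximal side), and returns the
#' body together with its ground-truth skeleton as a [subject_model()].
#'
#' @param spec a [body_spec()].
#' @param seed integer RNG seed; the same seed reproduces the body exactly.
#' @return A `subject_model` (labeled points + skeleton).
#' @export
generate_body <- function(spec = body_spec(), seed = 1) {
  skel <- tpose_skeleton(spec)
  r <- spec$radii[c("torso", "head", "upper_arm", "lower_arm", "upper_arm",
                    "lower_arm", "upper_leg", "lower_leg", "upper_leg",
                    "lower_leg")]
  with_seed(seed, {
    pts <- NULL; lab <- integer()
    # caps only at free ends: top of head, wrists, ankles; the torso is an
    # open cylinder (a pelvis cap would engulf the tops of the thighs)
    cap_a <- c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
               FALSE)
    cap_b <- c(FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE,
               TRUE)
    for (p in 1:10) {
      sj <- skel$segment_joint[p, ] + 1L
      a <- skel$joint_positions[sj[1], ]
      b <- skel$joint_positions[sj[2], ]
      L <- sqrt(sum((b - a)^2))
      area <- 2 * pi * r[p] * L + (cap_a[p] + cap_b[p]) * 2 * pi * r[p]^2
      n <- max(1L, round(spec$density * area))
      if (n < 20L)
        stop("sampling density yields fewer than 20 points for segment ",
             segment_names()[p], " (", n, ")")
      pts <- rbind(pts, sample_capsule(a, b, r[p], n, cap_a[p], cap_b[p]))
      lab <- c(lab, rep.int(p - 1L, n))
    }
    skel$segment_of_point <- lab
    subject_model(labeled_point_set(pts, labels = lab, n_segments = 10L),
                  skel)
  })
}

# Evaluate expr with a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Build an articulated pose from per-segment rotations
#'
#' Each non-root segment's local transform is a rotation about its proximal
#' joint (in reference-pose coordinates); the root may get a full rigid
#' transform. Rotations compose down the tree by forward kinematics.
#'
#' @param skeleton a `skeleton_model` in the reference pose.
#' @param rotations list of 3x3 rotation matrices indexed by segment id + 1
#'   (missing / NULL entries mean identity).
#' @param root_transform optional `rigid_transform` for the root segment
#'   (applied about the world origin; a plain rotation here rotates the root
#'   about its proximal joint like every other segment).
#' @return An `articulated_pose`.
#' @export
pose_from_rotations <- function(skeleton, rotations = list(),
                                root_transform = NULL) {
  P <- skeleton$P
  local <- vector("list", P)
  root <- which(skeleton$segment_parent == -1L)
  for (p in seq_len(P)) {
    R <- if (p <= length(rotations) && !is.null(rotations[[p]]))
      rotations[[p]] else diag(3)
    j0 <- skeleton$joint_positions[skeleton$segment_joint[p, 1] + 1L, ]
    local[[p]] <- rigid_transform(R, as.numeric(j0 - R %*% j0))
  }
  if (!is.null(root_transform)) {
    local[[root]] <- compose_transforms(root_transform, local[[root]])
  }
  forward_kinematics(skeleton, local)
}

#' Pose a synthetic body rigidly per segment
#'
#' Applies an articulated pose to a labeled body: every point moves with its
#' segment's world transform (rigid skinning, no blending, so bone lengths
#' and ground truth are exact).
#'
#' @param body a `subject_model` (e.g. from [generate_body()]).
#' @param pose an `articulated_pose`, or a rotations list passed to
#'   [pose_from_rotations()].
#' @param root_transform optional root `rigid_transform` when `pose` is a
#'   rotations list.
#' @return List with `points` (posed `labeled_point_set`), `joints` (posed
#'   J x 3 ground-truth joint matrix) and `pose`.
#' @export
pose_body <- function(body, pose = list(), root_transform = NULL) {
  skel <- body$skeleton
  if (!inherits(pose, "articulated_pose"))
    pose <- pose_from_rotations(skel, pose, root_transform)
  ps <- body$points
  out <- ps$points
  for (p in seq_len(skel$P)) {
    idx <- which(ps$labels == p - 1L)
    if (length(idx))
      out[idx, ] <- transform_points(ps$points[idx, , drop = FALSE],
                                     pose$world[[p]])
  }
  list(points = labeled_point_set(out, labels = ps$labels,
                                  n_segments = skel$P),
       joints = posed_joints(pose, skel),
       pose = pose)
}

#' Render a single-view depth-style frame of a posed body
#'
#' Keeps only camera-visible points (hidden-point-removal by default, or an
#' exact z-buffer rasterisation for oracle testing), adds Gaussian noise
#' along the viewing direction, and appends uniform outlier points inside
#' the inflated bounding volume. Ground-truth labels ride along for
#' evaluation only (outliers get `NA`).
#'
#' @param posed posed `labeled_point_set` (e.g. `pose_body(...)$points`).
#' @param camera a [camera_model()].
#' @param sigma_n depth noise standard deviation (meters).
#' @param outlier_frac fraction of visible count added as outliers, `[0,1)`.
#' @param seed RNG seed for noise and outliers.
#' @param method visibility method, `"hpr"` or `"zbuffer"`.
#' @param r_exp HPR flip-radius exponent.
#' @return A `labeled_point_set` with `visible = TRUE` rows and an
#'   `attr(, "n_outliers")`.
#' @export
render_depth_frame <- function(posed, camera, sigma_n = 0, outlier_frac = 0,
                               seed = 1, method = c("hpr", "zbuffer"),
                               r_exp = 2) {
  method <- match.arg(method)
  ps <- as_labeled_point_set(posed)
  bb <- apply(ps$points, 2L, range)
  cp <- camera$position
  if (all(cp >= bb[1, ] & cp <= bb[2, ]))
    stop("camera position lies inside the body's bounding volume")
  keep <- if (method == "hpr") {
    extract_visible(ps, camera, r_exp)$visible_mask
  } else {
    zbuffer_visible(ps$points, camera)
  }
  vis <- subset_points(ps, which(keep))
  n <- nrow(vis$points)
  with_seed(seed, {
    pts <- vis$points
    if (sigma_n > 0) {
      dirs <- sweep(pts, 2L, cp)  # viewing rays
      dirs <- dirs / sqrt(rowSums(dirs^2))
      pts <- pts + dirs * rnorm(n, 0, sigma_n)
    }
    n_out <- round(outlier_frac * n)
    lab <- vis$labels
    if (n_out > 0) {
      pad <- 0.15 * (bb[2, ] - bb[1, ] + 1e-9)
      out_pts <- sapply(1:3, function(k)
        runif(n_out, bb[1, k] - pad[k], bb[2, k] + pad[k]))
      out_pts <- matrix(out_pts, n_out, 3)
      pts <- rbind(pts, out_pts)
      lab <- c(lab, rep(NA_integer_, n_out))
    }
    res <- labeled_point_set(pts, labels = lab,
                             visible = rep(TRUE, nrow(pts)),
                             n_segments = ps$n_segments)
    attr(res, "n_outliers") <- n_out
    res
  })
}

# Exact visibility by z-buffer rasterisation with the camera intrinsics:
# a point is visible iff it is the nearest point mapping to its pixel.
zbuffer_visible <- function(points, camera, upscale = 1) {
  rel <- sweep(points, 2L, camera$position)
  depth <- -rel[, 3]  # camera looks down -z
  if (any(depth <= 0)) stop("all points must be in front of the camera")
  u <- round(camera$fx * upscale * rel[, 1] / depth + camera$cx * upscale)
  v <- round(camera$fy * upscale * rel[, 2] / depth + camera$cy * upscale)
  key <- paste(u, v)
  best <- tapply(depth, key, min)
  depth <= best[key] + 1e-12
}

#' Motion script for the sequence generator
#'
#' Canned whole-body motions with per-frame joint rotation targets:
#' `arm-wave` (both arms swing in the frontal plane), `walk-in-place`
#' (alternating hip/knee flexion), `turn-90` (the body yaws 90 degrees away
#' from the camera, occluding an arm: the vanished-segment case), and
#' `high-kick` (a fast leg raise with torso lean causing heavy
#' self-occlusion: the many-invalid-segments case).
#'
#' @param name one of `"arm-wave"`, `"walk-in-place"`, `"turn-90"`,
#'   `"high-kick"`.
#' @param frames number of frames.
#' @param sigma_n depth noise sd (meters); default 2 mm, typical of a
#'   time-of-flight sensor.
#' @param outlier_frac outlier fraction per frame (default 0.02).
#' @param amplitude peak rotation amplitude in radians (used by the
#'   oscillatory scripts).
#' @return Object of class `motion_script`: fields `name`, `frames`,
#'   `sigma_n`, `outlier_frac` and `rotations_at(t)` giving the per-segment
#'   rotation list of frame t.
#' @export
motion_script <- function(name = c("arm-wave", "walk-in-place", "turn-90",
                                   "high-kick"),
                          frames = 20, sigma_n = 0.002, outlier_frac = 0.02,
                          amplitude = 45 * pi / 180) {
  name <- match.arg(name)
  stopifnot(frames >= 1, outlier_frac >= 0, outlier_frac < 1)
  rotations_at <- switch(name,
    "arm-wave" = function(t) {
      # swing arms in the frontal (x-y) plane, opposite phases
      a <- amplitude * sin(2 * pi * (t - 1) / frames)
      list(NULL, NULL,
           rot_axis_angle(c(0, 0, 1), a),        # l upper arm
           rot_axis_angle(c(0, 0, 1), 0.5 * a),  # l lower arm
           rot_axis_angle(c(0, 0, 1), -a),       # r upper arm
           rot_axis_angle(c(0, 0, 1), -0.5 * a))
    },
    "walk-in-place" = function(t) {
      a <- amplitude * 0.7 * sin(2 * pi * (t - 1) / frames)
      rl <- vector("list", 10)
      rl[[7]] <- rot_axis_angle(c(1, 0, 0), a)    # l upper leg
      rl[[8]] <- rot_axis_angle(c(1, 0, 0), -abs(a) * 0.8)
      rl[[9]] <- rot_axis_angle(c(1, 0, 0), -a)   # r upper leg
      rl[[10]] <- rot_axis_angle(c(1, 0, 0), -abs(a) * 0.8)
      rl
    },
    "turn-90" = function(t) {
      yaw <- (pi / 2) * (t - 1) / max(1, frames - 1)
      rl <- vector("list", 10)
      rl[[1]] <- rot_axis_angle(c(0, 1, 0), yaw)  # root yaw: view change
      rl
    },
    "high-kick" = function(t) {
      # fast right-leg kick peaking mid-sequence, with torso lean
      s <- sin(pi * (t - 1) / max(1, frames - 1))
      rl <- vector("list", 10)
      rl[[1]] <- rot_axis_angle(c(1, 0, 0), -0.25 * s)
      rl[[9]] <- rot_axis_angle(c(1, 0, 0), -1.9 * s)   # r upper leg kick
      rl[[10]] <- rot_axis_angle(c(1, 0, 0), 0.6 * s)
      rl
    })
  structure(list(name = name, frames = as.integer(frames), sigma_n = sigma_n,
                 outlier_frac = outlier_frac, amplitude = amplitude,
                 rotations_at = rotations_at),
            class = "motion_script")
}

#' Generate a synthetic motion sequence with ground truth
#'
#' Poses the body per the script frame by frame. In `"depth"` mode each
#' frame is rendered to a single-view cloud (visibility + noise +
#' outliers); in `"full"` mode the complete posed body is returned
#' (laser-scan style). Ground-truth joints and poses are bundled.
#'
#' @param body a `subject_model` from [generate_body()].
#' @param script a [motion_script()].
#' @param camera a [camera_model()]; default looks at the body front from
#'   2.6 m.
#' @param seed RNG seed (per-frame seeds are derived deterministically).
#' @param mode `"depth"` or `"full"`.
#' @return List of class `synthetic_sequence`: `frames` (list of
#'   `labeled_point_set`), `truth` (list with `joints`, `poses`, `posed`),
#'   `camera`, `script`.
#' @export
generate_sequence <- function(body, script, camera = NULL, seed = 1,
                              mode = c("depth", "full")) {
  mode <- match.arg(mode)
  if (is.null(camera))
    camera <- camera_model(position = c(0, 0.95 * body$skeleton$joint_positions[2, 2], 2.6))
  frames <- vector("list", script$frames)
  joints <- vector("list", script$frames)
  poses <- vector("list", script$frames)
  posed_pts <- vector("list", script$frames)
  for (t in seq_len(script$frames)) {
    pb <- pose_body(body, script$rotations_at(t))
    joints[[t]] <- pb$joints
    poses[[t]] <- pb$pose
    posed_pts[[t]] <- pb$points
    frames[[t]] <- if (mode == "depth") {
      render_depth_frame(pb$points, camera, sigma_n = script$sigma_n,
                         outlier_frac = script$outlier_frac,
                         seed = seed * 1000L + t)
    } else pb$points
  }
  structure(list(frames = frames,
                 truth = list(joints = joints, poses = poses,
                              posed = posed_pts),
                 camera = camera, script = script, mode = mode),
            class = "synthetic_sequence")
}

#' @export
print.synthetic_sequence <- function(x, ...) {
  cat(sprintf("Synthetic %s sequence '%s': %d frames, %d-point body\n",
              x$mode, x$script$name, length(x$frames),
              nrow(x$truth$posed[[1]]$points)))
  invisible(x)
}
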