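test_that("body generation is deterministic and area-proportional", {
  spec <- body_spec(density = 250)
  b1 <- generate_body(spec, seed = 42)
  b2 <- generate_body(spec, seed = 42)
  expect_identical(b1$points$points, b2$points$points)
  expect_identical(b1$points$labels, b2$points$labels)
  b3 <- generate_body(spec, seed = 43)
  expect_false(identical(b1$points$points, b3$points$points))

  # per-segment counts track surface area within 10%
  counts <- tabulate(b1$points$labels + 1L, 10)
  skel <- b1$skeleton
  r <- c(0.14, 0.10, 0.05, 0.04, 0.05, 0.04, 0.06, 0.05, 0.06, 0.05)
  caps <- c(0, 1, 0, 1, 0, 1, 0, 1, 0, 1)   # free-end caps per segment
  areas <- vapply(1:10, function(p) {
    sj <- skel$segment_joint[p, ] + 1L
    L <- sqrt(sum((skel$joint_positions[sj[1], ] -
                     skel$joint_positions[sj[2], ])^2))
    2 * pi * r[p] * L + caps[p] * 2 * pi * r[p]^2
  }, numeric(1))
  expect_true(all(abs(counts - 250 * areas) <= 0.1 * 250 * areas + 1))

  # every point lies within 1.2 x its segment radius of the bone
  for (p in 1:10) {
    pts <- b1$points$points[b1$points$labels == p - 1L, , drop = FALSE]
    sj <- skel$segment_joint[p, ] + 1L
    a <- skel$joint_positions[sj[1], ]; b <- skel$joint_positions[sj[2], ]
    u <- (b - a) / sqrt(sum((b - a)^2))
    rel <- sweep(pts, 2, a)
    t_ <- pmin(pmax(rel %*% u, 0), sqrt(sum((b - a)^2)))
    d <- sqrt(rowSums((rel - outer(as.numeric(t_), u))^2))
    expect_true(all(d <= 1.2 * r[p] + 1e-9))
  }
  expect_error(generate_body(body_spec(density = 10)), "fewer than 20")
})

test_that("posing is rigid per segment with exact ground truth", {
  body <- generate_body(body_spec(density = 250), seed = 1)
  z <- pose_body(body, list())
  expect_equal(z$points$points, body$points$points)
  expect_equal(z$joints, unname(body$skeleton$joint_positions),
               ignore_attr = TRUE)
  # 90-degree shoulder rotation: wrist stays an arm's length from the
  # shoulder (chord geometry) and bone lengths are conserved exactly
  pb <- pose_body(body, list(NULL, NULL, rot_axis_angle(c(0, 0, 1), pi / 2)))
  shoulder <- body$skeleton$joint_positions[4, ]
  wrist0 <- body$skeleton$joint_positions[6, ]
  wrist1 <- pb$joints[6, ]
  arm_len <- sqrt(sum((wrist0 - shoulder)^2))
  expect_equal(sqrt(sum((wrist1 - shoulder)^2)), arm_len, tolerance = 1e-9)
  expect_equal(sqrt(sum((wrist1 - wrist0)^2)), sqrt(2) * arm_len,
               tolerance = 1e-9)
  posed_bl <- vapply(1:10, function(p) {
    sj <- body$skeleton$segment_joint[p, ] + 1L
    sqrt(sum((pb$joints[sj[1], ] - pb$joints[sj[2], ])^2))
  }, numeric(1))
  expect_equal(posed_bl, bone_lengths(body$skeleton), tolerance = 1e-12)
})

test_that("depth rendering subsets, perturbs and contaminates as asked", {
  body <- generate_body(body_spec(density = 250), seed = 1)
  cam <- camera_model(position = c(0, 1.1, 2.6))
  pb <- pose_body(body, list())
  clean <- render_depth_frame(pb$points, cam, sigma_n = 0, outlier_frac = 0,
                              seed = 5)
  # noiseless, outlier-free frames are subsets of the posed body
  d2 <- cross_dist2_test(clean$points, pb$points$points)
  expect_lt(max(apply(d2, 1, min)), 1e-12)
  expect_identical(attr(clean, "n_outliers"), 0)

  dirty <- render_depth_frame(pb$points, cam, sigma_n = 0.003,
                              outlier_frac = 0.1, seed = 5)
  n_vis <- nrow(dirty$points) - attr(dirty, "n_outliers")
  expect_identical(attr(dirty, "n_outliers"), round(0.1 * n_vis))
  expect_true(anyNA(dirty$labels))

  # frontal camera hides the back of the torso (z-buffer oracle with the
  # pixel pitch matched to the sampling density, so pixels see one point)
  zcam <- camera_model(position = c(0, 1.1, 2.6), fx = 25, fy = 25)
  zb <- render_depth_frame(pb$points, zcam, method = "zbuffer", seed = 5)
  back_torso <- which(body$points$labels == 0L & body$points$points[, 3] < -0.1)
  kept <- sum(apply(cross_dist2_test(pb$points$points[back_torso, , drop = FALSE],
                                     zb$points), 1, min) < 1e-12)
  expect_lt(kept / length(back_torso), 0.05)
  expect_error(render_depth_frame(pb$points,
                                  camera_model(position = c(0, 1, 0))),
               "inside")
})

test_that("sequences are reproducible with script-determined length", {
  body <- generate_body(body_spec(density = 250), seed = 1)
  sc <- motion_script("arm-wave", frames = 6, sigma_n = 0.002,
                      outlier_frac = 0.05)
  s1 <- generate_sequence(body, sc, seed = 3)
  s2 <- generate_sequence(body, sc, seed = 3)
  expect_identical(lapply(s1$frames, `[[`, "points"),
                   lapply(s2$frames, `[[`, "points"))
  expect_length(s1$frames, 6)
  expect_length(s1$truth$joints, 6)
  # ground-truth joints equal forward kinematics of the script's rotations
  for (t in c(1, 4)) {
    pose <- pose_from_rotations(body$skeleton, sc$rotations_at(t))
    expect_equal(s1$truth$joints[[t]], posed_joints(pose, body$skeleton),
                 tolerance = 1e-12)
  }
})

test_that("the turn-away script induces the vanished-arm precondition", {
  body <- generate_body(body_spec(density = 250), seed = 1)
  sc <- motion_script("turn-90", frames = 8)
  sq <- generate_sequence(body, sc, seed = 2)
  tpl_counts <- tabulate(body$points$labels + 1L, 10)
  frac <- vapply(sq$frames, function(fr) {
    tab <- tabulate(fr$labels[!is.na(fr$labels)] + 1L, 10)
    tab / tpl_counts
  }, numeric(10))
  # some frame leaves an arm segment with under a quarter of its points
  expect_lt(min(frac[3:6, ]), 0.25)
})
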