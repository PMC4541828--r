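test_that("rigid Procrustes recovers a constructed transform", {
  S <- small_cloud(20, 31)
  expect_lt(max(abs(rigid_fit(S, S)$R - diag(3))), 1e-10)
  R <- rot_axis_angle(c(0.3, 1, -0.5), 1.1); tr <- c(0.2, -1, 0.4)
  T_ <- sweep(S %*% t(R), 2, tr, "+")
  fit <- rigid_fit(S, T_)
  expect_equal(fit$R, R, tolerance = 1e-8)
  expect_equal(fit$t, tr, tolerance = 1e-8)
  # reflected target still yields a proper rotation
  refl <- S %*% diag(c(-1, 1, 1))
  expect_equal(det(rigid_fit(S, refl)$R), 1, tolerance = 1e-9)
  # under 3 points: translation-only with a warning record
  f2 <- rigid_fit(S[1:2, ], T_[1:2, ])
  expect_equal(f2$R, diag(3))
  expect_match(attr(f2, "warning"), "translation-only")
})

test_that("local ICP recovers a known single-segment rotation exactly", {
  body <- generate_body(body_spec(density = 250), seed = 6)
  R <- rot_axis_angle(c(0, 0, 1), 35 * pi / 180)
  pb <- pose_body(body, list(NULL, NULL, R))
  tgt <- pb$points
  local <- lapply(1:10, function(p) rigid_transform())
  res <- local_icp(2L, body, local, tgt, saicp_config(),
                   correspondences = seq_len(nrow(tgt$points)))
  expect_equal(res$local[[3]]$R, R, tolerance = 1e-8)
  # identity case: target is the template itself
  res0 <- local_icp(2L, body, local, body$points, saicp_config())
  expect_lt(max(abs(res0$local[[3]]$R - diag(3))), 1e-8)
  # no target points with the part's labels: unconstrained, unchanged
  no_arm <- subset_points(tgt, which(!(tgt$labels %in% c(2L, 3L))))
  resu <- local_icp(2L, body, local, no_arm, saicp_config())
  expect_true(resu$unconstrained)
  expect_equal(resu$local[[3]]$R, diag(3))
})

test_that("articulated fit recovers multi-joint poses from exact correspondences", {
  body <- generate_body(body_spec(density = 250), seed = 6)
  rot <- list(rot_axis_angle(c(0, 1, 0), 20 * pi / 180), NULL,
              rot_axis_angle(c(0, 0, 1), 40 * pi / 180),
              rot_axis_angle(c(0, 0, 1), 25 * pi / 180),
              rot_axis_angle(c(0, 0, 1), -35 * pi / 180),
              rot_axis_angle(c(0, 0, 1), -15 * pi / 180),
              rot_axis_angle(c(1, 0, 0), 30 * pi / 180),
              rot_axis_angle(c(1, 0, 0), -20 * pi / 180),
              rot_axis_angle(c(1, 0, 0), -30 * pi / 180), NULL)
  pb <- pose_body(body, rot)
  fit <- saicp(body, pb$points,
               correspondences = seq_len(nrow(pb$points$points)))
  rmse <- sqrt(mean(rowSums((fit$joints - pb$joints)^2)))
  height <- diff(range(body$points$points[, 2]))
  expect_lt(rmse, 1e-6 * height)
  # bone lengths conserved exactly by the rigid per-segment maps
  posed_skel <- fit$deformed$skeleton
  expect_equal(bone_lengths(posed_skel), bone_lengths(body$skeleton),
               tolerance = 1e-9)
})

test_that("zero articulation returns identity transforms", {
  body <- generate_body(body_spec(density = 250), seed = 2)
  fit <- saicp(body, body$points)
  for (p in 1:10) {
    expect_lt(max(abs(fit$pose$local[[p]]$R - diag(3))), 1e-8)
    expect_lt(max(abs(fit$pose$local[[p]]$t)), 1e-8)
  }
})

test_that("pose refinement does not worsen the GLTP-initialised residual", {
  body <- generate_body(body_spec(density = 250), seed = 12)
  rot <- list(NULL, NULL, rot_axis_angle(c(0, 0, 1), 35 * pi / 180),
              rot_axis_angle(c(0, 0, 1), 15 * pi / 180))
  pb <- pose_body(body, rot)
  # sensor-level noise: exactly coincident clouds are degenerate for a GMM
  set.seed(99)
  pb$points$points <- pb$points$points +
    matrix(rnorm(length(pb$points$points), 0, 0.002), ncol = 3)
  gfit <- gltp(body$points, pb$points, gltp_config(max_iter = 60))
  lab <- propagate_labels(gfit$P, body$points$labels)
  Xhat <- labeled_point_set(pb$points$points, labels = lab, n_segments = 10)
  # residual of the GLTP-initialised pose (identity articulation)
  before <- mean(sqrt(apply(cross_dist2_test(body$points$points,
                                             pb$points$points), 1, min)))
  fit <- saicp(body, Xhat, correspondences = gfit$P)
  expect_lte(fit$residual, before)
  # determinism: identical inputs give identical outputs
  fit2 <- saicp(body, Xhat, correspondences = gfit$P)
  expect_identical(fit$joints, fit2$joints)
})

test_that("temporal clamp limits per-joint rotation change", {
  body <- generate_body(body_spec(density = 250), seed = 2)
  prev <- identity_pose(body$skeleton)
  # unchanged pose passes through untouched
  same <- enforce_constraints(identity_pose(body$skeleton), prev, body,
                              saicp_config())
  for (p in 1:10)
    expect_lt(max(abs(same$local[[p]]$R - diag(3))), 1e-12)
  # a 90-degree jump is clamped to the 30-degree step
  jump <- pose_from_rotations(body$skeleton,
                              list(NULL, NULL,
                                   rot_axis_angle(c(0, 0, 1), pi / 2)))
  clamped <- enforce_constraints(jump, prev, body, saicp_config())
  ang <- rotation_angle(clamped$local[[3]]$R)
  expect_lte(ang, 30 * pi / 180 + 1e-9)
  expect_equal(ang, 30 * pi / 180, tolerance = 1e-6)
})

test_that("overlap constraint backs an interpenetrating limb off", {
  body <- generate_body(body_spec(density = 250), seed = 2)
  prev <- identity_pose(body$skeleton)
  # swing the right leg into the left leg's volume (non-adjacent overlap)
  bad <- pose_from_rotations(body$skeleton,
                             list(NULL, NULL, NULL, NULL, NULL, NULL,
                                  NULL, NULL,
                                  rot_axis_angle(c(0, 0, 1), 28 * pi / 180)))
  cfg <- saicp_config(overlap_constraint = TRUE, max_joint_step = pi)
  fixed <- enforce_constraints(bad, prev, body, cfg)
  halv <- attr(fixed, "halvings")
  posed <- labeled_point_set(
    artreg_pose_points_test(body, fixed$world), labels = body$points$labels,
    n_segments = 10)
  m1 <- m1_overlap(posed$points, posed$labels, 10)
  # either the overlap fell below the bound or 5 halvings were logged
  expect_true(max(m1[c(7, 9, 8, 10)], na.rm = TRUE) <= 0.3 || halv == 5L)
  expect_gte(halv, 1L)
})
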