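test_that("joint error averages offset-corrected distances", {
  set.seed(3)
  Nf <- 4; Nj <- 5
  M <- array(rnorm(Nf * Nj * 3), c(Nf, Nj, 3))
  O <- matrix(rnorm(Nj * 3, sd = 0.1), Nj, 3)
  J <- M + aperm(array(O, c(Nj, 3, Nf)), c(3, 1, 2))
  expect_equal(joint_error(J, M, O), 0)
  # one displaced entry contributes 1/(Nf*Nj) of its size
  J2 <- J
  J2[2, 3, 1] <- J2[2, 3, 1] + 1
  expect_equal(joint_error(J2, M, O), 1 / (Nf * Nj))
  # common translation of J and M cancels
  Jt <- J2 + 0.7; Mt <- M + 0.7
  expect_equal(joint_error(Jt, Mt, O), joint_error(J2, M, O))
  expect_error(joint_error(J, M[, 1:3, ], O), "shape")
})

test_that("offset calibration recovers axial offsets and drops transverse ones", {
  body <- generate_body(body_spec(density = 250), seed = 1)
  skel <- body$skeleton
  Nf <- 25
  J <- array(0, c(Nf, 15, 3))
  for (k in seq_len(Nf)) J[k, , ] <- skel$joint_positions
  expect_equal(calibrate_offsets(J, J, skeleton = skel),
               matrix(0, 15, 3), ignore_attr = TRUE)
  # markers displaced along the bone: the offset's norm is recovered
  axes <- artreg:::joint_bone_axes(J, 1:20, skel)
  d <- 0.03
  O_true <- t(apply(axes, 1, function(a)
    if (sum(a^2) == 0) c(0, 0, 0) else d * a / sqrt(sum(a^2))))
  M <- J - aperm(array(O_true, c(15, 3, Nf)), c(3, 1, 2))
  O_hat <- calibrate_offsets(J, M, skeleton = skel)
  nonzero <- rowSums(axes^2) > 0
  expect_equal(sqrt(rowSums(O_hat[nonzero, ]^2)),
               rep(d, sum(nonzero)), tolerance = 1e-9)
  # purely transverse displacement projects to ~0
  trans <- t(apply(axes, 1, function(a) {
    if (sum(a^2) == 0) return(c(0, 0, 0))
    v <- c(-a[2], a[1], 0)
    if (sum(v^2) < 1e-12) v <- c(0, -a[3], a[2])
    0.05 * v / sqrt(sum(v^2))
  }))
  Mt <- J - aperm(array(trans, c(15, 3, Nf)), c(3, 1, 2))
  O_t <- calibrate_offsets(J, Mt, skeleton = skel)
  expect_lt(max(abs(O_t[nonzero, ])), 1e-9)
})

test_that("labeling accuracy is the exact-match fraction over labeled points", {
  expect_equal(labeling_accuracy(c(0L, 1L, 2L), c(0L, 1L, 2L)), 1)
  expect_equal(labeling_accuracy(c(0L, 1L, 1L, 0L), c(0L, 1L, 0L, 1L)), 0.5)
  set.seed(8)
  a <- sample(0:9, 1000, replace = TRUE)
  b <- sample(0:9, 1000, replace = TRUE)
  b[sample(1000, 50)] <- NA
  n_ok <- 0; n_tot <- 0
  for (i in 1:1000) {
    if (!is.na(a[i]) && !is.na(b[i])) {
      n_tot <- n_tot + 1
      if (a[i] == b[i]) n_ok <- n_ok + 1
    }
  }
  expect_equal(labeling_accuracy(a, b), n_ok / n_tot)
})

test_that("LLE joint reconstruction is exact, equivariant and articulate", {
  body <- generate_body(body_spec(density = 250), seed = 5)
  jp <- body$skeleton$joint_positions
  # reference reproduces itself
  rec <- lle_ground_truth_joints(body$points, jp, body$points$points,
                                 body$skeleton)
  expect_lt(max(sqrt(rowSums((rec - jp)^2))), 1e-10)
  # rigid motion of the body moves the joints rigidly
  tf <- rigid_transform(rot_axis_angle(c(1, 0.5, 0), 0.8), c(0.5, -0.3, 1))
  rec_r <- lle_ground_truth_joints(body$points, jp,
                                   apply_rigid(body$points, tf)$points,
                                   body$skeleton)
  expect_lt(max(sqrt(rowSums((rec_r - apply_rigid(jp, tf))^2))), 1e-9)
  # 30-degree elbow bend: reconstructed elbow near the kinematic truth
  pb <- pose_body(body, list(NULL, NULL, NULL,
                             rot_axis_angle(c(0, 0, 1), 30 * pi / 180)))
  rec_b <- lle_ground_truth_joints(body$points, jp, pb$points$points,
                                   body$skeleton)
  height <- diff(range(body$points$points[, 2]))
  expect_lt(sqrt(sum((rec_b[5, ] - pb$joints[5, ])^2)), 0.02 * height)
})

test_that("depth pre-processing thresholds, denoises and prunes outliers", {
  cam <- camera_model(fx = 100, fy = 100, cx = 16, cy = 12,
                      width = 32, height = 24)
  # everything beyond the far threshold: flagged empty
  far <- matrix(6000, 24, 32)
  out <- preprocess_depth(far, cam, near = 0.5, far = 4)
  expect_true(attr(out, "empty"))
  expect_equal(nrow(out$points), 0)

  # a flat noisy patch plus one isolated far-off pixel
  set.seed(4)
  img <- matrix(0, 24, 32)
  img[8:16, 8:24] <- 2000 + rnorm(9 * 17, sd = 8)
  img[2, 2] <- 2000          # isolated: no neighbour within d_max
  res <- preprocess_depth(img, cam, near = 0.5, far = 4, d_max = 0.1,
                          lop_iter = 0)
  # the isolated back-projected point is removed
  expect_equal(nrow(res$points), 9 * 17)
  # denoising shrinks the depth spread of the patch
  res_l <- preprocess_depth(img, cam, near = 0.5, far = 4, d_max = 0.1,
                            lop_iter = 3)
  raw <- preprocess_depth(img, cam, near = 0.5, far = 4, d_max = 0.1,
                          lop_iter = 0)
  expect_lte(sd(res_l$points[, 3]), sd(raw$points[, 3]))
  # stage counts never increase
  sc <- attr(res_l, "stage_counts")
  expect_true(all(diff(sc) <= 0))
})
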