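test_that("OBB fitting recovers a rotated box volume", {
  corners <- as.matrix(expand.grid(c(-1, 1), c(-0.5, 0.5), c(-0.25, 0.25)))
  R <- rot_axis_angle(c(1, 2, 0.5), 0.7)
  pts <- sweep(corners %*% t(R), 2, c(3, -1, 2), "+")
  box <- fit_obb(pts)
  expect_equal(box$volume, 1.0, tolerance = 0.02)
  expect_true(all(points_in_obb(pts, box)))
  # orthonormal axes
  expect_equal(crossprod(box$axes), diag(3), tolerance = 1e-8)
  # volume is rigid-motion invariant within the grid refinement slack
  box2 <- fit_obb(corners)
  expect_equal(box$volume, box2$volume, tolerance = 0.02)
})

test_that("degenerate point sets get floor extents but stay enclosing", {
  line <- cbind(seq(0, 1, length.out = 7), 0, 0)
  box <- fit_obb(line)
  expect_equal(sort(box$half_extents)[1:2], rep(1e-6, 2))
  expect_true(all(points_in_obb(line, box)))
  one <- matrix(c(1, 2, 3), 1, 3)
  expect_true(points_in_obb(one, fit_obb(one)))
})

test_that("segment overlap metric counts shared box membership", {
  set.seed(1)
  A <- matrix(rnorm(90, sd = 0.2), 30, 3)
  B <- sweep(matrix(rnorm(90, sd = 0.2), 30, 3), 2, c(10, 0, 0), "+")
  pts <- rbind(A, B)
  lab <- rep(0:1, each = 30)
  expect_equal(m1_overlap(pts, lab, 2), c(0, 0))          # well separated
  dup <- rbind(A, A)
  expect_equal(m1_overlap(dup, lab, 2), c(1, 1))          # coincident
  # exactly half of segment 0 inside segment 1's box
  inb <- sweep(matrix(runif(45, -0.1, 0.1), 15, 3), 2, c(10, 0, 0), "+")
  outb <- matrix(runif(45, -0.1, 0.1), 15, 3)
  pts3 <- rbind(inb, outb, B)
  expect_equal(m1_overlap(pts3, lab, 2)[1], 0.5)
  expect_true(all(m1_overlap(pts3, lab, 2) >= 0 &
                    m1_overlap(pts3, lab, 2) <= 1))
})

test_that("volume deformation metric scales as volume (or torso height)", {
  set.seed(2)
  seg <- matrix(rnorm(150, sd = 0.3), 50, 3)
  expect_equal(m2_deformation(seg, seg), 1.0)
  expect_equal(m2_deformation(seg * 2, seg), 8.0, tolerance = 0.05 * 8)
  torso <- cbind(rnorm(60, sd = 0.05), runif(60, 0, 1), rnorm(60, sd = 0.05))
  stretched <- torso %*% diag(c(1, 1.5, 1))
  expect_equal(m2_deformation(stretched, torso, is_torso = TRUE), 1.5,
               tolerance = 0.05 * 1.5)
  expect_true(is.na(m2_deformation(matrix(0, 0, 3), seg)))
})

test_that("the validator classifies clean, vanished and corrupted frames", {
  body <- generate_body(body_spec(density = 250), seed = 4)
  # clean full scan with exact labels passes
  rep0 <- validate_segments(body$points, body)
  expect_identical(rep0$case, "PASS")
  expect_true(all(rep0$M1 >= 0 & rep0$M1 <= 1))
  expect_true(all(rep0$M2 > 0))

  # vanished arm: its points deleted, labels dragged onto nearby torso points
  lab <- body$points$labels
  arm <- which(lab %in% c(2L, 3L))
  keep <- setdiff(seq_along(lab), arm)
  pts <- body$points$points[keep, , drop = FALSE]
  lab2 <- lab[keep]
  torso_pts <- which(lab2 == 0L)
  # GLTP would drag the vanished arm's labels onto the nearest remaining
  # structure: relabel the torso points closest to the old shoulder
  d <- sqrt(rowSums(sweep(pts[torso_pts, , drop = FALSE], 2,
                          body$skeleton$joint_positions[4, ])^2))
  grab <- torso_pts[order(d)][1:25]
  lab2[grab[1:13]] <- 2L
  lab2[grab[14:25]] <- 3L
  rep1 <- validate_segments(labeled_point_set(pts, labels = lab2,
                                              n_segments = 10), body)
  expect_true(rep1$case %in% c("CASE_I", "CASE_II"))
  expect_true(any(rep1$fail_m1[c(3, 4)] | rep1$fail_count[c(3, 4)]))

  # most segments shuffled: the massive-occlusion case
  set.seed(9)
  lab3 <- lab
  shuffle <- which(lab %in% c(1L, 2L, 3L, 4L, 6L, 8L))
  lab3[shuffle] <- sample(0:9, length(shuffle), replace = TRUE)
  rep3 <- validate_segments(labeled_point_set(body$points$points,
                                              labels = lab3,
                                              n_segments = 10), body)
  expect_identical(rep3$case, "CASE_III")
})

test_that("remedies map failure cases to the prescribed actions", {
  rep <- structure(list(case = "CASE_I", invisible_segments = c(2L, 3L)),
                   class = "validation_report")
  act <- remedy(rep)
  expect_identical(act$action, "RERUN_GLTP_WITHOUT_SEGMENTS")
  expect_identical(act$segments, c(2L, 3L))
  rep$case <- "CASE_II"
  expect_identical(remedy(rep)$action, "RERUN_GLTP_TPOSE")
  rep$case <- "CASE_III"
  expect_identical(remedy(rep)$action, "CONSTRAINED_SAICP_ONLY")
  rep$case <- "PASS"
  expect_identical(remedy(rep)$action, "NONE")
})
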