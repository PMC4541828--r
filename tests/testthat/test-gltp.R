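test_that("Gaussian kernel matches its closed form", {
  expect_equal(gaussian_kernel(matrix(c(1, 2, 3), 1, 3), 1)$G,
               matrix(1, 1, 1))
  dup <- rbind(c(0, 0, 0), c(0, 0, 0))
  expect_equal(gaussian_kernel(dup, 0.5)$G, matrix(1, 2, 2))
  two <- rbind(c(0, 0, 0), c(2, 0, 0))
  G <- gaussian_kernel(two, 2)$G
  expect_equal(G[1, 2], exp(-0.5))
  expect_equal(G, t(G))
  expect_true(all(diag(G) == 1))
  expect_error(gaussian_kernel(two, 0), "beta")
})

test_that("LLE weights minimise constrained reconstruction error", {
  Y <- small_cloud(8, 2)
  w1 <- lle_weights(Y, 1)
  expect_equal(as.numeric(w1$L), rep(1, 8))
  # midpoint of two collinear neighbours gets (1/2, 1/2)
  line <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  wm <- lle_weights(line, 2)
  expect_equal(as.numeric(wm$L[2, ]), c(0.5, 0.5), tolerance = 1e-9)
  # rows sum to one; no self-neighbours
  w3 <- lle_weights(small_cloud(10, 3), 3)
  expect_equal(rowSums(w3$L), rep(1, 10), tolerance = 1e-8)
  expect_true(all(w3$neighbor_index != matrix(1:10, 10, 3)))
  # grid-search oracle: no weight vector on the constraint plane beats the
  # solved one by more than the conditioning allowance
  Y10 <- small_cloud(10, 7)
  fit <- lle_weights(Y10, 3)
  grid <- seq(-1, 2, by = 0.05)
  for (m in c(1, 5, 9)) {
    nb <- Y10[fit$neighbor_index[m, ], ]
    err <- function(w) sum((Y10[m, ] - colSums(nb * w))^2)
    e_fit <- err(fit$L[m, ])
    e_best <- Inf
    for (w1 in grid) for (w2 in grid) {
      e <- err(c(w1, w2, 1 - w1 - w2))
      if (e < e_best) e_best <- e
    }
    expect_lt(e_fit, e_best + 1e-3)
  }
  expect_error(lle_weights(small_cloud(5, 1), 5), "smaller")
})

test_that("initial variance follows the mean squared cross distance", {
  p <- matrix(c(0.3, -1, 2), 1, 3)
  expect_equal(init_sigma2(p, p), 0)
  expect_equal(init_sigma2(matrix(0, 1, 3), matrix(c(1, 0, 0), 1, 3)), 1 / 3)
  Y <- small_cloud(6, 1); X <- small_cloud(9, 2)
  R <- rot_axis_angle(c(1, 2, 3), 0.8)
  expect_equal(init_sigma2(Y %*% t(R), X %*% t(R)), init_sigma2(Y, X),
               tolerance = 1e-12)
  expect_error(init_sigma2(matrix(0, 0, 3), X), "non-empty")
})

test_that("E-step posteriors normalise and concentrate correctly", {
  # two equidistant template points, no outlier mass: 0.5 each
  T2 <- rbind(c(-1, 0, 0), c(1, 0, 0))
  X1 <- matrix(c(0, 0.5, 0), 1, 3)
  P <- e_step(T2, X1, sigma2 = 0.7, omega = 0)
  expect_equal(as.numeric(P$P), c(0.5, 0.5))
  # omega = 0: every column sums to exactly 1
  T5 <- small_cloud(5, 4); X7 <- small_cloud(7, 5)
  P0 <- e_step(T5, X7, sigma2 = 0.3, omega = 0)
  expect_equal(colSums(P0$P), rep(1, 7), tolerance = 1e-12)
  # coincident point at tiny variance dominates its column despite omega
  Tsp <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 3, 0), c(0, 0, 3), c(3, 3, 0))
  Pc <- e_step(Tsp, matrix(c(3, 0, 0), 1, 3), sigma2 = 1e-6, omega = 0.1)
  expect_gte(Pc$P[2, 1], 0.99)
  # column sums never exceed 1
  Pw <- e_step(T5, X7, sigma2 = 0.3, omega = 0.4)
  expect_true(all(colSums(Pw$P) <= 1 + 1e-12))
  expect_error(e_step(T5, X7, sigma2 = 0.3, omega = 1), "omega")
})

test_that("M-step solution is a fixed point and a stationary minimum", {
  Y <- small_cloud(8, 6)
  # X = Y with identity correspondences and lambda = 0: W = 0 exactly
  W0 <- gltp_solve_w(diag(8), Y, Y, gaussian_kernel(Y, 2)$G,
                     alpha = 10, lambda = 0, sigma2 = 0.5)
  expect_equal(W0, matrix(0, 8, 3), tolerance = 1e-12)
  # first-order optimality: perturbing the solved W never lowers the
  # objective on a random fixture
  X <- small_cloud(10, 7)
  G <- gaussian_kernel(Y, 2)$G
  lle <- lle_weights(Y, 3)
  P <- e_step(Y, X, sigma2 = 1, omega = 0.1)$P
  s2 <- 0.8; al <- 2; lam <- 5
  W <- gltp_solve_w(P, Y, X, G, lle$M_mat, al, lam, s2)
  Q0 <- gltp_objective(W, s2, P, Y, X, G, lle$M_mat, al, lam)
  for (k in seq_len(6)) {
    dW <- matrix(0, 8, 3)
    dW[((k - 1) %% 8) + 1, ((k - 1) %% 3) + 1] <- c(1e-3, -1e-3)[(k %% 2) + 1]
    Qp <- gltp_objective(W + dW, s2, P, Y, X, G, lle$M_mat, al, lam)
    expect_gte(Qp, Q0 - 1e-12)
  }
})

test_that("objective matches a term-by-term loop computation", {
  Y <- small_cloud(6, 8); X <- small_cloud(9, 9)
  G <- gaussian_kernel(Y, 1.5)$G
  lle <- lle_weights(Y, 3)
  P <- e_step(Y, X, 0.6, 0.1)$P
  set.seed(10)
  W <- matrix(rnorm(18, sd = 0.1), 6, 3)
  got <- gltp_objective(W, 0.6, P, Y, X, G, lle$M_mat, alpha = 3, lambda = 2)
  want <- objective_loops(W, 0.6, P, Y, X, G, lle$L, lle$neighbor_index,
                          alpha = 3, lambda = 2)
  expect_equal(got, want, tolerance = 1e-10)
  # zero deformation: the displacement-form topology penalty is exactly
  # zero, and the alpha term vanishes with W = 0
  Wz <- matrix(0, 6, 3)
  on_line <- cbind(seq_len(6), 0, 0)
  lle_l <- lle_weights(on_line, 2)
  Gl <- gaussian_kernel(on_line, 2)$G
  Pz <- matrix(0, 6, 4)
  q <- gltp_objective(Wz, 1, Pz, on_line, matrix(0, 4, 3), Gl, lle_l$M_mat,
                      alpha = 7, lambda = 11, topology = "displacement")
  expect_identical(q, 0)
  # interior points of a line reconstruct exactly even in the absolute form
  q_abs <- gltp_objective(Wz, 1, Pz, on_line, matrix(0, 4, 3), Gl,
                          lle_l$M_mat, alpha = 7, lambda = 11)
  res_rows <- rowSums(((diag(6) - lle_l$Lhat) %*% on_line)^2)
  expect_lt(max(res_rows[2:5]), 1e-18)
  expect_equal(q_abs, 11 / 2 * sum(res_rows), tolerance = 1e-8)
  # alpha term alone for a basis-vector W equals alpha/2 * G[1,1]
  We <- matrix(0, 6, 3); We[1, 1] <- 1
  q2 <- gltp_objective(We, 1, Pz, Y, matrix(0, 4, 3), G, NULL,
                       alpha = 7, lambda = 0)
  expect_equal(q2, 7 / 2 * G[1, 1])
})

test_that("self-registration leaves the template almost unmoved", {
  Y <- small_cloud(40, 11)
  fit <- gltp(Y, Y, gltp_config(max_iter = 40))
  diag_len <- sqrt(sum((apply(Y, 2, max) - apply(Y, 2, min))^2))
  expect_lt(max(sqrt(rowSums((fit$TY - Y)^2))), 1e-3 * diag_len)
})

test_that("registration reduces the residual on a bent synthetic arm", {
  body <- generate_body(body_spec(density = 250), seed = 5)
  bent <- pose_body(body, list(NULL, NULL,
                               rot_axis_angle(c(0, 0, 1), 30 * pi / 180)))
  fit <- gltp(body$points, bent$points, gltp_config(max_iter = 60))
  before <- mean(sqrt(apply(cross_dist2_test(body$points$points,
                                             bent$points$points), 1, min)))
  after <- mean(residuals(fit))
  expect_lt(after, before)
})

test_that("registration is equivariant under a common rigid motion", {
  Y <- small_cloud(30, 12); X <- small_cloud(30, 13) * 0.9 + 0.05
  R <- rot_axis_angle(c(1, 1, 0), 0.6); tr <- c(0.4, -0.2, 1)
  cfg <- gltp_config(max_iter = 25)
  f1 <- gltp(Y, X, cfg)
  f2 <- gltp(sweep(Y %*% t(R), 2, tr, "+"), sweep(X %*% t(R), 2, tr, "+"),
             cfg)
  expect_equal(f2$TY, sweep(f1$TY %*% t(R), 2, tr, "+"), tolerance = 1e-6)
})

test_that("lambda = 0 run is bit-identical to the CPD wrapper", {
  Y <- small_cloud(25, 14); X <- small_cloud(28, 15)
  cfg0 <- gltp_config(lambda = 0, max_iter = 20)
  f1 <- gltp(Y, X, cfg0)
  f2 <- cpd(Y, X, gltp_config(max_iter = 20))
  expect_identical(f1$W, f2$W)
  expect_identical(f1$trace, f2$trace)
})

test_that("EM objective is non-increasing on random fixtures", {
  for (seed in 1:5) {
    Y <- small_cloud(35, seed)
    X <- small_cloud(35, seed + 100) * 0.8
    fit <- gltp(Y, X, gltp_config(max_iter = 40))
    Q <- fit$trace$Q
    expect_true(all(diff(Q) <= 1e-8 * abs(Q[-length(Q)])),
                info = paste("seed", seed))
    expect_true(all(fit$trace$sigma2 > 0 & is.finite(fit$trace$sigma2)))
    expect_true(all(colSums(fit$P$P) <= 1 + 1e-12))
  }
})

test_that("CPD removes most of a 10-degree rigid rotation", {
  body <- generate_body(body_spec(density = 250), seed = 8)
  Y <- body$points$points
  R <- rot_axis_angle(c(0, 1, 0), 10 * pi / 180)
  X <- Y %*% t(R)
  before <- mean(sqrt(apply(cross_dist2_test(Y, X), 1, min)))
  fit <- cpd(Y, X, gltp_config(max_iter = 80, tol = 1e-7))
  expect_lt(mean(residuals(fit)), 0.05 * before)
})

test_that("lambda = 0 trajectory matches the independent CPD oracle", {
  Y <- small_cloud(50, 21)
  X <- small_cloud(50, 22) * 0.9
  iters <- 10
  oracle <- cpd_oracle(Y, X, beta = 2, alpha = 10, omega = 0.1, iters = iters)
  cfg <- gltp_config(lambda = 0, max_iter = iters, tol = 0)
  fit <- gltp(Y, X, cfg)
  # same deformed template after the same number of EM iterations, and the
  # same variance trajectory
  expect_equal(fit$TY, oracle$traj[[iters]], tolerance = 1e-6)
  expect_equal(fit$trace$sigma2, oracle$sigma2[seq_len(nrow(fit$trace))],
               tolerance = 1e-6)
})
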