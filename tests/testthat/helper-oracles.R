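# Independent oracles used by the tests. These re-derive quantities by
# different routes (loops, enumeration, ray casting) and must stay
# independent of the package's implementation paths.

# --- Naive coherent point drift EM, coded from the GMM update equations with
# explicit loops (independent of gltp()). Uses the same normalisation
# convention (each set to zero mean, unit RMS) so trajectories can be
# compared; returns per-iteration deformed templates in the original frame.
cpd_oracle <- function(Y, X, beta = 2, alpha = 10, omega = 0.1,
                       iters = 20) {
  Y <- as.matrix(Y); X <- as.matrix(X)
  M <- nrow(Y); N <- nrow(X); D <- 3
  mu_y <- colMeans(Y); mu_x <- colMeans(X)
  sc_y <- sqrt(mean(rowSums(sweep(Y, 2, mu_y)^2)))
  sc_x <- sqrt(mean(rowSums(sweep(X, 2, mu_x)^2)))
  Yn <- sweep(Y, 2, mu_y) / sc_y
  Xn <- sweep(X, 2, mu_x) / sc_x
  G <- matrix(0, M, M)
  for (i in 1:M) for (j in 1:M)
    G[i, j] <- exp(-sum((Yn[i, ] - Yn[j, ])^2) / (2 * beta^2))
  s2 <- 0
  for (m in 1:M) for (n in 1:N) s2 <- s2 + sum((Xn[n, ] - Yn[m, ])^2)
  s2 <- s2 / (D * M * N)
  W <- matrix(0, M, D)
  traj <- vector("list", iters)
  sig <- numeric(iters)
  for (it in 1:iters) {
    T_y <- Yn + G %*% W
    P <- matrix(0, M, N)
    cc <- (2 * pi * s2)^(D / 2) * omega * M / ((1 - omega) * N)
    for (n in 1:N) {
      num <- numeric(M)
      for (m in 1:M) num[m] <- exp(-sum((Xn[n, ] - T_y[m, ])^2) / (2 * s2))
      P[, n] <- num / (sum(num) + cc)
    }
    dP1 <- rowSums(P)
    A <- diag(dP1) %*% G + s2 * alpha * diag(M)
    B <- P %*% Xn - diag(dP1) %*% Yn
    W <- solve(A, B)
    T_y <- Yn + G %*% W
    Np <- sum(P)
    s2new <- 0
    for (n in 1:N) s2new <- s2new + sum(P[, n]) * sum(Xn[n, ]^2)
    s2new <- s2new - 2 * sum((P %*% Xn) * T_y)
    for (m in 1:M) s2new <- s2new + dP1[m] * sum(T_y[m, ]^2)
    s2 <- max(s2new / (Np * D), 1e-12)
    traj[[it]] <- sweep(T_y * sc_x, 2, mu_x, "+")
    sig[it] <- s2
  }
  list(traj = traj, sigma2 = sig)
}

# --- Ray-cast visibility oracle: each sample point carries a tangent disk
# of radius eps oriented along its surface normal (the disks tile the
# sampled surface); a point is hidden iff the segment from the camera to it
# intersects a strictly nearer point's disk.
raycast_visible <- function(points, cam_pos, eps, normals) {
  X <- as.matrix(points)
  n <- nrow(X)
  rel <- sweep(X, 2, cam_pos)
  d <- sqrt(rowSums(rel^2))
  vis <- logical(n)
  nd_rel <- rowSums(normals * rel)       # dot(n_j, p_j - C), fixed per j
  for (i in 1:n) {
    u <- rel[i, ] / d[i]
    denom <- as.numeric(normals %*% u)   # dot(n_j, u)
    tstar <- nd_rel / denom              # ray parameter at each disk plane
    # the blocker must be genuinely nearer than the queried point (by a
    # couple of disk radii), not a same-surface neighbour
    ok <- is.finite(tstar) & tstar > 0 & tstar < d[i] * (1 - 1e-9) &
      d < d[i] - 2 * eps
    if (!any(ok)) { vis[i] <- TRUE; next }
    hit <- outer(tstar[ok], u) - rel[ok, , drop = FALSE]
    miss2 <- rowSums(hit^2)              # distance^2 from disk centre
    blockers <- which(ok)[miss2 < eps^2]
    vis[i] <- length(setdiff(blockers, i)) == 0
  }
  vis
}

# --- Term-by-term objective evaluation with explicit loops.
objective_loops <- function(W, sigma2, P, Y, X, G, L, nbr, alpha, lambda) {
  M <- nrow(Y); N <- nrow(X)
  T_y <- Y + G %*% W
  e1 <- 0
  for (m in 1:M) for (n in 1:N)
    e1 <- e1 + P[m, n] * sum((X[n, ] - T_y[m, ])^2)
  e1 <- e1 / (2 * sigma2)
  e2 <- sum(P) * 3 / 2 * log(sigma2)
  e3 <- 0
  for (i in 1:M) for (j in 1:M) e3 <- e3 + sum(W[i, ] * W[j, ]) * G[i, j]
  e3 <- alpha / 2 * e3
  e4 <- 0
  if (lambda > 0) {
    for (m in 1:M) {
      rec <- T_y[m, ]
      for (k in seq_len(ncol(L))) rec <- rec - L[m, k] * T_y[nbr[m, k], ]
      e4 <- e4 + sum(rec^2)
    }
    e4 <- lambda / 2 * e4
  }
  e1 + e2 + e3 + e4
}

# --- Small deterministic point cloud.
small_cloud <- function(n, seed = 1, spread = 1) {
  set.seed(seed)
  matrix(rnorm(3 * n, sd = spread), n, 3)
}

# --- Uniform points on a unit sphere.
sphere_cloud <- function(n, seed = 1, radius = 1) {
  set.seed(seed)
  z <- runif(n, -1, 1)
  ph <- runif(n, 0, 2 * pi)
  r <- sqrt(1 - z^2)
  radius * cbind(r * cos(ph), r * sin(ph), z)
}

# --- Squared cross-distance helper for oracle computations.
cross_dist2_test <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  d2
}

# --- Apply per-segment world transforms to a subject's points through the
# exported rigid-transform API (independent of the package's internal path).
artreg_pose_points_test <- function(subject, world) {
  pts <- subject$points$points
  lab <- subject$points$labels
  for (p in seq_len(subject$skeleton$P)) {
    idx <- which(lab == p - 1L)
    if (length(idx))
      pts[idx, ] <- apply_rigid(subject$points$points[idx, , drop = FALSE],
                                world[[p]])
  }
  pts
}

# --- Deterministic near-uniform sphere sampling (Fibonacci lattice).
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(1 - z^2)
  phi <- pi * (1 + sqrt(5)) * i
  cbind(r * cos(phi), r * sin(phi), z)
}

# --- Plain nearest-neighbour index lookup for label refinement checks.
nearest_index_test <- function(A, B) {
  max.col(-cross_dist2_test(A, B), ties.method = "first")
}
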