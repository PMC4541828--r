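#' GLTP / CPD registration configuration
#'
#' Defaults follow the method's standard settings: outlier weight
#' `omega = 0.1`, `K = 10` LLE neighbours, motion-coherence weight
#' `alpha = 10`, Gaussian kernel width `beta = 2` (in normalised units, see
#' [gltp()]), topology weight `lambda = 5e6`. `lambda = 0` reduces the model
#' to plain coherent point drift. The topology penalty is annealed
#' geometrically (`anneal_lambda = 0.75` per iteration): it guards the
#' neighbourhood structure early, when correspondences are ambiguous, and
#' relaxes as the Gaussian components sharpen.
#'
#' @param omega outlier weight in `[0, 1)`.
#' @param K number of LLE neighbours (>= 1).
#' @param alpha motion-coherence trade-off (> 0).
#' @param beta Gaussian kernel width (> 0, normalised length units).
#' @param lambda local-topology trade-off (>= 0).
#' @param max_iter maximum EM iterations.
#' @param tol relative objective-change stopping tolerance.
#' @param anneal_alpha,anneal_lambda per-iteration geometric decay factors
#'   (deterministic annealing; `anneal_lambda = 0.75` relaxes the topology
#'   penalty as the match sharpens, `1` keeps it constant).
#' @param topology form of the LLE penalty: `"displacement"` (default)
#'   penalises neighbourhood distortion of the displacement field,
#'   `||(I - Lhat) G W||^2`, and is zero for an undeformed template;
#'   `"absolute"` penalises the reconstruction residual of the deformed
#'   points themselves. The two coincide on densely sampled surfaces where
#'   the template's own LLE residual vanishes; at sparse sampling the
#'   absolute form exerts a spurious collapse pressure even at `W = 0`.
#' @param normalize centre/scale both sets before the EM (standard practice);
#'   results are always returned in the original frame.
#' @return A list of class `gltp_config`.
#' @export
gltp_config <- function(omega = 0.1, K = 10, alpha = 10, beta = 2,
                        lambda = 5e6, max_iter = 100, tol = 1e-5,
                        anneal_alpha = 1, anneal_lambda = 0.75,
                        topology = c("displacement", "absolute"),
                        normalize = TRUE) {
  topology <- match.arg(topology)
  if (omega < 0 || omega >= 1) stop("omega must be in [0, 1)")
  if (alpha <= 0 || beta <= 0) stop("alpha and beta must be > 0")
  if (lambda < 0) stop("lambda must be >= 0")
  if (K < 1) stop("K must be >= 1")
  structure(list(omega = omega, K = as.integer(K), alpha = alpha, beta = beta,
                 lambda = lambda, max_iter = as.integer(max_iter), tol = tol,
                 anneal_alpha = anneal_alpha, anneal_lambda = anneal_lambda,
                 topology = topology, normalize = isTRUE(normalize)),
            class = "gltp_config")
}

#' Read a registration configuration from YAML or JSON
#' @param path file ending in .yaml/.yml or .json.
#' @return A `gltp_config`.
#' @export
read_gltp_config <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
          else jsonlite::fromJSON(path)
  do.call(gltp_config, vals[intersect(names(vals), names(formals(gltp_config)))])
}

#' Gaussian kernel matrix of a point set
#'
#' `g_ij = exp(-0.5 * ||(y_i - y_j) / beta||^2)`: symmetric, unit diagonal,
#' entries in (0, 1].
#'
#' @param Y point set (matrix or `labeled_point_set`).
#' @param beta kernel width (> 0).
#' @return Object of class `gaussian_kernel` with elements `G` and `beta`.
#' @export
gaussian_kernel <- function(Y, beta) {
  if (beta <= 0) stop("beta must be > 0")
  Y <- pts_of(Y)
  G <- exp(-cross_dist2(Y, Y) / (2 * beta^2))
  structure(list(G = G, beta = beta), class = "gaussian_kernel")
}

#' Locally-linear-embedding reconstruction weights
#'
#' Each point is expressed as a sum-to-one weighted combination of its K
#' nearest neighbours (self excluded; neighbours ordered by distance, ties by
#' index). The local Gram matrix is regularised by `1e-3 * trace` when
#' ill-conditioned (collinear neighbours), the standard LLE conditioning.
#'
#' @param Y point set (matrix or `labeled_point_set`), M points.
#' @param K neighbour count, `1 <= K < M`.
#' @return Object of class `lle_structure` with the M x K weight matrix `L`,
#'   `neighbor_index` (M x K, 1-based), the M x M expansion `Lhat`, and
#'   `M_mat = (I - Lhat)' (I - Lhat)`.
#' @export
lle_weights <- function(Y, K) {
  Y <- pts_of(Y)
  M <- nrow(Y)
  K <- as.integer(K)
  if (K >= M) stop("K must be smaller than the number of points")
  if (K < 1) stop("K must be >= 1")
  d2 <- cross_dist2(Y, Y)
  diag(d2) <- Inf
  L <- matrix(0, M, K)
  nbr <- matrix(0L, M, K)
  for (m in seq_len(M)) {
    ord <- order(d2[m, ], seq_len(M))[seq_len(K)]
    nbr[m, ] <- ord
    Z <- sweep(Y[ord, , drop = FALSE], 2L, Y[m, ])
    C <- tcrossprod(Z)
    tr <- sum(diag(C))
    if (tr <= 0) {
      C <- C + diag(K) * 1e-12
    } else if (K > 3L || rcond(C) < 1e-10) {
      C <- C + diag(K) * 1e-3 * tr
    }
    w <- solve(C, rep(1, K))
    L[m, ] <- w / sum(w)
  }
  Lhat <- matrix(0, M, M)
  for (m in seq_len(M)) Lhat[m, nbr[m, ]] <- L[m, ]
  IL <- diag(M) - Lhat
  structure(list(L = L, neighbor_index = nbr, Lhat = Lhat,
                 M_mat = crossprod(IL), K = K),
            class = "lle_structure")
}

#' Initial isotropic GMM variance
#'
#' `sigma^2 = (1 / (D M N)) * sum_{m,n} ||x_n - y_m||^2`.
#'
#' @param Y,X point sets (matrices or `labeled_point_set`s).
#' @return Scalar initial variance.
#' @export
init_sigma2 <- function(Y, X) {
  Y <- pts_of(Y); X <- pts_of(X)
  if (nrow(Y) == 0L || nrow(X) == 0L) stop("point sets must be non-empty")
  sum(cross_dist2(Y, X)) / (3 * nrow(Y) * nrow(X))
}

#' Local (nearest-neighbour) initial variance
#'
#' Warm-start estimate of the GMM variance for a template already close to
#' the target (pose tracking): the 95th percentile of the pooled two-way
#' nearest-neighbour squared distances, per dimension. Far templates get a
#' large value (many iterations of annealing, as with the all-pairs
#' formula); well-aligned templates start essentially converged, which is
#' where the tracking strategy saves its EM iterations.
#'
#' @param Y,X point sets (matrices or `labeled_point_set`s).
#' @return Scalar initial variance.
#' @export
nn_sigma2 <- function(Y, X) {
  Y <- pts_of(Y); X <- pts_of(X)
  d2 <- cross_dist2(Y, X)
  pooled <- c(apply(d2, 1L, min), apply(d2, 2L, min))
  max(as.numeric(quantile(pooled, 0.95)) / 3, 1e-10)
}

#' GMM posterior correspondences (E-step)
#'
#' `P[m, n] = exp(-||x_n - t_m||^2 / (2 sigma^2)) /
#' (sum_i exp(-||x_n - t_i||^2 / (2 sigma^2)) + c)` with the uniform-outlier
#' constant `c = (2 pi sigma^2)^{D/2} * omega M / ((1 - omega) N)`.
#'
#' @param T_y deformed template points (M x 3).
#' @param X target points (N x 3).
#' @param sigma2 current variance (> 0).
#' @param omega outlier weight in `[0, 1)`.
#' @return Object of class `correspondence_matrix`: elements `P`, `omega`,
#'   `sigma2`, `Np` (total posterior mass).
#' @export
e_step <- function(T_y, X, sigma2, omega = 0) {
  if (sigma2 <= 0) stop("sigma2 must be > 0")
  if (omega >= 1 || omega < 0) stop("omega must be in [0, 1)")
  T_y <- pts_of(T_y); X <- pts_of(X)
  M <- nrow(T_y); N <- nrow(X)
  d2 <- cross_dist2(T_y, X)
  # column-shifted evaluation: exact posteriors without underflow of the
  # numerator; a far-outlier column still goes to zero (cc term overflows)
  mcol <- apply(d2, 2L, min)
  num <- exp(-sweep(d2, 2L, mcol) / (2 * sigma2))
  cc <- (2 * pi * sigma2)^(3 / 2) * omega * M / ((1 - omega) * N)
  ccs <- if (cc > 0) cc * exp(mcol / (2 * sigma2)) else rep(0, N)
  den <- colSums(num) + ccs
  P <- sweep(num, 2L, den, "/")
  P[, !is.finite(den)] <- 0
  structure(list(P = P, omega = omega, sigma2 = sigma2, Np = sum(P)),
            class = "correspondence_matrix")
}

#' @export
print.correspondence_matrix <- function(x, ...) {
  cat("Correspondence posterior:", nrow(x$P), "x", ncol(x$P),
      sprintf("(omega = %.3g, sigma2 = %.3g, Np = %.4g)\n",
              x$omega, x$sigma2, x$Np))
  invisible(x)
}

#' Solve the M-step linear system for the deformation weights
#'
#' Solves `[d(P1) G + sigma2 alpha I + sigma2 lambda M G] W =
#' P X - (d(P1) + sigma2 lambda M) Y` directly; a singular system falls back
#' to a least-squares solve with a warning recorded on the result.
#'
#' @param P correspondence matrix (M x N) or `correspondence_matrix`.
#' @param Y template points (M x 3), `X` target points (N x 3).
#' @param G Gaussian kernel matrix (or `gaussian_kernel`).
#' @param M_mat LLE penalty matrix (M x M); ignored when `lambda = 0`.
#' @param alpha,lambda,sigma2 scalars as in the objective.
#' @param X target points (N x 3).
#' @param topology `"absolute"` (the printed update, with the
#'   `- sigma2 lambda M Y` right-hand term) or `"displacement"` (the term
#'   drops because the penalty vanishes at `W = 0`).
#' @param MG,MY optional precomputed `M_mat %*% G` and `M_mat %*% Y`.
#' @return M x 3 weight matrix `W` (attribute `warning` on fallback).
#' @export
gltp_solve_w <- function(P, Y, X, G, M_mat = NULL, alpha, lambda, sigma2,
                         topology = "absolute", MG = NULL, MY = NULL) {
  if (inherits(P, "correspondence_matrix")) P <- P$P
  if (inherits(G, "gaussian_kernel")) G <- G$G
  Y <- pts_of(Y); X <- pts_of(X)
  dP1 <- rowSums(P)
  A <- G * dP1 + diag(sigma2 * alpha, nrow(G))
  B <- P %*% X - Y * dP1
  if (lambda != 0) {
    if (is.null(MG)) MG <- M_mat %*% G
    A <- A + (sigma2 * lambda) * MG
    if (identical(topology, "absolute")) {
      if (is.null(MY)) MY <- M_mat %*% Y
      B <- B - (sigma2 * lambda) * MY
    }
  }
  W <- tryCatch(solve(A, B), error = function(e) {
    W <- qr.coef(qr(A, LAPACK = TRUE), B)
    W[is.na(W)] <- 0
    attr(W, "warning") <- "singular M-step system: least-squares fallback"
    W
  })
  W
}

#' GLTP objective (negative complete-data expectation)
#'
#' Weighted squared-distance term over posteriors, plus
#' `Np D / 2 * log(sigma2)`, the motion-coherence penalty
#' `alpha / 2 * Tr(W' G W)`, and the LLE topology penalty
#' `lambda / 2 * ||(I - Lhat)(Y + G W)||_F^2`.
#'
#' @param W deformation weights (M x 3).
#' @param sigma2 variance (> 0).
#' @param P posterior matrix (M x N) or `correspondence_matrix`.
#' @param Y template (M x 3), `X` target (N x 3).
#' @param G kernel matrix or `gaussian_kernel`.
#' @param M_mat LLE penalty matrix (ignored if `lambda = 0`).
#' @param alpha,lambda trade-off weights.
#' @param X target points (N x 3).
#' @param topology `"absolute"` (the penalty applies to the deformed points,
#'   as printed) or `"displacement"` (to the displacement field `G W`).
#' @return Scalar objective value.
#' @export
gltp_objective <- function(W, sigma2, P, Y, X, G, M_mat = NULL,
                           alpha, lambda, topology = "absolute") {
  if (sigma2 <= 0) stop("sigma2 must be > 0")
  if (inherits(P, "correspondence_matrix")) P <- P$P
  if (inherits(G, "gaussian_kernel")) G <- G$G
  Y <- pts_of(Y); X <- pts_of(X)
  GW <- G %*% W
  T_y <- Y + GW
  obj <- sum(P * cross_dist2(T_y, X)) / (2 * sigma2) +
    sum(P) * 3 / 2 * log(sigma2) +
    alpha / 2 * sum(W * GW)
  if (lambda != 0) {
    V <- if (identical(topology, "displacement")) GW else T_y
    obj <- obj + lambda / 2 * sum(V * (M_mat %*% V))
  }
  obj
}

# Standard GMM variance update given posteriors P and deformed template T_y.
update_sigma2 <- function(P, X, T_y) {
  Np <- sum(P)
  s2 <- (sum(colSums(P) * rowSums(X^2)) -
         2 * sum((P %*% X) * T_y) +
         sum(rowSums(P) * rowSums(T_y^2))) / (Np * 3)
  max(s2, 1e-12)
}

#' Fit a topology-aware non-rigid registration (GLTP)
#'
#' Registers a template point set `Y` onto a target `X` by EM over a Gaussian
#' mixture whose centroids are the template points displaced by a
#' kernel-smoothed deformation field `T(Y, W) = Y + G W`. The objective
#' combines the GMM matching term with a global motion-coherence penalty and
#' a local LLE topology penalty; `lambda = 0` is classic coherent point
#' drift. Both sets are centred and scaled internally (each to zero mean,
#' unit RMS radius) and the result is mapped back to the original frame, so
#' the default `beta`, `alpha`, `lambda` operate on a size-free scale.
#'
#' @param Y template (`labeled_point_set` or M x 3 matrix).
#' @param X target (`labeled_point_set` or N x 3 matrix).
#' @param config a [gltp_config()].
#' @param verbose print one line per EM iteration.
#' @param sigma2_init optional initial variance (normalised units),
#'   overriding the all-pairs [init_sigma2()] formula; tracking uses the
#'   local [nn_sigma2()] warm start here.
#' @return An object of class `gltp`: deformation weights `W`, kernel `G`,
#'   LLE structure `lle`, final posteriors `P` (`correspondence_matrix`),
#'   `sigma2` (normalised units), deformed template `TY` (original frame),
#'   per-iteration `trace` (iteration, objective `Q`, `sigma2`), `converged`,
#'   `n_iter`, the inputs and the normalisation parameters. `trace$Q` is the
#'   EM free energy (the penalised expected complete-data negative
#'   log-likelihood plus the posterior entropy terms), the quantity whose
#'   monotone decrease the E/M coordinate updates guarantee; the printed
#'   objective without the entropy terms is available per iteration as
#'   `trace$Q_penalised`.
#' @seealso [cpd()], [predict.gltp()], [residuals.gltp()]
#' @export
gltp <- function(Y, X, config = gltp_config(), verbose = FALSE,
                 sigma2_init = NULL) {
  Y_in <- as_labeled_point_set(Y)
  X_in <- as_labeled_point_set(X)
  Y0 <- Y_in$points; X0 <- X_in$points
  M <- nrow(Y0); N <- nrow(X0)
  if (M == 0L || N == 0L) stop("point sets must be non-empty")

  if (config$normalize) {
    mu_y <- colMeans(Y0); mu_x <- colMeans(X0)
    sc_y <- sqrt(mean(rowSums(sweep(Y0, 2L, mu_y)^2)))
    sc_x <- sqrt(mean(rowSums(sweep(X0, 2L, mu_x)^2)))
    if (sc_y == 0) sc_y <- 1
    if (sc_x == 0) sc_x <- 1
    Yn <- sweep(Y0, 2L, mu_y) / sc_y
    Xn <- sweep(X0, 2L, mu_x) / sc_x
  } else {
    mu_y <- mu_x <- c(0, 0, 0); sc_y <- sc_x <- 1
    Yn <- Y0; Xn <- X0
  }

  kern <- gaussian_kernel(Yn, config$beta)
  G <- kern$G
  lle <- NULL; M_mat <- NULL; MG <- NULL; MY <- NULL
  if (config$lambda > 0) {
    lle <- lle_weights(Yn, min(config$K, M - 1L))
    M_mat <- lle$M_mat
    MG <- M_mat %*% G
    if (identical(config$topology, "absolute")) MY <- M_mat %*% Yn
  }

  sigma2 <- if (is.null(sigma2_init)) init_sigma2(Yn, Xn) else sigma2_init
  W <- matrix(0, M, 3)
  alpha <- config$alpha; lambda <- config$lambda
  trace <- data.frame(iteration = integer(), Q = numeric(),
                      Q_penalised = numeric(), sigma2 = numeric())
  Q_prev <- Inf
  converged <- FALSE
  warn <- character()
  P <- NULL

  for (it in seq_len(config$max_iter)) {
    T_y <- Yn + G %*% W
    P <- e_step(T_y, Xn, sigma2, config$omega)
    W <- gltp_solve_w(P, Yn, Xn, G, M_mat, alpha, lambda, sigma2,
                      topology = config$topology, MG = MG, MY = MY)
    if (!is.null(attr(W, "warning"))) warn <- c(warn, attr(W, "warning"))
    T_y <- Yn + G %*% W
    sigma2 <- update_sigma2(P$P, Xn, T_y)
    Q_pen <- gltp_objective(W, sigma2, P, Yn, Xn, G, M_mat, alpha, lambda,
                            topology = config$topology)
    # free energy: adds the complete-data constants and posterior entropy;
    # the exact E-step and the W / sigma2 coordinate minimisations each
    # lower it, so it decreases monotonically (the entropy-free objective
    # need not: posterior sharpening can raise it transiently)
    Pm <- P$P
    p_out <- pmax(1 - colSums(Pm), 0)
    xlogx <- function(p) sum(p[p > 0] * log(p[p > 0]))
    Q <- Q_pen + P$Np * (3 / 2 * log(2 * pi) - log((1 - config$omega) / M)) +
      (if (config$omega > 0) sum(p_out) * (-log(config$omega / N)) else 0) +
      xlogx(Pm) + xlogx(p_out)
    # data-fit part: stopping is measured here so the annealing schedule of
    # the penalty terms does not mask convergence of the match itself
    Q_data <- sum(Pm * cross_dist2(T_y, Xn)) / (2 * sigma2) +
      P$Np * 3 / 2 * log(sigma2)
    if (!is.finite(Q)) {
      stop("non-finite objective at iteration ", it,
           " (sigma2 = ", format(sigma2), ")")
    }
    trace <- rbind(trace, data.frame(iteration = it, Q = Q,
                                     Q_penalised = Q_pen, sigma2 = sigma2))
    if (verbose) message(sprintf("gltp iter %3d  Q = %.6e  sigma2 = %.3e",
                                 it, Q, sigma2))
    if (is.finite(Q_prev) && abs(Q_prev - Q_data) < config$tol * abs(Q_prev)) {
      converged <- TRUE
      break
    }
    Q_prev <- Q_data
    alpha <- alpha * config$anneal_alpha
    lambda <- lambda * config$anneal_lambda
  }

  TY <- sweep((Yn + G %*% W) * sc_x, 2L, mu_x, "+")
  structure(list(W = W, G = kern, lle = lle, P = P, sigma2 = sigma2,
                 TY = TY, trace = trace, converged = converged,
                 n_iter = nrow(trace), config = config,
                 Y = Y_in, X = X_in,
                 norm = list(mu_y = mu_y, sc_y = sc_y,
                             mu_x = mu_x, sc_x = sc_x),
                 warnings = warn),
            class = "gltp")
}

#' Coherent point drift registration
#'
#' [gltp()] with the topology penalty switched off (`lambda = 0`): the
#' classic CPD non-rigid registration, used for subject shape
#' initialization where template and target poses are similar.
#'
#' @inheritParams gltp
#' @return A `gltp` fit object (see [gltp()]).
#' @export
cpd <- function(Y, X, config = gltp_config(), verbose = FALSE) {
  config$lambda <- 0
  gltp(Y, X, config, verbose)
}

#' @export
print.gltp <- function(x, ...) {
  kind <- if (x$config$lambda > 0) "GLTP" else "CPD"
  cat(sprintf("%s registration: %d -> %d points, %d EM iterations (%s)\n",
              kind, nrow(x$W), ncol(x$P$P), x$n_iter,
              if (x$converged) "converged" else "max_iter reached"))
  cat(sprintf("  final objective %.6g, sigma2 %.4g (normalised units)\n",
              tail(x$trace$Q, 1), x$sigma2))
  invisible(x)
}

#' @export
summary.gltp <- function(object, ...) {
  r <- residuals(object)
  out <- list(n_iter = object$n_iter, converged = object$converged,
              Q = tail(object$trace$Q, 1), sigma2 = object$sigma2,
              mean_residual = mean(r), max_residual = max(r),
              lambda = object$config$lambda)
  class(out) <- "summary.gltp"
  out
}

#' @export
print.summary.gltp <- function(x, ...) {
  cat(sprintf("%s fit: %d iterations (%s)\n",
              if (x$lambda > 0) "GLTP" else "CPD", x$n_iter,
              if (x$converged) "converged" else "not converged"))
  cat(sprintf("  objective %.6g | sigma2 %.4g\n", x$Q, x$sigma2))
  cat(sprintf("  nearest-neighbour residual: mean %.4g, max %.4g\n",
              x$mean_residual, x$max_residual))
  invisible(x)
}

#' @export
coef.gltp <- function(object, ...) object$W

#' Deform points with a fitted registration
#'
#' Without `newdata`, returns the deformed template `T(Y, W)` in the original
#' frame. With `newdata`, applies the learned deformation field to arbitrary
#' points (e.g. the invisible complement of a partial template) through the
#' Gaussian kernel between `newdata` and the template.
#'
#' @param object a `gltp` fit.
#' @param newdata optional points (matrix or `labeled_point_set`).
#' @param ... unused.
#' @return Deformed coordinates (n x 3 matrix).
#' @export
predict.gltp <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$TY)
  Pn <- pts_of(newdata)
  nm <- object$norm
  Pn_n <- sweep(Pn, 2L, nm$mu_y) / nm$sc_y
  Yn <- sweep(object$Y$points, 2L, nm$mu_y) / nm$sc_y
  Gn <- exp(-cross_dist2(Pn_n, Yn) / (2 * object$G$beta^2))
  out <- Pn_n + Gn %*% object$W
  sweep(out * nm$sc_x, 2L, nm$mu_x, "+")
}

#' @export
fitted.gltp <- function(object, ...) object$TY

#' Registration residuals
#'
#' Distance from each deformed template point to its nearest target point,
#' in the original length units.
#'
#' @param object a `gltp` fit.
#' @param ... unused.
#' @return Numeric vector, one entry per template point.
#' @export
residuals.gltp <- function(object, ...) {
  d2 <- cross_dist2(object$TY, object$X$points)
  sqrt(apply(d2, 1L, min))
}

#' Plot a registration fit
#'
#' Scatter of target (grey) and deformed template (colour by label when
#' available), projected on two coordinates.
#'
#' @param x a `gltp` fit.
#' @param dims which two coordinates to show (default x and y).
#' @param ... passed to `plot`.
#' @export
plot.gltp <- function(x, dims = c(1, 2), ...) {
  X <- x$X$points
  plot(X[, dims[1]], X[, dims[2]], col = "grey70", pch = 16, cex = 0.5,
       asp = 1, xlab = c("x", "y", "z")[dims[1]],
       ylab = c("x", "y", "z")[dims[2]], ...)
  lab <- x$Y$labels
  col <- if (is.null(lab)) "red" else lab + 2
  points(x$TY[, dims[1]], x$TY[, dims[2]], col = col, pch = 1, cex = 0.6)
  invisible(x)
}
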