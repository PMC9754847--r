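# Independent oracles used by the tests. None of these share code with the
# package implementations they check.

random_spd <- function(p, cond = 1) {
  A <- matrix(rnorm(p * p), p)
  crossprod(A) / p + cond * diag(p)
}

glasso_obj_oracle <- function(S, Omega, lam, penalize_diagonal = FALSE) {
  ch <- tryCatch(chol(Omega), error = function(e) NULL)
  if (is.null(ch)) return(Inf)
  pen <- sum(abs(Omega)) - if (penalize_diagonal) 0 else sum(abs(diag(Omega)))
  sum(S * Omega) - 2 * sum(log(diag(ch))) + lam * pen
}

# Monotone proximal-gradient (ISTA with backtracking) minimizer of the
# penalized negative log-likelihood: an algorithm entirely different from
# the blockwise coordinate-descent solver in the package.
oracle_glasso_ista <- function(S, lam, max_iter = 20000, tol = 1e-12) {
  p <- nrow(S)
  Omega <- diag(1 / pmax(diag(S), 1e-3))
  f <- glasso_obj_oracle(S, Omega, lam)
  step <- 1 / max(diag(S))
  for (it in seq_len(max_iter)) {
    grad <- S - chol2inv(chol(Omega))
    repeat {
      Znew <- Omega - step * grad
      Znew <- sign(Znew) * pmax(abs(Znew) - step * lam, 0)
      diag(Znew) <- diag(Omega - step * grad)        # off-diagonal penalty
      Znew <- (Znew + t(Znew)) / 2
      fnew <- glasso_obj_oracle(S, Znew, lam)
      if (fnew <= f + 1e-15) break
      step <- step / 2
      if (step < 1e-14) return(list(omega = Omega, objective = f))
    }
    done <- f - fnew < tol && it > 10
    Omega <- Znew; f <- fnew
    step <- step * 1.1
    if (done) break
  }
  list(omega = Omega, objective = f)
}

# Dense 3-parameter grid minimum of the 2x2 objective; the grid is built
# from S alone (centered on the ridged inverse), never from a solver run.
oracle_glasso_grid2 <- function(S, lam, n_ab = 41, n_c = 61) {
  C <- solve(S + lam * diag(2))
  ab1 <- seq(0.2 * C[1, 1], 3 * C[1, 1] + 1, length.out = n_ab)
  ab2 <- seq(0.2 * C[2, 2], 3 * C[2, 2] + 1, length.out = n_ab)
  cmax <- 1.5 * (abs(C[1, 2]) + 1 / lam_safe(lam))
  cs <- seq(-cmax, cmax, length.out = n_c)
  g <- expand.grid(a = ab1, b = ab2, c = cs)
  det_ <- g$a * g$b - g$c^2
  ok <- det_ > 1e-12 & g$a > 0
  g <- g[ok, ]; det_ <- det_[ok]
  obj <- S[1, 1] * g$a + S[2, 2] * g$b + 2 * S[1, 2] * g$c -
    log(det_) + lam * 2 * abs(g$c)
  min(obj)
}
lam_safe <- function(lam) max(lam, 0.05)

ar1_cov_oracle <- function(q, rho) rho^abs(outer(seq_len(q), seq_len(q), "-"))

# Pairwise-concordance AUC: mean over all (preictal, interictal) pairs.
brute_auc <- function(probs, labels) {
  pos <- probs[labels == 1]; neg <- probs[labels == 0]
  if (!length(pos) || !length(neg)) return(NA_real_)
  pairs <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(pairs)
}

# Exhaustive accuracy sweep: every cutoff class reachable in [0, 1] under
# the "probability >= cutoff" convention is represented among {0, the
# probabilities themselves, all midpoints, 1}.
brute_best_accuracy <- function(probs, labels) {
  z <- as.integer(labels)
  u <- sort(unique(probs))
  mids <- if (length(u) > 1) (u[-1] + u[-length(u)]) / 2 else numeric()
  cand <- sort(unique(pmin(pmax(c(0, u, mids, 1), 0), 1)))
  max(vapply(cand, function(ct) mean((probs >= ct) == (z == 1)), 0))
}

# Double-loop weighted covariance, straight from the defining sum.
brute_weighted_cov <- function(X, t, h, center = TRUE) {
  p <- nrow(X); q <- ncol(X)
  if (center) X <- X - rowMeans(X)
  S <- matrix(0, p, p); wsum <- 0
  for (i in seq_len(q)) {
    w <- exp(-((abs(i - t) / h)^2) / 2)
    S <- S + w * X[, i] %*% t(X[, i])
    wsum <- wsum + w
  }
  S / wsum
}

# Small deterministic epoch-set builder for classifier tests: two Gaussian
# clouds in feature space wrapped in the predictor-matrix class.
toy_predictor_matrix <- function(n1 = 20, n2 = 20, d = 5, shift = 3,
                                 seed = 1) {
  set.seed(seed)
  V <- rbind(matrix(rnorm(n1 * d, mean = shift / sqrt(d)), n1),
             matrix(rnorm(n2 * d), n2))
  structure(list(V = V, Z = c(rep(1L, n1), rep(0L, n2)),
                 feature_names = paste0("f", seq_len(d)),
                 edge_names = paste0("f", seq_len(d)),
                 feature_mode = "network", lam = 0.1,
                 kernel = kernel_spec(), center = TRUE,
                 scale_correlation = TRUE),
            class = "network_predictor_matrix")
}
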