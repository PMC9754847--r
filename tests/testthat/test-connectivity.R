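test_that("kernel weights match the Gaussian kernel definition", {
  sp <- kernel_spec()
  q <- 60
  w <- kernel_weights(30, q, sp)
  expect_equal(w[30], 1)                      # K(0) = 1
  expect_true(all(w > 0 & w <= 1))
  # symmetry around t
  expect_equal(w[30 - 7], w[30 + 7])
  # default bandwidth rule: h = q^(1/3)
  h <- q^(1 / 3)
  expect_equal(w[31], exp(-(1 / h)^2 / 2))
  # fixed bandwidth override
  wf <- kernel_weights(1, 5, kernel_spec(bandwidth = 2,
                                         bandwidth_rule = "fixed"))
  expect_equal(wf[3], exp(-1 / 2))
  expect_error(kernel_spec(bandwidth = -1, bandwidth_rule = "fixed"),
               "positive")
})

test_that("weighted covariance equals the double-loop formula", {
  set.seed(42)
  h <- 60^(1 / 3)
  for (trial in 1:5) {
    X <- matrix(rnorm(3 * 60), 3)
    t0 <- sample(60, 1)
    S <- weighted_covariance(X, t0, kernel_spec())
    expect_equal(unclass(S), brute_weighted_cov(X, t0, h),
                 tolerance = 1e-12, ignore_attr = TRUE)
    # literal (uncentered) second-moment form
    S_raw <- weighted_covariance(X, t0, kernel_spec(), center = FALSE)
    expect_equal(unclass(S_raw), brute_weighted_cov(X, t0, h, center = FALSE),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("huge bandwidth recovers the ordinary sample covariance", {
  set.seed(1)
  X <- matrix(rnorm(4 * 50), 4)
  sp <- kernel_spec(bandwidth = 1e8, bandwidth_rule = "fixed")
  Xc <- X - rowMeans(X)
  expect_equal(unclass(weighted_covariance(X, 10, sp)),
               Xc %*% t(Xc) / 50, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(unclass(averaged_covariance(X, sp)),
               Xc %*% t(Xc) / 50, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("averaged covariance is the mean of the per-time estimates", {
  set.seed(7)
  X <- matrix(rnorm(4 * 60), 4)
  sp <- kernel_spec()
  direct <- Reduce(`+`, lapply(1:60, function(t)
    unclass(weighted_covariance(X, t, sp)))) / 60
  expect_equal(unclass(averaged_covariance(X, sp)), direct,
               tolerance = 1e-12, ignore_attr = TRUE)
  # p = 1 sanity: centered two-point data has the plain variance
  x2 <- matrix(c(2, -2), 1)
  expect_equal(as.numeric(weighted_covariance(x2, 1, sp)), 4)
})

test_that("graphical lasso handles analytic cases", {
  set.seed(5)
  S <- random_spd(4)
  f0 <- graphical_lasso(S, 0)
  expect_lt(max(abs(f0$omega - solve(S))), 1e-6)

  fI <- graphical_lasso(diag(3), 0.4)
  expect_equal(fI$omega, diag(3))
  expect_equal(nrow(fI$support), 0)

  # 2x2 closed form: off-diagonal of the dual is soft-thresholded s
  for (s in c(0.15, 0.6, -0.45)) {
    for (lam in c(0.1, 0.3)) {
      f <- graphical_lasso(matrix(c(1, s, s, 1), 2), lam, tol = 1e-8)
      if (abs(s) <= lam) {
        expect_equal(f$omega, diag(2), tolerance = 1e-6)
      } else {
        sh <- sign(s) * (abs(s) - lam)
        expect_equal(f$omega, solve(matrix(c(1, sh, sh, 1), 2)),
                     tolerance = 1e-5)
      }
    }
  }
  expect_error(graphical_lasso(matrix(c(1, 2, 0, 1), 2), 0.1), "symmetric")
  expect_error(graphical_lasso(random_spd(3), -0.1), "non-negative")
})

test_that("solver objective is non-increasing and zero-variance channels warn", {
  set.seed(8)
  S <- random_spd(8, cond = 0.5)
  f <- graphical_lasso(S, 0.1)
  expect_true(all(diff(f$objective_path) <= 1e-8))
  S2 <- S; S2[1, ] <- 0; S2[, 1] <- 0
  expect_warning(graphical_lasso(S2, 0.2), "zero-variance")
})

test_that("permuting channels permutes the precision estimate consistently", {
  set.seed(13)
  S <- random_spd(6, cond = 0.3)
  perm <- sample(6)
  f1 <- graphical_lasso(S, 0.1, tol = 1e-7)
  f2 <- graphical_lasso(S[perm, perm], 0.1, tol = 1e-7)
  expect_equal(f2$omega, f1$omega[perm, perm], tolerance = 1e-5)
  W1 <- partial_correlation(f1)
  W2 <- partial_correlation(f2)
  expect_equal(W2, W1[perm, perm], tolerance = 1e-5)
})

test_that("partial correlations are correctly scaled and bounded", {
  expect_equal(partial_correlation(diag(4)), diag(4))
  O <- matrix(c(2, -1, -1, 2), 2)
  expect_equal(partial_correlation(O)[1, 2], 0.5)
  set.seed(3)
  for (trial in 1:10) {
    f <- graphical_lasso(random_spd(5, cond = 0.4), 0.05)
    W <- partial_correlation(f)
    expect_true(all(abs(W) <= 1 + 1e-9))
    off <- upper.tri(W)
    expect_true(all(sign(W[off]) == -sign(f$omega[off]) |
                      f$omega[off] == 0))
    # zero pattern matches the support
    expect_identical(W[off] == 0, f$omega[off] == 0)
  }
  expect_error(partial_correlation(matrix(c(0, 1, 1, 2), 2)), "positive")
})

test_that("upper-triangle vectorization is row-major and invertible", {
  expect_length(vectorize_upper(diag(21)), 210)
  expect_length(vectorize_upper(diag(19)), 171)
  W <- matrix(c(1, 0.3, 0.3, 1), 2)
  expect_equal(vectorize_upper(W), 0.3)
  # explicit row-major order on a 3x3
  W3 <- matrix(0, 3, 3)
  W3[1, 2] <- 12; W3[1, 3] <- 13; W3[2, 3] <- 23
  W3 <- W3 + t(W3); diag(W3) <- 1
  expect_equal(vectorize_upper(W3), c(12, 13, 23))
  expect_identical(edge_names(c("A", "B", "C")), c("A:B", "A:C", "B:C"))
  # round trip
  v <- vectorize_upper(W3)
  R <- diag(3); R[lower.tri(R)] <- v; R <- t(R); R[lower.tri(R)] <- v
  expect_equal(R, W3)
  expect_error(vectorize_upper(matrix(0, 2, 3)), "square")
})

test_that("per-epoch network vectors behave as the model predicts", {
  set.seed(21)
  sp <- kernel_spec()
  # diagonal truth + strong penalty: near-zero edge vector
  X <- matrix(rnorm(5 * 60), 5)
  v <- epoch_to_network_vector(X, lam = 0.8, spec = sp)
  expect_lt(max(abs(v)), 1e-8)
  # determinism
  expect_identical(v, epoch_to_network_vector(X, lam = 0.8, spec = sp))
  # two perfectly correlated channels dominate at small lambda
  base <- matrix(rnorm(4 * 60), 4)
  base[2, ] <- base[1, ] + rnorm(60, sd = 0.05)
  v2 <- epoch_to_network_vector(base, lam = 0.05, spec = sp)
  expect_equal(which.max(abs(v2)), 1L)       # edge (1,2) is index 1
})

test_that("support shrinks monotonically along a lambda grid", {
  set.seed(17)
  S <- random_spd(10, cond = 0.2)
  sizes <- vapply(c(0.01, 0.05, 0.1, 0.2, 0.4, 0.8),
                  function(l) nrow(graphical_lasso(S, l)$support), 0L)
  expect_true(all(diff(sizes) <= 0))
})

test_that("predictor matrix has the documented shapes and ordering", {
  sim <- simulate_epoch_set(simulation_config(p = 5, q = 20, n1 = 3, n2 = 5,
                                              seed = 4))
  vm <- build_predictor_matrix(sim$epochs, "network", lam = 0.2)
  expect_identical(dim(vm$V), c(8L, 10L))
  expect_equal(vm$Z, c(1, 1, 1, 0, 0, 0, 0, 0))
  expect_identical(colnames(vm$V), edge_names(paste0("E", 1:5)))

  vr <- build_predictor_matrix(sim$epochs, "raw")
  expect_identical(ncol(vr$V), 100L)           # p * q
  # row-major flattening: first q entries are channel 1's time course
  expect_equal(vr$V[1, 1:20], sim$epochs$epochs[[1]]$data[1, ],
               ignore_attr = TRUE)

  vc <- build_predictor_matrix(sim$epochs, "combined", lam = 0.2)
  expect_identical(ncol(vc$V), 110L)
  expect_equal(vc$V[, 1:10], vm$V, ignore_attr = TRUE)
})

test_that("predictor matrices round-trip with their JSON sidecar", {
  sim <- simulate_epoch_set(simulation_config(p = 4, q = 15, n1 = 2, n2 = 2,
                                              seed = 6))
  vm <- build_predictor_matrix(sim$epochs, "network", lam = 0.15)
  path <- withr::local_tempfile(fileext = ".csv")
  write_predictor_matrix(vm, path)
  back <- read_predictor_matrix(path)
  expect_equal(back$V, vm$V, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back$Z, vm$Z)
  expect_identical(back$edge_names, vm$edge_names)
  expect_equal(back$lam, 0.15)
})
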