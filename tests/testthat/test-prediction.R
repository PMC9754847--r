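test_that("ensemble fitting is deterministic and respects its contracts", {
  vm <- toy_predictor_matrix(seed = 2)
  m1 <- fit_ensemble(vm, B = 8, seed = 99)
  m2 <- fit_ensemble(vm, B = 8, seed = 99)
  expect_identical(m1$coefs, m2$coefs)
  expect_identical(m1$intercepts, m2$intercepts)
  expect_identical(dim(m1$coefs), c(5L, 8L))
  # well-separated clouds: every bootstrap selects something
  expect_true(all(colSums(abs(m1$coefs) > 1e-8) >= 1))
  # single-class input rejected
  expect_error(fit_ensemble(vm$V[vm$Z == 1, ], labels = rep(1, 20), B = 2),
               "both classes")
  # zero-variance column dropped with a warning, coefficient pinned at 0
  V2 <- vm$V; V2[, 3] <- 7
  expect_warning(m3 <- fit_ensemble(V2, labels = vm$Z, B = 4, seed = 1),
                 "zero-variance")
  expect_true(all(m3$coefs[3, ] == 0))
})

test_that("fixed-lambda single-bootstrap ensemble equals one lasso fit", {
  vm <- toy_predictor_matrix(seed = 5)
  m <- fit_ensemble(vm, B = 1, lambda_rule = "fixed",
                    lambda_logistic = 0.05, seed = 3)
  expect_identical(ncol(m$coefs), 1L)
  p1 <- predict_probability(m, vm$V)
  expect_true(all(p1 >= 0 & p1 <= 1))
  # probabilities order the two classes correctly on separable data
  expect_gt(min(p1[vm$Z == 1]), max(p1[vm$Z == 0]) - 0.5)
})

test_that("ensemble probability is the exact mean of member probabilities", {
  model <- structure(list(coefs = cbind(c(1, 0), c(0, -2)),
                          intercepts = c(0.5, -1), nonzero_tol = 1e-8,
                          feature_names = c("a", "b"), edge_names = NULL,
                          B = 2L),
                     class = "seizure_ensemble")
  x <- rbind(c(0.3, 0.7), c(-1, 2))
  manual <- (plogis(0.5 + x[, 1] * 1) + plogis(-1 - 2 * x[, 2])) / 2
  expect_equal(predict_probability(model, x), manual)
  # all-zero model: probability one half everywhere
  null_model <- structure(list(coefs = matrix(0, 3, 4),
                               intercepts = rep(0, 4), nonzero_tol = 1e-8,
                               feature_names = letters[1:3],
                               edge_names = NULL, B = 4L),
                          class = "seizure_ensemble")
  expect_equal(predict_probability(null_model, matrix(rnorm(6), 2)),
               c(0.5, 0.5))
  expect_error(predict_probability(model, matrix(0, 1, 3)), "columns")
  # monotonicity under all-positive coefficients
  pos_model <- structure(list(coefs = matrix(abs(rnorm(6)), 2),
                              intercepts = c(0, 0, 0), nonzero_tol = 1e-8,
                              feature_names = c("a", "b"),
                              edge_names = NULL, B = 3L),
                         class = "seizure_ensemble")
  x0 <- c(0.2, 0.1)
  expect_gte(predict_probability(pos_model, rbind(x0 + c(1, 0)))[1],
             predict_probability(pos_model, rbind(x0))[1])
})

test_that("selection frequencies are exact multiples of 1/B", {
  coefs <- cbind(c(1, 0, 0.5, 0), c(2, 0, 0, 0),
                 c(0.1, 0, 1, 0), c(-1, 0, 2, 0))
  model <- structure(list(coefs = coefs, intercepts = rep(0, 4),
                          nonzero_tol = 1e-8, B = 4L,
                          feature_names = paste0("e", 1:4),
                          edge_names = paste0("e", 1:4)),
                     class = "seizure_ensemble")
  imp <- edge_importance(model)
  expect_equal(imp$psi, c(1, 0, 0.75, 0))
  expect_true(all(imp$psi * 4 == round(imp$psi * 4)))
  expect_equal(imp$ranking[1:2], c(1L, 3L))
  # stable tie-break by ascending index
  expect_equal(imp$ranking[3:4], c(2L, 4L))
  top <- ranked_edges(imp, 2)
  expect_identical(top$edge_name, c("e1", "e3"))
})

test_that("cutoff selection maximizes accuracy over all thresholds", {
  # worked case: any cutoff in (0.2, 0.8) is perfect; midpoint 0.5 returned
  expect_equal(select_cutoff(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 0.5)
  # all-positive labels: cutoff 0 calls everything positive
  expect_equal(select_cutoff(c(0.3, 0.9), c(1, 1)), 0)
  set.seed(30)
  for (trial in 1:50) {
    m <- sample(2:12, 1)
    probs <- round(runif(m), 2)
    labels <- rbinom(m, 1, 0.5)
    ct <- select_cutoff(probs, labels)
    acc <- mean((probs >= ct) == (labels == 1))
    expect_equal(acc, brute_best_accuracy(probs, labels))
  }
})

test_that("metrics match hand-computed confusion and rank-sum AUC", {
  m <- compute_metrics(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0), 0.5)
  expect_equal(m$sens, 1)
  expect_equal(m$fdr, 0)
  expect_equal(m$auc, 1)

  # tied probabilities: average rank gives AUC one half
  expect_equal(compute_metrics(c(0.4, 0.4), c(1, 0), 0.5)$auc, 0.5)

  m2 <- compute_metrics(c(0.9, 0.6, 0.55, 0.5, 0.2, 0.1),
                        c(1, 0, 1, 0, 1, 0), 0.52)
  expect_equal(unname(m2$confusion), c(2, 1, 2, 1))   # TP FP TN FN
  expect_equal(m2$sens, 2 / 3)
  expect_equal(m2$fdr, 1 / 3)
  # concordant pairs: (0.9 beats all 3) + (0.55 beats 2) + (0.2 beats 1)
  expect_equal(m2$auc, 6 / 9)
  expect_equal(m2$auc, brute_auc(c(0.9, 0.6, 0.55, 0.5, 0.2, 0.1),
                                 c(1, 0, 1, 0, 1, 0)))

  # no positive calls: FDR defined as 0
  m3 <- compute_metrics(c(0.1, 0.2), c(1, 0), 0.9)
  expect_equal(m3$fdr, 0)
  expect_warning(compute_metrics(c(0.2, 0.8), c(1, 1), 0.5), "single class")
})

test_that("rank-sum AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(31)
  for (trial in 1:10) {
    m <- sample(6:30, 1)
    probs <- runif(m)
    labels <- c(1, 0, rbinom(m - 2, 1, 0.5))
    ours <- compute_metrics(probs, labels, 0.5)$auc
    ref <- as.numeric(pROC::auc(pROC::roc(labels, probs, quiet = TRUE,
                                          direction = "<")))
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})

test_that("cross-validation separates separable data and shuffled labels do not", {
  sim <- simulate_epoch_set(simulation_config(p = 6, q = 40, n1 = 25,
                                              n2 = 25, n_diff = 3,
                                              edge_prob = 0.1, seed = 14))
  res <- cross_validate(sim$epochs, "network", k = 5, B = 20, seed = 14)
  expect_gt(res$metrics$auc, 0.9)
  expect_s3_class(res$importance, "edge_importance")
  expect_equal(nrow(res$oof), 50)
  # determinism of the whole protocol
  res2 <- cross_validate(sim$epochs, "network", k = 5, B = 20, seed = 14)
  expect_identical(res$oof$prob, res2$oof$prob)
  expect_identical(res$metrics$auc, res2$metrics$auc)
  # class smaller than k rejected
  expect_error(cross_validate(sim$epochs, "network", k = 30, B = 5),
               "at least k")
})

test_that("leave-one-out on a tiny epoch set returns finite metrics", {
  vm <- toy_predictor_matrix(n1 = 6, n2 = 6, seed = 8)
  # glmnet warns about tiny per-fold class counts; that smallness is the point
  res <- suppressWarnings(cross_validate(vm, k = 6L, B = 5, seed = 2))
  expect_true(is.finite(res$metrics$auc))
  expect_true(is.finite(res$metrics$sens))
  expect_true(res$metrics$cutoff >= 0 && res$metrics$cutoff <= 1)
})
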