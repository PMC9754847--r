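# Stratified fold ids: within each class, folds are assigned round-robin
# after a random permutation, so every fold holds both classes whenever
# each class has >= k members.
stratified_folds <- function(z, k) {
  foldid <- integer(length(z))
  for (cls in unique(z)) {
    idx <- which(z == cls)
    foldid[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  foldid
}

#' Fit a bootstrap ensemble of lasso-penalized logistic models
#'
#' Stage 2 of the pipeline. Columns of the predictor matrix are
#' standardized using full-training statistics; the logistic-lasso penalty
#' is chosen once by stratified cross-validation on the full training set
#' (`lambda_rule = "cv_once"`) and reused across bootstraps. For each of B
#' replicates, a class-stratified bootstrap (n1 preictal draws and n2
#' interictal draws, with replacement) is refit; coefficients are stored
#' back on the original column scale. Deterministic given `seed`.
#'
#' @param V a `network_predictor_matrix`, or an n x d numeric matrix (then
#'   supply `labels`).
#' @param labels binary vector (1 preictal, 0 interictal); ignored when `V`
#'   carries its own.
#' @param B number of bootstrap replicates (default 100).
#' @param lambda_rule `"cv_once"` (default) or `"fixed"` (then supply
#'   `lambda_logistic`).
#' @param lambda_logistic penalty used when `lambda_rule = "fixed"`.
#' @param seed integer seed governing CV folds and bootstrap draws.
#' @param nonzero_tol threshold below which a coefficient counts as zero
#'   (original scale).
#' @param cv_folds folds for the one-off penalty selection.
#' @return An object of class `seizure_ensemble`: `coefs` (d x B, original
#'   scale), `intercepts`, `center`/`scale` standardization parameters,
#'   `lambda_logistic`, `B`, `seed`, `nonzero_tol`, `feature_names`,
#'   `edge_names`.
#' @export
fit_ensemble <- function(V, labels = NULL, B = 100L,
                         lambda_rule = c("cv_once", "fixed"),
                         lambda_logistic = NULL, seed = 1L,
                         nonzero_tol = 1e-8, cv_folds = 5L) {
  lambda_rule <- match.arg(lambda_rule)
  en <- NULL
  if (inherits(V, "network_predictor_matrix")) {
    labels <- V$Z; en <- V$edge_names; X <- V$V
  } else X <- as.matrix(V)
  if (is.null(labels)) stop("labels are required when V is a plain matrix")
  z <- as.integer(labels)
  if (length(unique(z)) < 2)
    stop("both classes must be present to fit the ensemble")
  if (B < 1) stop("B must be >= 1")
  n1 <- sum(z == 1); n2 <- sum(z == 0)
  d <- ncol(X)

  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  dead <- !is.finite(scl) | scl < 1e-12
  if (any(dead)) {
    warning(sum(dead), " zero-variance column(s) dropped from the fit")
    scl[dead] <- 1
  }
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  Xs[, dead] <- 0
  live <- which(!dead)
  if (length(live) < 2)
    stop("fewer than two informative columns; cannot fit the ensemble")

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  if (lambda_rule == "cv_once") {
    k <- min(cv_folds, n1, n2)
    foldid <- stratified_folds(z, k)
    cv <- glmnet::cv.glmnet(Xs[, live, drop = FALSE], z, family = "binomial",
                            alpha = 1, foldid = foldid, standardize = FALSE)
    lambda_logistic <- cv$lambda.min
  } else if (is.null(lambda_logistic) || lambda_logistic < 0) {
    stop("lambda_rule = \"fixed\" requires a non-negative lambda_logistic")
  }
  # short descending path ending at the target: warm starts stabilize the fit
  lam_path <- unique(lambda_logistic * 2^seq(5, 0, length.out = 12))

  coefs <- matrix(0, d, B)
  intercepts <- numeric(B)
  idx1 <- which(z == 1); idx0 <- which(z == 0)
  for (b in seq_len(B)) {
    take <- c(sample(idx1, n1, replace = TRUE),
              sample(idx0, n2, replace = TRUE))
    fit <- glmnet::glmnet(Xs[take, live, drop = FALSE], z[take],
                          family = "binomial", alpha = 1,
                          lambda = lam_path, standardize = FALSE)
    cf <- as.matrix(stats::coef(fit, s = lambda_logistic, exact = FALSE))
    intercepts[b] <- cf[1, 1]
    coefs[live, b] <- cf[-1, 1]
  }
  # back to the original column scale
  coefs_orig <- coefs / scl
  intercepts <- intercepts - colSums(coefs * (ctr / scl))

  structure(list(coefs = coefs_orig, intercepts = intercepts,
                 center = ctr, scale = scl, dropped = which(dead),
                 lambda_logistic = lambda_logistic, B = as.integer(B),
                 seed = as.integer(seed), nonzero_tol = nonzero_tol,
                 feature_names = colnames(X), edge_names = en,
                 n1 = n1, n2 = n2),
            class = "seizure_ensemble")
}

#' @export
print.seizure_ensemble <- function(x, ...) {
  cat(sprintf("<seizure_ensemble> B = %d, d = %d, lambda = %.4g, trained on %d + %d epochs\n",
              x$B, nrow(x$coefs), x$lambda_logistic, x$n1, x$n2))
  invisible(x)
}

#' Ensemble-averaged preictal probability
#'
#' For each row x, every bootstrap model contributes
#' `plogis(intercept_b + x . beta_b)`; the ensemble probability is their
#' arithmetic mean -- the proportion of models assigning the epoch to the
#' preictal state, smoothed by each model's own probability.
#'
#' @param model a `seizure_ensemble`.
#' @param rows m x d matrix on the original feature scale (or a
#'   `network_predictor_matrix`).
#' @return length-m vector of probabilities in \[0, 1\].
#' @export
predict_probability <- function(model, rows) {
  if (inherits(rows, "network_predictor_matrix")) rows <- rows$V
  rows <- if (is.null(dim(rows))) matrix(rows, nrow = 1) else as.matrix(rows)
  if (ncol(rows) != nrow(model$coefs))
    stop("rows have ", ncol(rows), " columns; model expects ",
         nrow(model$coefs))
  eta <- sweep(rows %*% model$coefs, 2, model$intercepts, "+")
  rowMeans(stats::plogis(eta))
}

#' Per-edge selection frequencies (importance weights)
#'
#' `psi_i` is the fraction of the B bootstrap fits in which edge i's
#' coefficient is nonzero (|beta| above the model's `nonzero_tol`). The
#' greater the weight, the more consistently that connection separates
#' preictal from interictal epochs; this is the method's explainability
#' output. Ties in the ranking break by ascending edge index (stable).
#'
#' @param model a `seizure_ensemble`.
#' @param edge_names optional label vector overriding the model's.
#' @return An object of class `edge_importance`: `psi` (each a multiple of
#'   1/B in \[0, 1\]), `edge_names`, `ranking`.
#' @export
edge_importance <- function(model, edge_names = NULL) {
  psi <- rowMeans(abs(model$coefs) > model$nonzero_tol)
  nm <- edge_names %||% model$edge_names %||% model$feature_names
  ranking <- order(-psi, seq_along(psi))
  structure(list(psi = psi, edge_names = nm, ranking = ranking, B = model$B),
            class = "edge_importance")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.edge_importance <- function(x, n = 10L, ...) {
  cat(sprintf("<edge_importance> top %d of %d edges (B = %d):\n",
              min(n, length(x$psi)), length(x$psi), x$B))
  top <- x$ranking[seq_len(min(n, length(x$psi)))]
  nm <- x$edge_names %||% as.character(top)
  for (i in top) cat(sprintf("  %-28s %.2f\n", nm[i], x$psi[i]))
  invisible(x)
}

#' Ranked edge table
#' @param imp an `edge_importance`.
#' @param n number of top edges (default all).
#' @return data frame with columns `rank`, `edge_name`, `psi`.
#' @export
ranked_edges <- function(imp, n = length(imp$psi)) {
  top <- imp$ranking[seq_len(min(n, length(imp$psi)))]
  data.frame(rank = seq_along(top),
             edge_name = (imp$edge_names %||% as.character(top))[top],
             psi = imp$psi[top])
}

#' Accuracy-maximizing probability cutoff
#'
#' Candidate cutoffs are the midpoints between adjacent sorted unique
#' probabilities, together with 0 and 1; the candidate maximizing
#' `(TP + TN) / m` (with "positive" meaning probability >= cutoff) is
#' returned, ties broken toward the smallest cutoff.
#'
#' @param probs predicted probabilities.
#' @param labels binary labels.
#' @return the selected cutoff.
#' @export
select_cutoff <- function(probs, labels) {
  z <- as.integer(labels)
  u <- sort(unique(probs))
  cand <- sort(unique(c(0, if (length(u) > 1)
    (u[-1] + u[-length(u)]) / 2, 1)))
  acc <- vapply(cand, function(ct) mean((probs >= ct) == (z == 1)), 0)
  cand[which.max(acc)]      # which.max takes the first (smallest) maximizer
}

#' Sensitivity, false discovery rate and AUC of epoch predictions
#'
#' A positive call is `prob >= cutoff`. SENS = TP / (TP + FN) is the
#' proportion of preictal epochs called positive; FDR = FP / (TP + FP) is
#' the proportion of positive calls that are not preictal (0 when there
#' are no positive calls). AUC is computed from the Mann-Whitney rank-sum
#' statistic with average ranks for ties, so it is cutoff-independent.
#'
#' @param probs predicted probabilities.
#' @param labels binary labels (1 preictal, 0 interictal).
#' @param cutoff probability threshold (e.g. from [select_cutoff()]).
#' @return An object of class `prediction_metrics`: `sens`, `fdr`, `auc`,
#'   `cutoff`, `accuracy` and the `confusion` counts (TP, FP, TN, FN).
#' @export
compute_metrics <- function(probs, labels, cutoff = 0.5) {
  z <- as.integer(labels)
  pos <- probs >= cutoff
  tp <- sum(pos & z == 1); fp <- sum(pos & z == 0)
  tn <- sum(!pos & z == 0); fn <- sum(!pos & z == 1)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  fdr <- if (tp + fp > 0) fp / (tp + fp) else 0
  n1 <- sum(z == 1); n2 <- sum(z == 0)
  if (n1 > 0 && n2 > 0) {
    r <- rank(probs)
    auc <- (sum(r[z == 1]) - n1 * (n1 + 1) / 2) / (n1 * n2)
  } else {
    warning("AUC undefined with a single class")
    auc <- NA_real_
  }
  structure(list(sens = sens, fdr = fdr, auc = auc, cutoff = cutoff,
                 accuracy = (tp + tn) / length(z),
                 confusion = c(TP = tp, FP = fp, TN = tn, FN = fn)),
            class = "prediction_metrics")
}

#' @export
print.prediction_metrics <- function(x, ...) {
  cat(sprintf("<prediction_metrics> AUC %.3f | SENS %.1f%% | FDR %.1f%% | cutoff %.3f\n",
              x$auc, 100 * x$sens, 100 * x$fdr, x$cutoff))
  cat(sprintf("  confusion: TP %d, FP %d, TN %d, FN %d\n",
              x$confusion["TP"], x$confusion["FP"],
              x$confusion["TN"], x$confusion["FN"]))
  invisible(x)
}

#' Stratified k-fold evaluation of the two-stage pipeline
#'
#' Builds per-epoch features, then evaluates out-of-fold: for each fold an
#' ensemble is fit on the training epochs only and ensemble probabilities
#' are computed for the held-out epochs. Out-of-fold probabilities are
#' pooled; the accuracy-maximizing cutoff is chosen on the pooled
#' probabilities and SENS/FDR/AUC are computed from them. Edge importance
#' is reported from a final ensemble refit on all epochs. (The stage-1
#' feature map is a per-epoch transform with a fixed global penalty, so
#' held-out features involve no training-set statistics.)
#'
#' @param epochs an `epoch_set`, or a prebuilt `network_predictor_matrix`.
#' @param mode feature mode, see [build_predictor_matrix()].
#' @param k number of folds (default 5); each class needs >= k epochs.
#' @param B bootstrap replicates per ensemble.
#' @param lam stage-1 graphical-lasso penalty.
#' @param spec a [kernel_spec()].
#' @param center,scale_correlation stage-1 settings.
#' @param seed integer governing folds, penalty CV and bootstraps.
#' @param lambda_rule,lambda_logistic stage-2 penalty rule, see
#'   [fit_ensemble()].
#' @return A list of class `cv_result`: `metrics` (a
#'   `prediction_metrics`), `importance` (an `edge_importance`), `oof`
#'   (data frame of pooled out-of-fold probabilities), `model` (the final
#'   all-data ensemble), `k`, `seed`, and `protocol` metadata.
#' @export
cross_validate <- function(epochs, mode = c("network", "raw", "combined"),
                           k = 5L, B = 100L, lam = 0.1,
                           spec = kernel_spec(), center = TRUE,
                           scale_correlation = TRUE, seed = 1L,
                           lambda_rule = c("cv_once", "fixed"),
                           lambda_logistic = NULL) {
  mode <- match.arg(mode)
  lambda_rule <- match.arg(lambda_rule)
  vm <- if (inherits(epochs, "network_predictor_matrix")) epochs else
    build_predictor_matrix(epochs, mode = mode, lam = lam, spec = spec,
                           center = center,
                           scale_correlation = scale_correlation)
  z <- vm$Z
  n1 <- sum(z == 1); n2 <- sum(z == 0)
  if (min(n1, n2) < k)
    stop("each class needs at least k = ", k, " epochs (have ", n1, " / ",
         n2, ")")

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  foldid <- stratified_folds(z, k)
  sub_seeds <- sample.int(.Machine$integer.max %/% 2, k + 1L)

  probs <- numeric(length(z))
  for (f in seq_len(k)) {
    tr <- foldid != f
    model_f <- fit_ensemble(vm$V[tr, , drop = FALSE], labels = z[tr], B = B,
                            lambda_rule = lambda_rule,
                            lambda_logistic = lambda_logistic,
                            seed = sub_seeds[f])
    probs[!tr] <- predict_probability(model_f, vm$V[!tr, , drop = FALSE])
  }

  cutoff <- select_cutoff(probs, z)
  metrics <- compute_metrics(probs, z, cutoff)
  final <- fit_ensemble(vm, B = B, lambda_rule = lambda_rule,
                        lambda_logistic = lambda_logistic,
                        seed = sub_seeds[k + 1L])
  imp <- edge_importance(final)
  structure(list(metrics = metrics, importance = imp,
                 oof = data.frame(prob = probs, label = z, fold = foldid),
                 model = final, k = k, seed = seed,
                 protocol = sprintf(
                   "stratified %d-fold CV; cutoff chosen on pooled out-of-fold probabilities; psi from all-data refit",
                   k)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result> ", x$protocol, "\n", sep = "")
  print(x$metrics)
  invisible(x)
}
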