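#' Kernel specification for time-varying covariance weights
#'
#' The time-varying covariance at time point t weights observation i by
#' `K(|i - t| / h)` with a Gaussian kernel `K(u) = exp(-u^2 / 2)` (so the
#' weight at i = t is always 1). The default bandwidth rule sets
#' `h = q^(1/3)`, where q is the number of time points in the epoch over
#' which the kernel smooths; a fixed numeric bandwidth can be supplied
#' instead.
#'
#' @param kernel kernel family; only `"gaussian"` is provided.
#' @param bandwidth positive bandwidth h, required when
#'   `bandwidth_rule = "fixed"`.
#' @param bandwidth_rule `"power_third"` (h = q^(1/3), the default) or
#'   `"fixed"`.
#' @return An object of class `kernel_spec`.
#' @export
kernel_spec <- function(kernel = "gaussian", bandwidth = NULL,
                        bandwidth_rule = c("power_third", "fixed")) {
  kernel <- match.arg(kernel, "gaussian")
  bandwidth_rule <- match.arg(bandwidth_rule)
  if (bandwidth_rule == "fixed") {
    if (is.null(bandwidth) || !is.numeric(bandwidth) || bandwidth <= 0)
      stop("fixed bandwidth_rule requires a positive numeric bandwidth")
  } else if (!is.null(bandwidth)) {
    stop("bandwidth is only used with bandwidth_rule = \"fixed\"")
  }
  structure(list(kernel = kernel, bandwidth = bandwidth,
                 bandwidth_rule = bandwidth_rule),
            class = "kernel_spec")
}

kernel_bandwidth <- function(spec, q) {
  if (spec$bandwidth_rule == "fixed") spec$bandwidth else q^(1 / 3)
}

#' Kernel weights over the time points of an epoch
#'
#' @param t target time index, 1..q.
#' @param q number of time points in the epoch.
#' @param spec a [kernel_spec()].
#' @return length-q vector of weights in (0, 1], with weight 1 at index t.
#' @export
kernel_weights <- function(t, q, spec = kernel_spec()) {
  if (t < 1 || t > q) stop("t must lie in 1..q")
  h <- kernel_bandwidth(spec, q)
  u <- (abs(seq_len(q) - t)) / h
  exp(-u^2 / 2)
}

center_rows <- function(X) X - rowMeans(X)

#' Kernel-weighted covariance at one time point
#'
#' Computes `sum_i w_it x_i x_i' / sum_i w_it` over the q columns of the
#' epoch, with Gaussian kernel weights centered at time t. With
#' `center = TRUE` (default) each electrode's within-epoch temporal mean is
#' subtracted first; `center = FALSE` uses the raw second-moment form.
#'
#' @param X p x q epoch matrix (electrodes x time points).
#' @param t time index, 1..q.
#' @param spec a [kernel_spec()].
#' @param center subtract per-electrode temporal means first?
#' @return A p x p symmetric positive-semidefinite matrix with attributes
#'   `time_index` and `weights`.
#' @export
weighted_covariance <- function(X, t, spec = kernel_spec(), center = TRUE) {
  X <- as.matrix(X)
  q <- ncol(X)
  if (q < 2) stop("epoch must contain at least 2 time points")
  w <- kernel_weights(t, q, spec)
  if (center) X <- center_rows(X)
  S <- (X * rep(w, each = nrow(X))) %*% t(X) / sum(w)
  S <- (S + t(S)) / 2
  attr(S, "time_index") <- t
  attr(S, "weights") <- w
  S
}

#' Within-epoch average of the time-varying covariances
#'
#' Averages the kernel-weighted covariance over all q time points:
#' `(1/q) * sum_t S(t)`. Because each S(t) is the same outer-product sum
#' under different column weights, the average collapses to a single
#' weighted covariance with per-column weight
#' `a_i = (1/q) * sum_t w_it / sum_j w_jt`, which is how it is computed.
#'
#' @inheritParams weighted_covariance
#' @return A p x p symmetric positive-semidefinite matrix with attribute
#'   `time_index = "averaged"`.
#' @export
averaged_covariance <- function(X, spec = kernel_spec(), center = TRUE) {
  X <- as.matrix(X)
  q <- ncol(X)
  if (q < 2) stop("epoch must contain at least 2 time points")
  h <- kernel_bandwidth(spec, q)
  idx <- seq_len(q)
  W <- exp(-(outer(idx, idx, function(i, t) (i - t) / h))^2 / 2)
  a <- rowMeans(W / rep(colSums(W), each = q))    # a_i = mean_t w_it / W.t
  if (center) X <- center_rows(X)
  S <- (X * rep(a, each = nrow(X))) %*% t(X)
  S <- (S + t(S)) / 2
  attr(S, "time_index") <- "averaged"
  S
}

# ---- graphical lasso -----------------------------------------------------

soft_threshold <- function(x, lam) sign(x) * pmax(abs(x) - lam, 0)

# coordinate descent for: min_b 0.5 b' W11 b - s12' b + lam |b|_1
lasso_cd <- function(W11, s12, lam, beta, tol, max_iter = 2000L) {
  v <- as.vector(W11 %*% beta)
  dvec <- diag(W11)
  for (it in seq_len(max_iter)) {
    dmax <- 0
    for (j in seq_along(beta)) {
      r <- s12[j] - v[j] + dvec[j] * beta[j]
      bj <- soft_threshold(r, lam) / dvec[j]
      d <- bj - beta[j]
      if (d != 0) {
        v <- v + W11[, j] * d
        beta[j] <- bj
        if (abs(d) > dmax) dmax <- abs(d)
      }
    }
    if (dmax < tol) break
  }
  beta
}

glasso_objective <- function(S, Omega, lam, penalize_diagonal = FALSE) {
  ch <- tryCatch(chol(Omega), error = function(e) NULL)
  if (is.null(ch)) return(Inf)
  pen <- sum(abs(Omega)) - if (penalize_diagonal) 0 else sum(abs(diag(Omega)))
  sum(S * Omega) - 2 * sum(log(diag(ch))) + lam * pen
}

glasso_recover_omega <- function(W, Bmat) {
  p <- ncol(W)
  Omega <- matrix(0, p, p)
  for (j in seq_len(p)) {
    idx <- setdiff(seq_len(p), j)
    beta <- Bmat[, j]
    theta_jj <- 1 / (W[j, j] - sum(W[idx, j] * beta))
    Omega[j, j] <- theta_jj
    Omega[idx, j] <- -beta * theta_jj
  }
  (Omega + t(Omega)) / 2
}

#' Sparse precision matrix estimation (graphical lasso)
#'
#' Minimizes `Tr(S Omega) - log det Omega + lam * ||Omega||_1` over
#' positive-definite matrices, with the L1 penalty applied to off-diagonal
#' entries by default (set `penalize_diagonal = TRUE` for the literal
#' all-entries penalty). Solved by blockwise coordinate descent on the dual
#' (one lasso subproblem per column of the covariance estimate W), the
#' standard graphical-lasso algorithm. `lam = 0` returns the unpenalized
#' maximum-likelihood inverse, ridging S by `ridge_eps * I` first if it is
#' numerically singular.
#'
#' @param S p x p symmetric covariance estimate.
#' @param lam non-negative L1 penalty.
#' @param penalize_diagonal also penalize diagonal entries?
#' @param ridge_eps ridge added to a singular S when `lam = 0`; also the
#'   variance floor for degenerate (zero-variance) channels.
#' @param tol convergence tolerance on the mean absolute off-diagonal
#'   change of W per sweep.
#' @param max_iter maximum number of outer sweeps.
#' @return An object of class `precision_estimate`: `omega` (p x p,
#'   symmetric positive-definite), `lam`, `support` (2-column matrix of
#'   off-diagonal nonzero index pairs, upper triangle, at threshold 1e-8),
#'   `sigma` (the dual estimate W = Omega^-1), `objective_path`,
#'   `iterations`, `converged`.
#' @export
graphical_lasso <- function(S, lam, penalize_diagonal = FALSE,
                            ridge_eps = 1e-8, tol = 1e-5, max_iter = 200L) {
  S <- as.matrix(S)
  if (nrow(S) != ncol(S)) stop("S must be square")
  if (max(abs(S - t(S))) > 1e-8) stop("S must be symmetric")
  if (lam < 0) stop("lam must be non-negative")
  S <- (S + t(S)) / 2
  p <- nrow(S)

  dg <- diag(S)
  if (any(dg < ridge_eps)) {
    warning("zero-variance channel(s): variance floored at ridge_eps")
    diag(S) <- pmax(dg, ridge_eps)
  }

  if (lam == 0) {
    ev <- min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
    if (ev < ridge_eps) S <- S + ridge_eps * diag(p)
    Omega <- chol2inv(chol(S))
    Omega <- (Omega + t(Omega)) / 2
    return(new_precision_estimate(Omega, S, lam,
                                  glasso_objective(S, Omega, lam,
                                                   penalize_diagonal),
                                  iterations = 0L, converged = TRUE))
  }

  if (p == 1L) {
    w <- S[1, 1] + if (penalize_diagonal) lam else 0
    Omega <- matrix(1 / w)
    return(new_precision_estimate(Omega, matrix(w), lam,
                                  glasso_objective(matrix(w), Omega, lam,
                                                   penalize_diagonal),
                                  iterations = 0L, converged = TRUE))
  }

  W <- S
  if (penalize_diagonal) diag(W) <- diag(S) + lam
  Bmat <- matrix(0, p - 1L, p)
  inner_tol <- tol / 50
  off <- row(S) != col(S)
  obj_path <- numeric()
  converged <- FALSE
  iterations <- 0L

  for (iter in seq_len(max_iter)) {
    iterations <- iter
    W_old <- W
    for (j in seq_len(p)) {
      idx <- setdiff(seq_len(p), j)
      Bmat[, j] <- lasso_cd(W[idx, idx, drop = FALSE], S[idx, j], lam,
                            Bmat[, j], inner_tol)
      w12 <- as.vector(W[idx, idx, drop = FALSE] %*% Bmat[, j])
      W[idx, j] <- w12
      W[j, idx] <- w12
    }
    obj_path <- c(obj_path,
                  glasso_objective(S, glasso_recover_omega(W, Bmat), lam,
                                   penalize_diagonal))
    if (mean(abs(W[off] - W_old[off])) < tol) { converged <- TRUE; break }
  }

  Omega <- glasso_recover_omega(W, Bmat)
  # exact zeros from the lasso subproblems, symmetrized conservatively
  zero <- matrix(FALSE, p, p)
  for (j in seq_len(p)) {
    idx <- setdiff(seq_len(p), j)
    zero[idx, j] <- Bmat[, j] == 0
  }
  Omega[off][zero[off] & t(zero)[off]] <- 0

  fit <- new_precision_estimate(Omega, W, lam, obj_path,
                                iterations = iterations,
                                converged = converged)
  if (!converged) {
    cond <- structure(
      class = c("seizconn_convergence_error", "error", "condition"),
      list(message = sprintf(
             "graphical lasso did not converge in %d sweeps", max_iter),
           call = sys.call(-1), fit = fit))
    stop(cond)
  }
  fit
}

new_precision_estimate <- function(Omega, Sigma, lam, objective_path,
                                   iterations, converged) {
  p <- nrow(Omega)
  up <- which(upper.tri(Omega) & abs(Omega) > 1e-8, arr.ind = TRUE)
  structure(list(omega = Omega, sigma = Sigma, lam = lam,
                 support = up, objective_path = objective_path,
                 iterations = iterations, converged = converged),
            class = "precision_estimate")
}

#' @export
print.precision_estimate <- function(x, ...) {
  p <- nrow(x$omega)
  cat(sprintf("<precision_estimate> p = %d, lambda = %g, %d/%d off-diagonal edges\n",
              p, x$lam, nrow(x$support), p * (p - 1) / 2))
  invisible(x)
}

#' Stationarity (KKT) residual of a graphical-lasso fit
#'
#' Measures `max | S - Omega^-1 + lam * Gamma |` where Gamma is the sign of
#' Omega on its active off-diagonal set; on the inactive set the residual
#' is the amount by which `|S - Omega^-1|` exceeds lam. Zero at an exact
#' solution.
#'
#' @param S the covariance matrix the fit was computed from.
#' @param fit a `precision_estimate`.
#' @param penalize_diagonal must match the fit.
#' @return maximum absolute stationarity violation.
#' @export
kkt_residual <- function(S, fit, penalize_diagonal = FALSE) {
  Omega <- fit$omega
  lam <- fit$lam
  R <- S - chol2inv(chol(Omega))
  p <- nrow(S)
  viol <- matrix(0, p, p)
  active <- Omega != 0
  viol[active] <- abs(R[active] + lam * sign(Omega[active]))
  viol[!active] <- pmax(abs(R[!active]) - lam, 0)
  if (!penalize_diagonal) diag(viol) <- abs(diag(R))
  max(viol)
}

#' Partial correlations from a precision matrix
#'
#' `W[i, j] = -omega_ij / sqrt(omega_ii * omega_jj)` off the diagonal, 1 on
#' it: the standardized conditional-dependence strength between two
#' electrodes given all others. The zero pattern of W equals the
#' off-diagonal support of the precision matrix.
#'
#' @param omega a `precision_estimate` or a p x p precision matrix with
#'   strictly positive diagonal.
#' @return p x p symmetric matrix of partial correlations.
#' @export
partial_correlation <- function(omega) {
  if (inherits(omega, "precision_estimate")) omega <- omega$omega
  omega <- as.matrix(omega)
  d <- diag(omega)
  if (any(d <= 0)) stop("precision matrix must have positive diagonal")
  s <- 1 / sqrt(d)
  W <- -(omega * outer(s, s))
  diag(W) <- 1
  (W + t(W)) / 2
}

#' Vectorize the upper triangle of a symmetric matrix by row
#'
#' Concatenates `W[1,2..p], W[2,3..p], ..., W[p-1,p]`, giving the length
#' `d = p(p-1)/2` edge-strength vector. Edge names are aligned
#' index-for-index by [edge_names()].
#'
#' @param W symmetric p x p matrix, p >= 2.
#' @return numeric vector of length p(p-1)/2.
#' @export
vectorize_upper <- function(W) {
  W <- as.matrix(W)
  if (nrow(W) != ncol(W)) stop("W must be square")
  if (nrow(W) < 2) stop("W must be at least 2 x 2")
  t(W)[lower.tri(W)]     # row-major upper triangle
}

#' Edge names aligned with [vectorize_upper()]
#'
#' @param channel_labels length-p character vector.
#' @param sep separator between the two channel labels of an edge.
#' @return character vector of length p(p-1)/2, in row-major
#'   upper-triangle order.
#' @export
edge_names <- function(channel_labels, sep = ":") {
  p <- length(channel_labels)
  out <- character(p * (p - 1) / 2)
  k <- 0L
  for (i in seq_len(p - 1L)) for (j in (i + 1L):p) {
    k <- k + 1L
    out[k] <- paste(channel_labels[i], channel_labels[j], sep = sep)
  }
  out
}

#' Per-epoch network feature vector
#'
#' The stage-1 composition: averaged kernel-weighted covariance ->
#' (optional rescaling to a correlation matrix) -> graphical lasso ->
#' partial correlations -> row-major upper-triangle vectorization. With
#' `scale_correlation = TRUE` (default) the penalty acts on a
#' correlation-scale matrix, so one global `lam` is comparable across
#' epochs and channels.
#'
#' @param epoch an `eeg_epoch` or a p x q matrix.
#' @param lam graphical-lasso penalty (default 0.1).
#' @param spec a [kernel_spec()].
#' @param center subtract per-electrode means before covariance?
#' @param scale_correlation rescale the averaged covariance to unit
#'   diagonal before the graphical lasso?
#' @param ... passed to [graphical_lasso()].
#' @return numeric vector of length p(p-1)/2.
#' @export
epoch_to_network_vector <- function(epoch, lam = 0.1, spec = kernel_spec(),
                                    center = TRUE, scale_correlation = TRUE,
                                    ...) {
  X <- if (inherits(epoch, "eeg_epoch")) epoch$data else as.matrix(epoch)
  S <- averaged_covariance(X, spec = spec, center = center)
  if (scale_correlation) {
    s <- 1 / sqrt(pmax(diag(S), 1e-12))
    S <- S * outer(s, s)
  }
  fit <- graphical_lasso(S, lam, ...)
  vectorize_upper(partial_correlation(fit))
}

#' Build the predictor matrix for classification
#'
#' Rows are epochs, ordered preictal block first then interictal block,
#' with matching binary labels Z. Three feature modes:
#' \describe{
#'   \item{network}{vectorized per-epoch partial-correlation networks,
#'     d = p(p-1)/2 columns (the network predictor matrix);}
#'   \item{raw}{each epoch flattened row-major to length p*q;}
#'   \item{combined}{column-wise concatenation `[network | raw]`.}
#' }
#'
#' @param epochs an `epoch_set`.
#' @param mode `"network"`, `"raw"` or `"combined"`.
#' @param lam,spec,center,scale_correlation stage-1 settings, see
#'   [epoch_to_network_vector()].
#' @return An object of class `network_predictor_matrix`: `V` (n x d
#'   matrix), `Z` (labels), `feature_names`, `edge_names` (network-mode
#'   part only), `feature_mode`, plus the stage-1 settings.
#' @export
build_predictor_matrix <- function(epochs,
                                   mode = c("network", "raw", "combined"),
                                   lam = 0.1, spec = kernel_spec(),
                                   center = TRUE, scale_correlation = TRUE) {
  mode <- match.arg(mode)
  if (length(epochs$epochs) == 0) stop("epoch set is empty")
  dims <- vapply(epochs$epochs, function(e) dim(e$data), c(0L, 0L))
  if (length(unique(dims[1, ])) != 1L || length(unique(dims[2, ])) != 1L)
    stop("all epochs must share the same p and q")
  p <- dims[1, 1]; q <- dims[2, 1]

  labs <- vapply(epochs$epochs, function(e) e$label, 0L)
  ord <- order(labs, decreasing = TRUE)       # preictal block first
  eps <- epochs$epochs[ord]
  Z <- labs[ord]

  en <- edge_names(epochs$channel_labels)
  net <- NULL; raw <- NULL
  if (mode %in% c("network", "combined")) {
    net <- t(vapply(eps, function(e)
      epoch_to_network_vector(e$data, lam = lam, spec = spec, center = center,
                              scale_correlation = scale_correlation),
      numeric(p * (p - 1) / 2)))
    colnames(net) <- en
  }
  if (mode %in% c("raw", "combined")) {
    raw <- t(vapply(eps, function(e) as.vector(t(e$data)), numeric(p * q)))
    colnames(raw) <- paste0(rep(epochs$channel_labels, each = q),
                            "_t", rep(seq_len(q), p))
  }
  V <- switch(mode, network = net, raw = raw, combined = cbind(net, raw))
  structure(list(V = V, Z = Z, feature_names = colnames(V),
                 edge_names = en, feature_mode = mode, lam = lam,
                 kernel = spec, center = center,
                 scale_correlation = scale_correlation,
                 origin_sec = vapply(eps, function(e) e$origin_sec, 0)),
            class = "network_predictor_matrix")
}

#' @export
print.network_predictor_matrix <- function(x, ...) {
  cat(sprintf("<network_predictor_matrix> %d x %d (%s mode), n1 = %d, n2 = %d\n",
              nrow(x$V), ncol(x$V), x$feature_mode,
              sum(x$Z == 1), sum(x$Z == 0)))
  invisible(x)
}

#' Serialize a predictor matrix as CSV plus a JSON sidecar
#'
#' The CSV holds Z and the feature columns; the sidecar records the
#' feature mode, penalty, kernel spec, centering flag and edge names so a
#' downstream run is reproducible bit-for-bit.
#'
#' @param vm a `network_predictor_matrix`.
#' @param path CSV path; the sidecar is written as `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_predictor_matrix <- function(vm, path) {
  df <- data.frame(Z = vm$Z, vm$V, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  side <- list(feature_mode = vm$feature_mode, lam = vm$lam,
               kernel = unclass(vm$kernel), center = vm$center,
               scale_correlation = vm$scale_correlation,
               edge_names = vm$edge_names,
               feature_names = vm$feature_names)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a predictor matrix written by [write_predictor_matrix()]
#' @param path CSV path with `<path>.json` sidecar alongside.
#' @return A `network_predictor_matrix`.
#' @export
read_predictor_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  V <- as.matrix(df[, -1, drop = FALSE])
  structure(list(V = V, Z = df$Z, feature_names = colnames(V),
                 edge_names = side$edge_names,
                 feature_mode = side$feature_mode, lam = side$lam,
                 kernel = structure(side$kernel, class = "kernel_spec"),
                 center = side$center,
                 scale_correlation = side$scale_correlation),
            class = "network_predictor_matrix")
}
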