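#' Configuration for the matrix-normal epoch simulator
#'
#' Epochs are drawn from a matrix-normal model `X ~ MN(0, Sigma_T (x)
#' Sigma_S)`: `Sigma_S` is the spatial (electrode) covariance, the inverse
#' of a planted sparse precision matrix, and `Sigma_T` is an AR(1)
#' temporal covariance (`rho_T^|i-j|`) emulating within-epoch
#' autocorrelation. Preictal and interictal classes share a baseline
#' sparse precision support; the preictal class carries `n_diff`
#' additional edges of magnitude `delta`, the class-differential
#' connectivity the pipeline is meant to recover. Independent N(0,
#' noise_sd^2) observation noise is added on top.
#'
#' @param p electrodes per epoch.
#' @param q time points per epoch (seconds, after per-second averaging).
#' @param n1,n2 preictal / interictal epoch counts.
#' @param edge_prob baseline edge probability of the shared sparse support.
#' @param n_diff number of extra preictal-only (differential) edges.
#' @param delta off-diagonal magnitude of planted edges, on a scale chosen
#'   so partial correlations are interpretable (|delta| < 1).
#' @param rho_T AR(1) temporal correlation (|rho_T| < 1).
#' @param noise_sd observation-noise standard deviation.
#' @param seed integer seed.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(p = 10L, q = 60L, n1 = 60L, n2 = 60L,
                              edge_prob = 0.05, n_diff = 5L, delta = 0.4,
                              rho_T = 0.3, noise_sd = 0.1, seed = 1L) {
  stopifnot(p >= 2, q >= 2, n1 >= 0, n2 >= 0,
            edge_prob >= 0, edge_prob <= 1,
            abs(delta) < 1, abs(rho_T) < 1, noise_sd >= 0)
  if (n_diff > p * (p - 1) / 2)
    stop("n_diff exceeds the number of available edges")
  structure(list(p = as.integer(p), q = as.integer(q),
                 n1 = as.integer(n1), n2 = as.integer(n2),
                 edge_prob = edge_prob, n_diff = as.integer(n_diff),
                 delta = delta, rho_T = rho_T, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Planted preictal / interictal precision-matrix pair
#'
#' Builds a shared Erdos-Renyi off-diagonal support with entries
#' `+/- delta`, then adds `n_diff` extra edges (magnitude `delta`) to the
#' preictal matrix only. Both matrices receive the same diagonal,
#' `|min eigenvalue| + 1` computed over the two off-diagonal patterns, so
#' they are symmetric positive-definite and differ in exactly the
#' `n_diff` planted positions (a per-matrix diagonal would make every
#' entry class-differential after rescaling).
#'
#' @param cfg a [simulation_config()].
#' @return An object of class `ground_truth`: `omega_pre`, `omega_inter`
#'   (p x p SPD precision matrices) and `diff_edges` (2-column matrix of
#'   upper-triangle differential positions).
#' @export
make_precision_pair <- function(cfg) {
  p <- cfg$p
  ut <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
  with_seed(cfg$seed, {
    shared <- stats::runif(nrow(ut)) < cfg$edge_prob
    signs <- sample(c(-1, 1), nrow(ut), replace = TRUE)
    avail <- which(!shared)
    if (cfg$n_diff > length(avail))
      stop("n_diff infeasible: only ", length(avail),
           " non-baseline edges available")
    extra <- if (cfg$n_diff > 0) sample(avail, cfg$n_diff) else integer()

    off_inter <- matrix(0, p, p)
    off_inter[ut[shared, , drop = FALSE]] <- cfg$delta * signs[shared]
    off_inter <- off_inter + t(off_inter)
    off_pre <- off_inter
    add <- matrix(0, p, p)
    add[ut[extra, , drop = FALSE]] <- cfg$delta * signs[extra]
    off_pre <- off_pre + add + t(add)

    m <- min(eigen(off_pre, symmetric = TRUE, only.values = TRUE)$values,
             eigen(off_inter, symmetric = TRUE, only.values = TRUE)$values)
    dg <- abs(min(m, 0)) + 1
    omega_pre <- off_pre; diag(omega_pre) <- dg
    omega_inter <- off_inter; diag(omega_inter) <- dg

    structure(list(omega_pre = omega_pre, omega_inter = omega_inter,
                   diff_edges = ut[extra, , drop = FALSE]),
              class = "ground_truth")
  })
}

#' Draw from a matrix normal distribution
#'
#' Samples `X = M + A G B'` with `A A' = sigma_S`, `B B' = sigma_T`
#' (Cholesky factors) and G a p x q matrix of independent standard
#' normals, so `vec(X)` has covariance `sigma_T (x) sigma_S`. With
#' `n_draws > 1` all draws are generated in one vectorized pass through
#' the Kronecker identity `vec(A G B') = (B (x) A) vec(G)`.
#'
#' @param M p x q mean matrix (or a scalar, recycled).
#' @param sigma_S p x p SPD spatial covariance.
#' @param sigma_T q x q SPD temporal covariance.
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @param n_draws number of draws.
#' @return A p x q matrix, or a p x q x n_draws array when `n_draws > 1`.
#' @export
sample_matrix_normal <- function(M, sigma_S, sigma_T, seed = NULL,
                                 n_draws = 1L) {
  p <- nrow(sigma_S); q <- nrow(sigma_T)
  A <- t(tryCatch(chol(sigma_S),
                  error = function(e) stop("sigma_S must be SPD")))
  Bm <- t(tryCatch(chol(sigma_T),
                   error = function(e) stop("sigma_T must be SPD")))
  if (length(M) == 1) M <- matrix(M, p, q)
  if (!all(dim(M) == c(p, q))) stop("M must be p x q")
  draw <- function() {
    if (n_draws == 1L) {
      G <- matrix(stats::rnorm(p * q), p, q)
      M + A %*% G %*% t(Bm)
    } else {
      # vec(A G B') = (B (x) A) vec(G): one matmul for all draws
      L <- kronecker(Bm, A)
      G <- matrix(stats::rnorm(p * q * n_draws), p * q, n_draws)
      array(as.vector(M) + L %*% G, c(p, q, n_draws))
    }
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

ar1_covariance <- function(q, rho) {
  idx <- seq_len(q)
  rho^abs(outer(idx, idx, "-"))
}

#' Simulate a labeled epoch set with planted differential connectivity
#'
#' Draws `n1` preictal epochs with spatial covariance
#' `solve(omega_pre)` and `n2` interictal epochs with
#' `solve(omega_inter)`, each with AR(1) temporal covariance and additive
#' observation noise, labeled 1/0. Deterministic given `cfg$seed`.
#'
#' @param cfg a [simulation_config()].
#' @param truth optionally, a precomputed [make_precision_pair()] result.
#' @return A list: `epochs` (an `epoch_set`) and `truth` (a
#'   `ground_truth`).
#' @export
simulate_epoch_set <- function(cfg, truth = NULL) {
  if (is.null(truth)) truth <- make_precision_pair(cfg)
  sigma_pre <- chol2inv(chol(truth$omega_pre))
  sigma_inter <- chol2inv(chol(truth$omega_inter))
  sigma_T <- ar1_covariance(cfg$q, cfg$rho_T)

  epochs <- with_seed(cfg$seed + 1L, {
    out <- vector("list", cfg$n1 + cfg$n2)
    for (i in seq_len(cfg$n1 + cfg$n2)) {
      pre <- i <= cfg$n1
      X <- sample_matrix_normal(0, if (pre) sigma_pre else sigma_inter,
                                sigma_T)
      if (cfg$noise_sd > 0)
        X <- X + matrix(stats::rnorm(cfg$p * cfg$q, sd = cfg$noise_sd),
                        cfg$p, cfg$q)
      out[[i]] <- new_epoch(X, as.integer(pre), "synthetic", i,
                            origin_sec = (i - 1) * cfg$q)
    }
    out
  })
  list(epochs = new_epoch_set(epochs, paste0("E", seq_len(cfg$p))),
       truth = truth)
}

#' Simulate a toy continuous recording with seizure annotations
#'
#' Gaussian-noise channels at the given sampling rate plus a validated
#' annotation table: a fixture for exercising the state-labeling and
#' epoching arithmetic end to end (no EEG waveform realism intended).
#'
#' @param plan 2-column matrix or data frame of seizure (onset, offset)
#'   seconds; may have zero rows.
#' @param duration_sec recording length in seconds.
#' @param fs sampling rate in Hz (integer).
#' @param p number of channels.
#' @param seed integer seed.
#' @return A list: `recording` (an [eeg_recording()]) and `annotation` (a
#'   [seizure_annotation()]).
#' @export
simulate_recording <- function(plan, duration_sec, fs = 256L, p = 21L,
                               seed = 1L) {
  plan <- as.matrix(plan)
  if (nrow(plan) > 0 &&
      (min(plan[, 1]) < 0 || max(plan[, 2]) > duration_sec))
    stop("seizure plan must lie within [0, duration_sec]")
  ann <- if (nrow(plan) > 0) seizure_annotation(plan[, 1], plan[, 2])
         else seizure_annotation()
  sig <- with_seed(seed,
                   matrix(stats::rnorm(p * fs * duration_sec), nrow = p))
  rec <- eeg_recording(sig, paste0("E", seq_len(p)), fs,
                       start_time_sec = 0, montage = "referential")
  list(recording = rec, annotation = ann)
}
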