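# Polynomial rolling hash over the serialized config: a light provenance
# fingerprint so every output artifact can be matched to the exact
# settings that made it. (Kept in doubles below 2^31 -- not cryptographic.)
config_hash <- function(cfg) {
  bytes <- utf8ToInt(paste(deparse(cfg), collapse = ""))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

default_run_config <- function() {
  list(recordings = list(),          # list of {path, start_time_sec, montage}
       annotations = NULL,           # CSV path
       out_dir = ".",
       channels = "chbmit21",        # preset name or character vector
       epoch_seconds = 60,
       preictal_minutes = 30,
       postictal_hours = 2,
       kernel = list(kernel = "gaussian", bandwidth = NULL,
                     bandwidth_rule = "power_third"),
       lam = 0.1,
       scale_correlation = TRUE,
       center = TRUE,
       feature_mode = "network",
       B = 100, k = 5, seed = 1,
       lambda_rule = "cv_once",
       patient_id = "patient")
}

#' Read a pipeline run configuration
#'
#' JSON (always) or YAML (when the `yaml` package is installed); keys
#' missing from the file fall back to package defaults. The effective
#' merged configuration is what [run_extract()] and [run_predict()] write
#' next to their outputs.
#'
#' @param path config file, or `NULL` for the defaults.
#' @return A named list of class `run_config`.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("YAML config requires the yaml package; use JSON instead")
      yaml::read_yaml(path)
    } else jsonlite::read_json(path, simplifyVector = TRUE)
    for (nm in names(user)) cfg[[nm]] <- user[[nm]]
  }
  structure(cfg, class = c("run_config", "list"))
}

resolve_channels <- function(channels) {
  if (is.character(channels) && length(channels) == 1 &&
      channels %in% c("chbmit21", "fhpku19"))
    channel_preset(channels) else as.character(channels)
}

resolve_kernel <- function(k) {
  kernel_spec(kernel = k$kernel %||% "gaussian",
              bandwidth = k$bandwidth,
              bandwidth_rule = k$bandwidth_rule %||% "power_third")
}

write_effective_config <- function(cfg, dir) {
  jsonlite::write_json(
    c(unclass(cfg), list(config_hash = config_hash(cfg),
                         package_version =
                           as.character(utils::packageVersion("seizconn")))),
    file.path(dir, "effective_config.json"),
    auto_unbox = TRUE, digits = NA, null = "null")
}

#' Extract labeled epochs from recordings on disk
#'
#' Reads every configured EDF recording (placed on the patient timeline by
#' its `start_time_sec`), restricts it to the configured channel set,
#' applies the preictal/interictal state rules over the whole timeline,
#' extracts per-second-averaged epochs, and writes the epoch set (manifest
#' plus signals) and the effective config to `cfg$out_dir`.
#'
#' @param cfg a `run_config` (see [read_run_config()]).
#' @return The combined `epoch_set`, invisibly; artifacts on disk.
#' @export
run_extract <- function(cfg) {
  if (length(cfg$recordings) == 0) stop("config lists no recordings")
  channels <- resolve_channels(cfg$channels)
  ann <- read_annotations(cfg$annotations)

  recs <- lapply(cfg$recordings, function(r) {
    select_channels(read_edf(r$path,
                             start_time_sec = r$start_time_sec %||% 0,
                             montage = r$montage %||% "referential"),
                    channels)
  })
  span_lo <- min(vapply(recs, function(r) r$start_time_sec, 0))
  span_hi <- max(vapply(recs, function(r)
    r$start_time_sec + recording_duration(r), 0))
  intervals <- label_states(ann, span_lo, span_hi,
                            preictal_minutes = cfg$preictal_minutes,
                            postictal_hours = cfg$postictal_hours)
  if (length(intervals$dropped_seizures))
    message("dropped close-spaced seizure(s): ",
            paste(intervals$dropped_seizures, collapse = ", "))

  sets <- lapply(recs, function(r)
    extract_epochs(r, intervals, epoch_seconds = cfg$epoch_seconds,
                   patient_id = cfg$patient_id))
  all_epochs <- do.call(c, lapply(sets, function(s) s$epochs))
  for (i in seq_along(all_epochs)) all_epochs[[i]]$epoch_index <- i
  es <- new_epoch_set(all_epochs, channels)

  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_epoch_set(es, cfg$out_dir)
  write_effective_config(cfg, cfg$out_dir)
  invisible(es)
}

#' Cross-validated prediction from an extracted epoch set
#'
#' Reads the epoch manifest written by [run_extract()] (or
#' [write_epoch_set()]), builds the configured predictor matrix, runs
#' stratified k-fold evaluation and writes `metrics.json` (SENS, FDR,
#' AUC, cutoff, confusion counts, protocol, config hash, seed) and
#' `edges.csv` (edges ranked by selection frequency psi) into
#' `cfg$out_dir`.
#'
#' @param cfg a `run_config`; `cfg$epochs_dir` defaults to `cfg$out_dir`.
#' @return The `cv_result`, invisibly; artifacts on disk.
#' @export
run_predict <- function(cfg) {
  epochs_dir <- cfg$epochs_dir %||% cfg$out_dir
  if (!file.exists(file.path(epochs_dir, "manifest.csv")))
    stop("no epoch manifest in ", epochs_dir, "; run the extract step first")
  es <- read_epoch_set(epochs_dir)
  if (min(es$n1, es$n2) < cfg$k)
    stop("insufficient epochs per class for ", cfg$k, "-fold CV: ",
         es$n1, " preictal, ", es$n2, " interictal")

  res <- cross_validate(es, mode = cfg$feature_mode, k = cfg$k, B = cfg$B,
                        lam = cfg$lam, spec = resolve_kernel(cfg$kernel),
                        center = cfg$center,
                        scale_correlation = cfg$scale_correlation,
                        seed = cfg$seed,
                        lambda_rule = cfg$lambda_rule)

  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  m <- res$metrics
  jsonlite::write_json(
    list(auc = m$auc, sens = m$sens, fdr = m$fdr, cutoff = m$cutoff,
         accuracy = m$accuracy, confusion = as.list(m$confusion),
         protocol = res$protocol, feature_mode = cfg$feature_mode,
         seed = cfg$seed, config_hash = config_hash(cfg),
         package_version = as.character(utils::packageVersion("seizconn"))),
    file.path(cfg$out_dir, "metrics.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(ranked_edges(res$importance),
                   file.path(cfg$out_dir, "edges.csv"), row.names = FALSE)
  write_effective_config(cfg, cfg$out_dir)
  invisible(res)
}
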