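#' Pipeline configuration
#'
#' All tunable stage parameters in one validated object, with defaults
#' matching the analysis the package documents: 0.05-35 Hz EEG band
#' down-sampled to 256 Hz, epochs -1 to +5 s with a -1 to 0 s baseline, ERD
#' rectangle 15-23 Hz x 0-1 s, alpha-band (8-13 Hz) synchronization over
#' central/centro-parietal/fronto-central homologues, 0.01-0.2 Hz
#' hemoglobin band with -2 to +10 s epochs, HBO peak feature, leave-one-out
#' cross-validation. Unknown keys are rejected.
#'
#' @param ... Overrides for any of the defaults; see the source of
#'   `pipeline_defaults()` for the full key list.
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- pipeline_defaults()
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad))
    stop(sprintf("unknown configuration key(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  defaults[names(over)] <- over
  structure(defaults, class = "pipeline_config")
}

pipeline_defaults <- function() {
  list(
    eeg_band = c(0.05, 35), eeg_fs_out = 256, eeg_channel = "Cz",
    epoch_window = c(-1, 5), baseline_window = c(-1, 0),
    ersp_freqs = seq(4, 30, by = 1), ersp_method = "stft",
    erd_band = c(15, 23), erd_window = c(0, 1),
    psi_band = c(8, 13),
    psi_pairs = list(c("C3", "C4"), c("CP3", "CP4"), c("FC3", "FC4")),
    fnirs_band = c(0.01, 0.2), fnirs_channels = fnirs_default_channels(),
    fnirs_window = c(-2, 10), fnirs_baseline = c(-2, 0),
    hbo_mode = "peak", hbo_window = c(0, 10),
    cv_scheme = "leave-one-out",
    seed = 1L, log_level = "info"
  )
}

#' Write a pipeline configuration to YAML
#' @param config A [pipeline_config()].
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#'
#' Round-trips losslessly with [write_config()]; unknown keys are rejected.
#'
#' @param path YAML path.
#' @return A [pipeline_config()].
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw <- lapply(raw, function(v) if (is.list(v) && all(lengths(v) > 1)) v else v)
  # YAML reads numeric vectors back as lists of scalars; restore vectors,
  # but keep list-of-vectors fields (psi_pairs) as lists.
  raw <- lapply(raw, function(v) {
    if (is.list(v) && all(vapply(v, length, 0L) == 1L)) unlist(v) else v
  })
  if (!is.null(raw$psi_pairs)) raw$psi_pairs <- lapply(raw$psi_pairs, unlist)
  do.call(pipeline_config, raw)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  cat(yaml::as.yaml(unclass(x)))
  invisible(x)
}

#' Run the full biomarker-to-balance pipeline
#'
#' For every subject the EEG chain (filter, down-sample, epoch at the
#' configured channel, ERSP, baseline normalization, ERD index) and the
#' fNIRS chain (band-pass, epoch + baseline correction, trial/channel
#' average, scalar HBO feature) are run, the resulting features are merged
#' with the clinical table (AGE, BBS), and the balance regression is fitted
#' and cross-validated. Alternatively, a precomputed feature table can be
#' passed directly via `features`, skipping the signal stages.
#'
#' @param subjects Data frame with columns `subject_id`, `eeg` (path stem
#'   for [read_eeg_csv()]) and `fnirs` (stem for [read_fnirs_csv()]).
#'   Ignored when `features` is given.
#' @param clinical Data frame (or CSV path) with columns `subject_id`,
#'   `AGE`, `BBS`. Ignored when `features` is given.
#' @param config A [pipeline_config()].
#' @param features Optional precomputed [feature_table()] (or CSV path).
#' @return A `pipeline_result`: `features`, `fit` ([fit_bbs_model()]),
#'   `cv` ([loo_cv()]), `config`, and `report` (plain-text summary echoing
#'   the configuration and the fitted model).
#' @examples
#' res <- run_pipeline(features = stroke_features())
#' cat(res$report)
#' @export
run_pipeline <- function(subjects = NULL, clinical = NULL,
                         config = pipeline_config(), features = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  log_lines <- character()
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    if (identical(config$log_level, "info")) message(line)
  }
  if (is.null(features)) {
    if (is.null(subjects) || is.null(clinical))
      stop("either `features` or both `subjects` and `clinical` are required",
           call. = FALSE)
    if (is.character(clinical)) clinical <- read.csv(clinical)
    names(clinical) <- tolower(names(clinical))
    if (!all(c("subject_id", "age", "bbs") %in% names(clinical)))
      stop("clinical table needs columns subject_id, age, bbs", call. = FALSE)
    missing_eeg <- subjects$subject_id[!file.exists(paste0(sub("\\.csv$", "", subjects$eeg), ".csv"))]
    missing_nir <- subjects$subject_id[!file.exists(paste0(sub("\\.(hbo\\.)?csv$", "", subjects$fnirs), ".hbo.csv"))]
    missing_cli <- setdiff(subjects$subject_id, clinical$subject_id)
    if (length(missing_eeg) || length(missing_nir) || length(missing_cli))
      stop(sprintf("missing inputs - EEG: [%s]; fNIRS: [%s]; clinical: [%s]",
                   paste(missing_eeg, collapse = ", "),
                   paste(missing_nir, collapse = ", "),
                   paste(missing_cli, collapse = ", ")), call. = FALSE)
    say("computing features for %d subject(s)", nrow(subjects))
    rows <- lapply(seq_len(nrow(subjects)), function(i) {
      sid <- subjects$subject_id[i]
      eeg <- read_eeg_csv(subjects$eeg[i])
      eeg <- suppressMessages(
        preprocess_eeg(eeg, band = config$eeg_band, fs_out = config$eeg_fs_out))
      ep <- epoch_eeg(eeg, channel = config$eeg_channel,
                      window = config$epoch_window)
      grid <- baseline_normalize(
        compute_ersp(ep, freqs = config$ersp_freqs, method = config$ersp_method),
        baseline_window = config$baseline_window)
      erd <- erd_index(grid, band = config$erd_band, window = config$erd_window)
      nir <- read_fnirs_csv(subjects$fnirs[i])
      nir <- bandpass_hemo(nir, band = config$fnirs_band)
      hep <- epoch_and_correct(nir, channels = config$fnirs_channels,
                               window = config$fnirs_window,
                               baseline = config$fnirs_baseline)
      hbo <- hbo_scalar(average_curve(hep), mode = config$hbo_mode,
                        window = config$hbo_window)
      say("  %s: ERD = %.4f, HBO(%s) = %.4f", sid, erd$value, config$hbo_mode, hbo)
      data.frame(subject_id = sid, ERD = erd$value, HBO = hbo)
    })
    feat <- do.call(rbind, rows)
    merged <- merge(feat, stats::setNames(clinical[c("subject_id", "age", "bbs")],
                                          c("subject_id", "AGE", "BBS")),
                    by = "subject_id", sort = FALSE)
    features <- feature_table(merged)
  } else {
    if (is.character(features)) features <- read_features(features)
    features <- feature_table(features, enforce_bbs = FALSE)
    say("using precomputed features for %d subject(s)", nrow(features))
  }
  fit <- fit_bbs_model(features)
  cv <- loo_cv(features)
  report <- pipeline_report(config, features, fit, cv, log_lines)
  structure(list(features = features, fit = fit, cv = cv,
                 config = config, report = report),
            class = "pipeline_result")
}

pipeline_report <- function(config, features, fit, cv, log_lines) {
  sm <- summarize_features(features)
  coef_lines <- sprintf("  %-9s %8.1f  (%.1f, %.1f)  p = %.3f",
                        names(fit$beta), fit$beta,
                        fit$ci95[, 1], fit$ci95[, 2], fit$p)
  paste(c("== balance biomarker pipeline report ==",
          "", "-- configuration --", yaml::as.yaml(unclass(config)),
          "-- stage log --", if (length(log_lines)) log_lines else "(none)",
          "", "-- feature summary (mean, sample sd) --",
          sprintf("  %-4s mean %8.3f  sd %8.3f", rownames(sm), sm$mean, sm$sd),
          "", "-- regression (coefficient, 95% CI, p) --", coef_lines,
          sprintf("  R^2 = %.3f, adjusted R^2 = %.3f", fit$r2, fit$r2_adj),
          "", sprintf("-- %s cross-validation --", cv$scheme),
          sprintf("  RMSE = %.2f BBS points over %d held-out predictions",
                  cv$rmse, length(cv$fold_predictions)),
          ""),
        collapse = "\n")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(x$report)
  invisible(x)
}
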