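#' Multi-channel EEG recording
#'
#' Container for a continuous EEG recording: a channels-by-time sample
#' matrix in microvolts, the sampling rate, 10/20-convention channel labels
#' and an event table of movement onsets.
#'
#' @param samples Numeric matrix, channels x time, microvolts.
#' @param fs Sampling rate in Hz (> 0).
#' @param channel_names Character vector of channel labels, one per row of
#'   `samples`. Labels are stored uppercased except for a trailing `z`
#'   (10/20 midline convention, e.g. `"Cz"`).
#' @param events Data frame with columns `onset`, `duration`, `trial_type`
#'   (seconds, 0-based time origin at recording start). Onsets must be
#'   strictly increasing and every `onset + duration` must fit inside the
#'   recording.
#' @return An object of class `eeg_recording`.
#' @seealso [simulate_eeg_trials()], [read_eeg_csv()]
#' @export
eeg_recording <- function(samples, fs, channel_names,
                          events = events_frame()) {
  samples <- as.matrix(samples)
  if (!is.numeric(samples)) stop("`samples` must be numeric", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a single positive number", call. = FALSE)
  channel_names <- normalize_1020(channel_names)
  if (length(channel_names) != nrow(samples))
    stop(sprintf("%d channel names for %d sample rows",
                 length(channel_names), nrow(samples)), call. = FALSE)
  events <- validate_events(events, ncol(samples) / fs)
  rownames(samples) <- channel_names
  structure(list(samples = samples, fs = fs, channel_names = channel_names,
                 events = events),
            class = "eeg_recording")
}

#' fNIRS hemoglobin recording
#'
#' Container for oxygenated (HBO) and deoxygenated (HBR) hemoglobin
#' concentration-change time series. Total hemoglobin is not stored: it is
#' materialized as `hbo + hbr` wherever needed, which keeps the HBT = HBO +
#' HBR identity true by construction.
#'
#' @param hbo,hbr Numeric matrices, channels x time, micromolar
#'   concentration change; identical shapes required.
#' @param fs Sampling rate in Hz (default fNIRS hardware rate is 20 Hz).
#' @param channel_names Source-detector labels (`"S2-D4"` style).
#' @param events As in [eeg_recording()].
#' @return An object of class `fnirs_recording`.
#' @seealso [simulate_fnirs_session()], [read_fnirs_csv()]
#' @export
fnirs_recording <- function(hbo, hbr, fs = 20, channel_names,
                            events = events_frame()) {
  hbo <- as.matrix(hbo); hbr <- as.matrix(hbr)
  if (!identical(dim(hbo), dim(hbr)))
    stop("`hbo` and `hbr` must have identical shape", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a single positive number", call. = FALSE)
  channel_names <- as.character(channel_names)
  if (length(channel_names) != nrow(hbo))
    stop(sprintf("%d channel names for %d channels",
                 length(channel_names), nrow(hbo)), call. = FALSE)
  events <- validate_events(events, ncol(hbo) / fs)
  rownames(hbo) <- rownames(hbr) <- channel_names
  structure(list(hbo = hbo, hbr = hbr, fs = fs,
                 channel_names = channel_names, events = events),
            class = "fnirs_recording")
}

validate_events <- function(events, duration_s) {
  if (is.null(events)) return(events_frame())
  events <- as.data.frame(events)
  need <- c("onset", "duration", "trial_type")
  if (!all(need %in% names(events)))
    stop("events need columns onset, duration, trial_type", call. = FALSE)
  events <- events[, need]
  if (nrow(events)) {
    if (any(diff(events$onset) <= 0))
      stop("event onsets must be strictly increasing", call. = FALSE)
    if (any(events$onset + events$duration > duration_s + 1e-9))
      stop("an event extends past the end of the recording", call. = FALSE)
  }
  events
}

# Uppercase 10/20 labels but keep the midline 'z' lowercase: cz -> Cz.
normalize_1020 <- function(x) {
  x <- toupper(as.character(x))
  sub("Z$", "z", x)
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channel(s) x %d samples @ %g Hz (%.1f s), %d event(s)\n",
              nrow(x$samples), ncol(x$samples), x$fs, ncol(x$samples) / x$fs,
              nrow(x$events)))
  cat(" channels:", paste(x$channel_names, collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.fnirs_recording <- function(x, ...) {
  cat(sprintf("<fnirs_recording> %d channel(s) x %d samples @ %g Hz (%.1f s), %d event(s)\n",
              nrow(x$hbo), ncol(x$hbo), x$fs, ncol(x$hbo) / x$fs,
              nrow(x$events)))
  invisible(x)
}
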