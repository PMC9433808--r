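#' Band-pass filter and down-sample an EEG recording
#'
#' Zero-phase Butterworth filtering (cascaded high-pass and low-pass stages,
#' each applied forward-backward) followed by decimation to `fs_out`. The
#' pass band already removes everything above the output Nyquist, so
#' integer-ratio decimation keeps every `fs / fs_out`-th sample. Event
#' onsets are stored in seconds and therefore carry over unchanged.
#'
#' The pipeline assumes its input has already been cleaned of ocular and
#' muscular artifacts; no automatic artifact rejection is applied here, and
#' a message says so.
#'
#' @param rec An [eeg_recording()].
#' @param band Pass band, Hz (default 0.05-35).
#' @param fs_out Output sampling rate, Hz (default 256); must not exceed the
#'   input rate, and the band's upper edge must be below `fs_out / 2`.
#' @param order Butterworth order per stage.
#' @return A filtered, down-sampled [eeg_recording()].
#' @export
preprocess_eeg <- function(rec, band = c(0.05, 35), fs_out = 256, order = 4) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (fs_out > rec$fs)
    stop("`fs_out` must not exceed the recording rate", call. = FALSE)
  assert_band(band, fs_out, "band")
  message("preprocess_eeg: no automatic artifact rejection applied; ",
          "input is assumed artifact-cleaned")
  filt <- bandpass_rows(rec$samples, rec$fs, band, order = order)
  ratio <- rec$fs / fs_out
  if (abs(ratio - round(ratio)) < 1e-9) {
    keep <- seq(1L, ncol(filt), by = round(ratio))
    out <- filt[, keep, drop = FALSE]
  } else {
    warning(sprintf("non-integer decimation ratio %.4f: resampling %g -> %g Hz",
                    ratio, rec$fs, fs_out))
    out <- t(apply(filt, 1L, signal::resample,
                   p = round(fs_out), q = round(rec$fs)))
  }
  eeg_recording(out, fs = fs_out, channel_names = rec$channel_names,
                events = rec$events)
}

#' Cut single-channel epochs around movement onsets
#'
#' One row per event, a verbatim slice of the recording (no detrending).
#' Sample windows are half-open: an epoch covers
#' `[onset + window[1], onset + window[2])`. Events whose window would run
#' past either edge of the recording are dropped with a message, not an
#' error.
#'
#' @param rec An [eeg_recording()].
#' @param channel Channel label to epoch (default `"Cz"`).
#' @param window Epoch window in seconds relative to onset (default -1 to
#'   +5; the first second is the baseline).
#' @return An object of class `eeg_epochs`: fields `data` (trials x time
#'   matrix), `fs`, `times` (seconds relative to onset), `t0_index` (sample
#'   index of onset, 1-based), `window`, `channel`, `n_dropped`.
#' @export
epoch_eeg <- function(rec, channel = "Cz", window = c(-1, 5)) {
  stopifnot(inherits(rec, "eeg_recording"))
  assert_interval(window, "window")
  channel <- normalize_1020(channel)
  if (!channel %in% rec$channel_names)
    stop(sprintf("channel \"%s\" not present in the recording", channel),
         call. = FALSE)
  if (!nrow(rec$events)) stop("recording has no events", call. = FALSE)
  x <- rec$samples[channel, ]
  fs <- rec$fs
  len <- round((window[2] - window[1]) * fs)
  starts <- round(rec$events$onset * fs) + round(window[1] * fs) + 1L
  ok <- starts >= 1L & (starts + len - 1L) <= length(x)
  if (any(!ok))
    message(sprintf("epoch_eeg: dropped %d event(s) too close to a recording edge",
                    sum(!ok)))
  if (!any(ok)) stop("no event fits inside the recording", call. = FALSE)
  data <- t(vapply(starts[ok], function(s) x[s:(s + len - 1L)], numeric(len)))
  structure(list(data = data, fs = fs,
                 times = window[1] + (0:(len - 1L)) / fs,
                 t0_index = -round(window[1] * fs) + 1L,
                 window = window, channel = channel,
                 n_dropped = sum(!ok)),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  cat(sprintf("<eeg_epochs> %s: %d trial(s) x %d samples @ %g Hz, window [%g, %g) s (%d dropped)\n",
              x$channel, nrow(x$data), ncol(x$data), x$fs,
              x$window[1], x$window[2], x$n_dropped))
  invisible(x)
}

#' Event-related spectral perturbation (trial-averaged time-frequency power)
#'
#' For each trial a time-frequency amplitude estimate `F_k(f, t)` is formed,
#' and the ERSP is the mean over trials of `|F_k|^2`. The default estimator
#' is a short-time Fourier transform: Hann window of `window_s` seconds,
#' hop of 1/16 window, with the windowed DFT evaluated directly at the
#' requested frequencies and amplitude-normalized so a unit sinusoid yields
#' power near 1. A Morlet-wavelet estimator is available as an alternative.
#'
#' @param ep An [epoch_eeg()] result.
#' @param freqs Frequencies of interest, Hz (all below Nyquist).
#' @param method `"stft"` (default) or `"morlet"`.
#' @param window_s STFT window length, seconds.
#' @param morlet_cycles Number of cycles of the Morlet wavelet.
#' @return An object of class `ersp_grid`: `power` (frequency x time),
#'   `freqs`, `times` (seconds relative to onset), `n_trials`,
#'   `normalized = FALSE`, `baseline_per_freq = NULL`, `method`.
#' @export
compute_ersp <- function(ep, freqs = seq(4, 30, by = 1),
                         method = c("stft", "morlet"),
                         window_s = 0.5, morlet_cycles = 7) {
  stopifnot(inherits(ep, "eeg_epochs"))
  method <- match.arg(method)
  if (any(freqs >= ep$fs / 2))
    stop(sprintf("requested frequency above the Nyquist limit %g Hz", ep$fs / 2),
         call. = FALSE)
  if (any(freqs <= 0)) stop("frequencies must be > 0", call. = FALSE)
  if (method == "stft") grid <- ersp_stft(ep, freqs, window_s)
  else grid <- ersp_morlet(ep, freqs, morlet_cycles)
  structure(c(grid, list(n_trials = nrow(ep$data), normalized = FALSE,
                         baseline_per_freq = NULL, n_baseline_bins = NULL,
                         method = method)),
            class = "ersp_grid")
}

ersp_stft <- function(ep, freqs, window_s) {
  fs <- ep$fs
  L <- round(window_s * fs)
  nt <- ncol(ep$data)
  if (L > nt) stop("STFT window longer than the epoch", call. = FALSE)
  hop <- max(1L, round(L / 16))
  starts <- seq(1L, nt - L + 1L, by = hop)
  centers <- ep$times[1] + (starts - 1L + (L - 1) / 2) / fs
  hann <- 0.5 * (1 - cos(2 * pi * (0:(L - 1)) / (L - 1)))
  # Direct windowed DFT at the requested frequencies, scaled so a unit
  # sinusoid at f gives |F| ~ 1.
  E <- exp(-2i * pi * outer(freqs, (0:(L - 1)) / fs)) / (sum(hann) / 2)
  idx <- outer(0:(L - 1L), starts, "+")
  P <- matrix(0, length(freqs), length(starts))
  for (k in seq_len(nrow(ep$data))) {
    seg <- matrix(ep$data[k, ][idx], nrow = L) * hann
    P <- P + Mod(E %*% seg)^2
  }
  list(power = P / nrow(ep$data), freqs = freqs, times = centers)
}

ersp_morlet <- function(ep, freqs, cycles) {
  fs <- ep$fs
  nt <- ncol(ep$data)
  P <- matrix(0, length(freqs), nt)
  for (j in seq_along(freqs)) {
    f <- freqs[j]
    sd_t <- cycles / (2 * pi * f)
    half <- ceiling(3.5 * sd_t * fs)
    tt <- (-half:half) / fs
    w <- exp(2i * pi * f * tt) * exp(-tt^2 / (2 * sd_t^2))
    w <- w / sum(Mod(w)) * 2          # unit-sinusoid amplitude ~ 1
    for (k in seq_len(nrow(ep$data))) {
      re <- stats::filter(ep$data[k, ], Re(w), sides = 2)
      im <- stats::filter(ep$data[k, ], Im(w), sides = 2)
      P[j, ] <- P[j, ] + (re^2 + im^2)
    }
  }
  keep <- which(!is.na(P[1, ]) & !is.na(P[length(freqs), ]))
  list(power = P[, keep, drop = FALSE] / nrow(ep$data),
       freqs = freqs, times = ep$times[keep])
}

#' Subtractive baseline normalization of an ERSP grid
#'
#' For every frequency, the mean power over the baseline time bins is
#' subtracted from the whole row (subtraction, not a dB ratio), so that the
#' per-frequency mean over the baseline window is exactly zero afterwards.
#' The per-frequency baseline and the number of baseline bins are stored on
#' the grid. A dB-ratio mode exists behind `mode = "db"` but is never the
#' default.
#'
#' @param grid An unnormalized `ersp_grid`.
#' @param baseline_window Baseline interval in seconds relative to onset
#'   (default -1 to 0); half-open `[start, end)` on bin centers.
#' @param mode `"subtract"` (default) or `"db"` (10 log10 power / baseline).
#' @return The normalized `ersp_grid` (`normalized = TRUE`).
#' @export
baseline_normalize <- function(grid, baseline_window = c(-1, 0),
                               mode = c("subtract", "db")) {
  stopifnot(inherits(grid, "ersp_grid"))
  mode <- match.arg(mode)
  if (isTRUE(grid$normalized))
    stop("grid is already baseline-normalized", call. = FALSE)
  assert_interval(baseline_window, "baseline_window")
  bins <- grid$times >= baseline_window[1] & grid$times < baseline_window[2]
  if (!any(bins))
    stop("baseline window contains no time bins of the grid", call. = FALSE)
  base <- rowMeans(grid$power[, bins, drop = FALSE])
  grid$power <- switch(mode,
    subtract = grid$power - base,
    db = 10 * log10(sweep(grid$power, 1L, base, "/")))
  grid$baseline_per_freq <- base
  grid$n_baseline_bins <- sum(bins)
  grid$baseline_window <- baseline_window
  grid$normalized <- TRUE
  grid$norm_mode <- mode
  grid
}

#' @export
print.ersp_grid <- function(x, ...) {
  cat(sprintf("<ersp_grid> %d freq x %d time bins (%g-%g Hz, %.2f-%.2f s), %d trial(s), %s%s\n",
              length(x$freqs), length(x$times), min(x$freqs), max(x$freqs),
              min(x$times), max(x$times), x$n_trials, x$method,
              if (isTRUE(x$normalized)) ", baseline-normalized" else ""))
  invisible(x)
}

#' Scalar ERD index: mean negative normalized power in a band-time rectangle
#'
#' The index is the arithmetic mean of the strictly negative normalized-ERSP
#' bins inside the band x window rectangle (default 15-23 Hz, 0-1 s after
#' onset); positive bins are excluded, not zeroed. When the rectangle holds
#' no negative bin at all, the index is 0 with `empty_flag` set, so the
#' feature stays defined (and auditable) for every subject.
#'
#' @param grid A baseline-normalized `ersp_grid`.
#' @param band Frequency band, Hz, inclusive at both edges.
#' @param window Time window, seconds, half-open `[start, end)`.
#' @return An object of class `erd_index`: `value` (<= 0, power units),
#'   `band`, `window`, `n_negative_bins`, `empty_flag`. `as.numeric()`
#'   extracts the value.
#' @export
erd_index <- function(grid, band = c(15, 23), window = c(0, 1)) {
  stopifnot(inherits(grid, "ersp_grid"))
  if (!isTRUE(grid$normalized))
    stop("`grid` must be baseline-normalized first", call. = FALSE)
  assert_interval(band, "band")
  assert_interval(window, "window")
  fr <- grid$freqs >= band[1] & grid$freqs <= band[2]
  tw <- grid$times >= window[1] & grid$times < window[2]
  if (!any(fr) || !any(tw))
    stop("the band x window rectangle contains no grid bins", call. = FALSE)
  vals <- grid$power[fr, tw]
  neg <- vals[vals < 0]
  structure(list(value = if (length(neg)) mean(neg) else 0,
                 band = band, window = window,
                 n_negative_bins = length(neg),
                 empty_flag = length(neg) == 0L),
            class = "erd_index")
}

#' @export
as.numeric.erd_index <- function(x, ...) x$value

#' @export
print.erd_index <- function(x, ...) {
  cat(sprintf("<erd_index> %.4f (%d negative bin(s), %g-%g Hz x %g-%g s%s)\n",
              x$value, x$n_negative_bins, x$band[1], x$band[2],
              x$window[1], x$window[2],
              if (x$empty_flag) ", no negative bins" else ""))
  invisible(x)
}
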