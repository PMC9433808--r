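#' Band-pass filter hemoglobin time series
#'
#' Zero-phase Butterworth filtering of HBO and HBR independently to the
#' 0.01-0.2 Hz band, attenuating slow drift and cardiac/respiratory
#' oscillations. The very low high-pass edge needs long reflective padding
#' (three filter time constants), which in turn needs a recording at least
#' three time constants long.
#'
#' @param rec An [fnirs_recording()].
#' @param band Pass band, Hz (default 0.01-0.2).
#' @param order Butterworth order per stage (default 3).
#' @return The filtered [fnirs_recording()].
#' @export
bandpass_hemo <- function(rec, band = c(0.01, 0.2), order = 3) {
  stopifnot(inherits(rec, "fnirs_recording"))
  assert_band(band, rec$fs, "band")
  dur <- ncol(rec$hbo) / rec$fs
  if (dur < 3 / band[1])
    stop(sprintf("recording of %.1f s is shorter than 3 filter time constants (%.1f s) of the %g Hz edge",
                 dur, 3 / band[1], band[1]), call. = FALSE)
  rec$hbo <- bandpass_rows(rec$hbo, rec$fs, band, order = order)
  rec$hbr <- bandpass_rows(rec$hbr, rec$fs, band, order = order)
  rownames(rec$hbo) <- rownames(rec$hbr) <- rec$channel_names
  rec
}

#' Epoch hemoglobin series and subtract the per-trial baseline
#'
#' Cuts per-trial slices of HBO and HBR for the requested channels
#' (default the eight sensorimotor channels), subtracts the per-trial,
#' per-channel mean of the baseline window from each slice, and materializes
#' HBT as HBO + HBR after correction. A requested channel that is missing is
#' an error naming it; silently analysing a different channel set would be
#' worse than failing.
#'
#' @param rec An [fnirs_recording()] with events.
#' @param channels Channel labels to use.
#' @param window Epoch window, seconds relative to onset (default -2 to +10).
#' @param baseline Baseline window, seconds (default -2 to 0), half-open.
#' @return A `hemo_epochs` object: `hbo`, `hbr`, `hbt` are
#'   trials x time x channel arrays; plus `fs`, `times`, `window`,
#'   `baseline_window`, `channels_used`, `n_dropped`.
#' @export
epoch_and_correct <- function(rec, channels = fnirs_default_channels(),
                              window = c(-2, 10), baseline = c(-2, 0)) {
  stopifnot(inherits(rec, "fnirs_recording"))
  assert_interval(window, "window")
  assert_interval(baseline, "baseline")
  missing <- setdiff(channels, rec$channel_names)
  if (length(missing))
    stop(sprintf("channel(s) not in the recording: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  if (!nrow(rec$events)) stop("recording has no events", call. = FALSE)
  fs <- rec$fs
  len <- round((window[2] - window[1]) * fs)
  times <- window[1] + (0:(len - 1L)) / fs
  starts <- round(rec$events$onset * fs) + round(window[1] * fs) + 1L
  ntime <- ncol(rec$hbo)
  ok <- starts >= 1L & (starts + len - 1L) <= ntime
  if (any(!ok))
    message(sprintf("epoch_and_correct: dropped %d event(s) too close to a recording edge",
                    sum(!ok)))
  if (!any(ok)) stop("no event fits inside the recording", call. = FALSE)
  starts <- starts[ok]
  bbin <- times >= baseline[1] & times < baseline[2]
  if (!any(bbin)) stop("baseline window contains no samples", call. = FALSE)
  cut <- function(mat) {
    arr <- array(NA_real_, c(length(starts), len, length(channels)),
                 dimnames = list(NULL, NULL, channels))
    for (ci in seq_along(channels)) {
      x <- mat[channels[ci], ]
      for (k in seq_along(starts)) {
        seg <- x[starts[k]:(starts[k] + len - 1L)]
        arr[k, , ci] <- seg - mean(seg[bbin])
      }
    }
    arr
  }
  hbo <- cut(rec$hbo); hbr <- cut(rec$hbr)
  structure(list(hbo = hbo, hbr = hbr, hbt = hbo + hbr,
                 fs = fs, times = times, window = window,
                 baseline_window = baseline, channels_used = channels,
                 n_dropped = sum(!ok)),
            class = "hemo_epochs")
}

#' @export
print.hemo_epochs <- function(x, ...) {
  cat(sprintf("<hemo_epochs> %d trial(s) x %d samples x %d channel(s) @ %g Hz, window [%g, %g) s\n",
              dim(x$hbo)[1], dim(x$hbo)[2], dim(x$hbo)[3], x$fs,
              x$window[1], x$window[2]))
  invisible(x)
}

#' Trial- and channel-averaged hemoglobin time courses
#'
#' Averages each species over trials per channel, then over channels (the
#' two orders coincide here because every channel carries the same trials;
#' with unequal trial counts the per-channel average would come first).
#'
#' @param ep A [epoch_and_correct()] result.
#' @return A `hemo_curve`: numeric vectors `hbo`, `hbr`, `hbt` on the grid
#'   `times`, plus `fs` and `n_trials`.
#' @export
average_curve <- function(ep) {
  stopifnot(inherits(ep, "hemo_epochs"))
  avg <- function(a) {
    per_ch <- apply(a, c(2, 3), mean)  # time x channel
    rowMeans(per_ch)
  }
  structure(list(hbo = avg(ep$hbo), hbr = avg(ep$hbr), hbt = avg(ep$hbt),
                 times = ep$times, fs = ep$fs, n_trials = dim(ep$hbo)[1]),
            class = "hemo_curve")
}

#' @export
print.hemo_curve <- function(x, ...) {
  cat(sprintf("<hemo_curve> %d samples @ %g Hz over [%g, %g] s, %d trial(s); HBO peak %.3f\n",
              length(x$hbo), x$fs, min(x$times), max(x$times), x$n_trials,
              max(x$hbo)))
  invisible(x)
}

#' Scalar hemoglobin feature: peak or area of the averaged curve
#'
#' `mode = "peak"` takes the maximum of the averaged curve over the task
#' window; `mode = "area"` the trapezoidal signed integral against the
#' horizontal axis (negative lobes subtract; set `absolute = TRUE` for the
#' unsigned variant). The regression predictor defaults to the peak.
#'
#' @param curve A [average_curve()] result.
#' @param mode `"peak"` or `"area"`.
#' @param window Feature window, seconds (default 0-10), inclusive.
#' @param species Which curve: `"hbo"` (default), `"hbr"` or `"hbt"`.
#' @param absolute For `mode = "area"`, integrate `|curve|` instead.
#' @return A single number: micromolar (peak) or micromolar-seconds (area).
#' @export
hbo_scalar <- function(curve, mode = c("peak", "area"), window = c(0, 10),
                       species = c("hbo", "hbr", "hbt"), absolute = FALSE) {
  stopifnot(inherits(curve, "hemo_curve"))
  mode <- match.arg(mode)
  species <- match.arg(species)
  assert_interval(window, "window")
  # a half-open epoch window ends one sample before its nominal edge, so
  # allow the feature window to reach up to one sample period past the grid
  if (window[1] < min(curve$times) - 1e-9 ||
      window[2] > max(curve$times) + 1 / curve$fs + 1e-9)
    stop("feature window lies outside the curve support", call. = FALSE)
  sel <- curve$times >= window[1] & curve$times <= window[2]
  y <- curve[[species]][sel]
  t <- curve$times[sel]
  if (mode == "peak") max(y)
  else trapezoid(t, if (absolute) abs(y) else y)
}
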