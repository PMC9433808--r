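#' Instantaneous phase of band-limited EEG channels
#'
#' Each channel is zero-phase band-pass filtered to the band of interest and
#' the instantaneous phase is taken from the analytic signal (Hilbert
#' transform). An edge trim of one filter settling length (1.5 cycles of the
#' band's low edge) is recorded and excluded by the downstream
#' synchronization computation, where filter transients make the phase
#' unreliable.
#'
#' @param rec An [eeg_recording()].
#' @param band Band of interest, Hz (default alpha, 8-13).
#' @param order Butterworth order per filter stage.
#' @return A `phase_series`: `phase` (channels x time, radians in
#'   `(-pi, pi]`), `band`, `fs`, `trim` (samples excluded at each edge),
#'   `channel_names`, `events`.
#' @export
instantaneous_phase <- function(rec, band = c(8, 13), order = 4) {
  stopifnot(inherits(rec, "eeg_recording"))
  assert_band(band, rec$fs, "band")
  sds <- apply(rec$samples, 1L, stats::sd)
  if (any(sds == 0))
    stop(sprintf("channel(s) %s are constant: phase is undefined for a zero signal",
                 paste(rec$channel_names[sds == 0], collapse = ", ")),
         call. = FALSE)
  filt <- bandpass_rows(rec$samples, rec$fs, band, order = order)
  phase <- t(apply(filt, 1L, function(x) Arg(analytic_signal(x))))
  trim <- ceiling(1.5 / band[1] * rec$fs)
  phase_series(phase, fs = rec$fs, band = band, trim = trim,
               channel_names = rec$channel_names, events = rec$events)
}

#' Construct a phase series directly
#'
#' Low-level constructor, mainly useful for feeding known phases into
#' [psi()].
#'
#' @param phase Channels x time matrix of phases, radians; values are
#'   wrapped into `(-pi, pi]`.
#' @param fs Sampling rate, Hz.
#' @param band Band of interest, Hz (metadata).
#' @param trim Samples excluded at each edge (default 0).
#' @param channel_names Channel labels.
#' @param events Event table (optional).
#' @return A `phase_series` object.
#' @export
phase_series <- function(phase, fs, band = c(NA_real_, NA_real_), trim = 0L,
                         channel_names = rownames(phase),
                         events = events_frame()) {
  phase <- as.matrix(phase)
  if (is.null(channel_names))
    channel_names <- sprintf("CH%d", seq_len(nrow(phase)))
  # wrap into (-pi, pi]
  phase <- -((-phase + pi) %% (2 * pi) - pi)
  rownames(phase) <- channel_names
  structure(list(phase = phase, fs = fs, band = band, trim = as.integer(trim),
                 channel_names = channel_names, events = events),
            class = "phase_series")
}

#' @export
print.phase_series <- function(x, ...) {
  cat(sprintf("<phase_series> %d channel(s) x %d samples @ %g Hz, band %g-%g Hz, trim %d\n",
              nrow(x$phase), ncol(x$phase), x$fs, x$band[1], x$band[2], x$trim))
  invisible(x)
}

#' Phase synchronization index of a channel pair
#'
#' The PSI is the resultant length of the instantaneous phase-difference
#' distribution: with `d(t) = phase_x(t) - phase_y(t)`,
#' `PSI = sqrt(mean(cos d)^2 + mean(sin d)^2)`, a number in `[0, 1]`.
#' 1 means complete synchronization, 0 complete desynchronization.
#'
#' @param ph A `phase_series`.
#' @param pair Length-2 vector of channel labels (or indices).
#' @param window Optional time window in seconds from recording start; the
#'   average runs over its intersection with the trimmed support. `NULL`
#'   (default) uses the whole trimmed support. A list of windows pools the
#'   samples of all of them (used for per-trial task intervals).
#' @return A `psi_result` with fields `pairs`, `values`, `band`, `window`.
#' @export
psi <- function(ph, pair, window = NULL) {
  stopifnot(inherits(ph, "phase_series"), length(pair) == 2L)
  idx <- match_channels(ph, pair)
  n <- ncol(ph$phase)
  support <- (ph$trim + 1L):(n - ph$trim)
  if (!is.null(window)) {
    wins <- if (is.list(window)) window else list(window)
    sel <- integer()
    for (w in wins) {
      assert_interval(w, "window")
      sel <- c(sel, seq.int(max(1L, floor(w[1] * ph$fs) + 1L),
                            min(n, ceiling(w[2] * ph$fs))))
    }
    support <- intersect(support, unique(sel))
  }
  if (!length(support))
    stop("window is empty after edge trimming", call. = FALSE)
  d <- ph$phase[idx[1], support] - ph$phase[idx[2], support]
  val <- sqrt(mean(cos(d))^2 + mean(sin(d))^2)
  structure(list(pairs = list(ph$channel_names[idx]), values = val,
                 band = ph$band,
                 window = if (is.null(window)) range(support / ph$fs) else window),
            class = "psi_result")
}

match_channels <- function(ph, pair) {
  if (is.numeric(pair)) {
    idx <- as.integer(pair)
    if (any(idx < 1L | idx > nrow(ph$phase)))
      stop("channel index out of range", call. = FALSE)
    return(idx)
  }
  pair <- normalize_1020(pair)
  idx <- match(pair, ph$channel_names)
  if (anyNA(idx))
    stop(sprintf("unknown channel label(s): %s",
                 paste(pair[is.na(idx)], collapse = ", ")), call. = FALSE)
  idx
}

#' @export
print.psi_result <- function(x, ...) {
  lab <- vapply(x$pairs, paste, "", collapse = "-")
  cat("<psi_result>\n")
  for (i in seq_along(lab)) cat(sprintf("  %s: %.4f\n", lab[i], x$values[i]))
  if (!is.null(x$inter_psi)) cat(sprintf("  mean inter-PSI: %.4f\n", x$inter_psi))
  invisible(x)
}

#' Inter-hemispheric phase synchronization over homologous channel pairs
#'
#' Computes the PSI of each left-right homologous electrode pair (default
#' the motor-relevant central, centro-parietal and fronto-central
#' homologues) and their mean, the subject-level "inter-PSI". When the
#' recording carries movement events, the average runs over the pooled task
#' intervals (`task_window` after each onset), i.e. synchronization during
#' exercise; otherwise over the whole trimmed support.
#'
#' @param rec An [eeg_recording()].
#' @param band Band of interest, Hz (default alpha, 8-13).
#' @param homologous_pairs List of length-2 character vectors, each with one
#'   left-hemisphere (odd-numbered) and one right-hemisphere (even-numbered)
#'   10/20 label.
#' @param task_window Seconds relative to onset (default 0-5).
#' @return A `psi_result` with one value per pair plus `inter_psi`, the mean
#'   over pairs.
#' @export
interhemispheric_psi <- function(rec, band = c(8, 13),
                                 homologous_pairs = list(c("C3", "C4"),
                                                         c("CP3", "CP4"),
                                                         c("FC3", "FC4")),
                                 task_window = c(0, 5)) {
  stopifnot(inherits(rec, "eeg_recording"))
  for (p in homologous_pairs) validate_homologous(p)
  ph <- instantaneous_phase(rec, band = band)
  windows <- NULL
  if (nrow(rec$events))
    windows <- lapply(rec$events$onset, function(o) o + task_window)
  vals <- numeric(length(homologous_pairs))
  for (i in seq_along(homologous_pairs))
    vals[i] <- psi(ph, homologous_pairs[[i]], window = windows)$values
  structure(list(pairs = lapply(homologous_pairs, normalize_1020),
                 values = vals, band = band, window = task_window,
                 inter_psi = mean(vals)),
            class = "psi_result")
}

validate_homologous <- function(pair) {
  if (length(pair) != 2L)
    stop("each homologous pair must have exactly two labels", call. = FALSE)
  side <- vapply(normalize_1020(pair), function(lab) {
    num <- suppressWarnings(as.integer(sub("^[A-Za-z]+", "", lab)))
    if (is.na(num)) "midline" else if (num %% 2L == 1L) "left" else "right"
  }, "")
  if (!setequal(side, c("left", "right")))
    stop(sprintf("pair (%s) is not inter-hemispheric: one left (odd) and one right (even) label required",
                 paste(pair, collapse = ", ")), call. = FALSE)
  invisible(pair)
}

#' Compare a scalar feature between two groups of subjects
#'
#' Two-sided comparison of per-subject scalars (such as inter-PSI values)
#' between two groups, by Welch's t-test (default) or the Mann-Whitney
#' rank-sum test.
#'
#' @param values_a,values_b Numeric vectors, one value per subject; both
#'   groups need at least two subjects.
#' @param test `"welch"` or `"mann-whitney"`.
#' @return A list of class `group_comparison`: `statistic`, `p_value`,
#'   `test`, `n_a`, `n_b`.
#' @export
group_compare <- function(values_a, values_b, test = c("welch", "mann-whitney")) {
  test <- match.arg(test)
  if (length(values_a) < 2L || length(values_b) < 2L)
    stop("both groups need at least 2 subjects", call. = FALSE)
  if (test == "welch") {
    if (stats::var(values_a) == 0 && stats::var(values_b) == 0)
      stop("both groups have zero variance: the t statistic is undefined; ",
           "use test = \"mann-whitney\" or check the inputs", call. = FALSE)
    ht <- stats::t.test(values_a, values_b, var.equal = FALSE)
  } else {
    ht <- suppressWarnings(stats::wilcox.test(values_a, values_b, exact = NULL))
  }
  structure(list(statistic = unname(ht$statistic), p_value = ht$p.value,
                 test = test, n_a = length(values_a), n_b = length(values_b)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: statistic = %.4f, p = %.4g (n = %d vs %d)\n",
              x$test, x$statistic, x$p_value, x$n_a, x$n_b))
  invisible(x)
}
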