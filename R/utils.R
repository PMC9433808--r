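# Internal helpers shared across modules.

#' @importFrom stats coef confint fft lm pt qt rnorm runif sd t.test
#'   wilcox.test predict var
#' @importFrom utils read.csv write.csv read.delim write.table
NULL

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so simulators are pure functions of their arguments.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}

assert_interval <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 2L || any(!is.finite(x)))
    stop(sprintf("`%s` must be a numeric length-2 interval", name), call. = FALSE)
  if (x[1] >= x[2])
    stop(sprintf("`%s` is reversed: (%g, %g)", name, x[1], x[2]), call. = FALSE)
  if (positive && x[1] <= 0)
    stop(sprintf("`%s` must be strictly positive", name), call. = FALSE)
  invisible(x)
}

assert_band <- function(band, fs, name = "band") {
  assert_interval(band, name, positive = TRUE)
  if (band[2] >= fs / 2)
    stop(sprintf("`%s` upper edge %g Hz is at or above the Nyquist limit %g Hz",
                 name, band[2], fs / 2), call. = FALSE)
  invisible(band)
}

# Forward-backward (zero-phase) Butterworth filtering with reflective padding.
# High-pass and low-pass stages are cascaded separately: a single band-pass
# polynomial is numerically fragile at very small normalized edges
# (e.g. 0.01 Hz at 20 Hz sampling), while the cascade stays stable.
zerophase_filter <- function(x, fs, low = NULL, high = NULL, order = 4) {
  n <- length(x)
  edge <- if (!is.null(low)) low else high
  pad <- min(n - 1L, ceiling(3 * fs / edge))
  xp <- c(rev(x[2:(pad + 1L)]), x, rev(x[(n - pad):(n - 1L)]))
  run <- function(z, flt) {
    y <- as.numeric(signal::filter(flt, z))
    rev(as.numeric(signal::filter(flt, rev(y))))
  }
  if (!is.null(high))
    xp <- run(xp, signal::butter(order, high / (fs / 2), type = "low"))
  if (!is.null(low))
    xp <- run(xp, signal::butter(order, low / (fs / 2), type = "high"))
  xp[(pad + 1L):(pad + n)]
}

bandpass_rows <- function(mat, fs, band, order = 4) {
  t(apply(mat, 1L, zerophase_filter, fs = fs, low = band[1], high = band[2],
          order = order))
}

# Analytic signal by the standard frequency-domain construction: double the
# positive frequencies, zero the negative ones, keep DC (and Nyquist).
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1; h[n / 2 + 1L] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1L] <- 1; h[2:((n + 1L) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# Trapezoidal integral of y(t) on an arbitrary grid.
trapezoid <- function(t, y) {
  sum(diff(t) * (head(y, -1L) + tail(y, -1L)) / 2)
}

#' @importFrom utils head tail
NULL

events_frame <- function(onset = numeric(), duration = numeric(),
                         trial_type = character()) {
  data.frame(onset = as.numeric(onset), duration = as.numeric(duration),
             trial_type = as.character(trial_type))
}
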