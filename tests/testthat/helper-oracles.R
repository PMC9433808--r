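# Independent oracles and small fixture builders used across the suite.
# Each oracle recomputes a quantity from its mathematical definition with
# explicit sums/loops, deliberately avoiding the package's code paths.

# Build an eeg_epochs object directly from a trials x time matrix.
make_epochs <- function(data, fs, window = c(-1, 5)) {
  len <- ncol(data)
  structure(list(data = data, fs = fs,
                 times = window[1] + (0:(len - 1)) / fs,
                 t0_index = -round(window[1] * fs) + 1L,
                 window = window, channel = "Cz", n_dropped = 0L),
            class = "eeg_epochs")
}

# Build a bare (unnormalized) ersp_grid from a power matrix.
make_grid <- function(power, freqs, times) {
  structure(list(power = power, freqs = freqs, times = times,
                 n_trials = 1L, normalized = FALSE,
                 baseline_per_freq = NULL, n_baseline_bins = NULL,
                 method = "stft"),
            class = "ersp_grid")
}

# Trial-averaged windowed-DFT power, straight from the definition:
# F_k(f, t) = sum_m w[m] x_k[t + m] exp(-2 pi i f m / fs), averaged |F|^2.
ersp_oracle <- function(data, fs, freqs, window_s = 0.5) {
  L <- round(window_s * fs)
  hop <- max(1, round(L / 16))
  hann <- 0.5 * (1 - cos(2 * pi * (0:(L - 1)) / (L - 1)))
  norm <- (sum(hann) / 2)^2
  starts <- seq(1, ncol(data) - L + 1, by = hop)
  P <- matrix(0, length(freqs), length(starts))
  for (k in seq_len(nrow(data)))
    for (j in seq_along(freqs))
      for (m in seq_along(starts)) {
        seg <- data[k, starts[m]:(starts[m] + L - 1)]
        ang <- 2 * pi * freqs[j] * (0:(L - 1)) / fs
        re <- sum(seg * hann * cos(ang))
        im <- -sum(seg * hann * sin(ang))
        P[j, m] <- P[j, m] + (re^2 + im^2) / norm
      }
  P / nrow(data)
}

# Analytic signal by explicit DFT sums (no fft()).
analytic_oracle <- function(x) {
  n <- length(x)
  ks <- 0:(n - 1)
  X <- vapply(ks, function(k) sum(x * exp(-2i * pi * k * ks / n)), complex(1))
  h <- numeric(n)
  if (n %% 2 == 0) { h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2 }
  else { h[1] <- 1; h[2:((n + 1) / 2)] <- 2 }
  vapply(ks, function(m) sum(X * h * exp(2i * pi * ks * m / n)) / n, complex(1))
}

# Welch two-sample t statistic and p-value in closed form.
welch_oracle <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  tstat <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(statistic = tstat, p = 2 * pt(-abs(tstat), df))
}

# OLS by the normal equations.
ols_oracle <- function(X, y) as.numeric(solve(t(X) %*% X, t(X) %*% y))

# Unwrap a phase sequence by removing 2*pi jumps.
unwrap_phase <- function(p) {
  d <- diff(p)
  d <- d - 2 * pi * round(d / (2 * pi))
  c(p[1], p[1] + cumsum(d))
}

# Reference (Table-style) generating coefficients used throughout:
# (intercept, ERD, HBO, AGE, HBO^2).
ref_beta <- c(30.6, -12.4, 37.3, -0.5, -10.6)
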