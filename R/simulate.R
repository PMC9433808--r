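#' Simulate EEG trials with a controllable desynchronization depth
#'
#' Generates a single Cz-like channel as 1/f Gaussian background noise plus
#' an ongoing oscillation in `erd_band` whose amplitude is multiplied by
#' `1 - erd_depth` from movement onset (end of the preparation phase) to the
#' end of the dynamic dorsiflexion phase, then recovers linearly to its
#' resting amplitude over the static-hold and rest phases. This reproduces
#' the qualitative beta-band event-related desynchronization the analysis
#' chain is designed to quantify, with the injected amplitude factor as
#' ground truth.
#'
#' Trials are laid back to back, so consecutive onsets are exactly one trial
#' total apart. A `pre_roll_s` lead-in and `post_roll_s` tail of resting
#' signal guarantee that the default epoch window (-1 to +5 s) always fits.
#'
#' @param timing A [trial_timing()].
#' @param n_trials Number of trials.
#' @param fs Sampling rate, Hz.
#' @param erd_depth Fractional amplitude drop in `[0, 1]`; 0 injects no
#'   desynchronization.
#' @param erd_band Oscillation band, Hz; the carrier is its midpoint.
#' @param seed Integer; the same seed reproduces the identical recording.
#' @param osc_amp Resting oscillation amplitude, microvolts.
#' @param noise_sd Standard deviation of the 1/f background, microvolts.
#' @param pre_roll_s,post_roll_s Resting padding before the first and after
#'   the last trial, seconds. `post_roll_s` must be at least `prep_s` so the
#'   full trial clock of the last event fits in the recording.
#' @return An [eeg_recording()] with one channel `"Cz"` and one
#'   `"dorsiflexion"` event per trial at each movement onset.
#' @examples
#' rec <- simulate_eeg_trials(n_trials = 5, erd_depth = 0.5, seed = 1)
#' rec$events$onset  # 3.0, 14.5, 26.0, ...
#' @export
simulate_eeg_trials <- function(timing = trial_timing(), n_trials = 50,
                                fs = 256, erd_depth = 0.5,
                                erd_band = c(15, 23), seed = 1,
                                osc_amp = 2, noise_sd = 1,
                                pre_roll_s = 2, post_roll_s = 2) {
  stopifnot(inherits(timing, "trial_timing"), n_trials >= 1)
  assert_band(erd_band, fs, "erd_band")
  if (erd_depth < 0 || erd_depth > 1)
    stop("`erd_depth` must be in [0, 1]", call. = FALSE)
  if (post_roll_s < timing$prep_s)
    stop("`post_roll_s` must be >= prep_s so the last trial clock fits",
         call. = FALSE)
  total <- timing_total(timing)
  dur <- pre_roll_s + n_trials * total + post_roll_s
  n <- round(dur * fs)
  t <- (0:(n - 1)) / fs
  onsets <- pre_roll_s + (0:(n_trials - 1)) * total + timing$prep_s

  # Amplitude envelope: suppressed during the dynamic phase, linear recovery
  # across the static hold and rest.
  env <- rep(1, n)
  recovery <- timing$static_s + timing$rest_s
  for (o in onsets) {
    i_dyn <- which(t >= o & t < o + timing$dynamic_s)
    env[i_dyn] <- 1 - erd_depth
    i_rec <- which(t >= o + timing$dynamic_s & t < o + timing$dynamic_s + recovery)
    env[i_rec] <- 1 - erd_depth +
      erd_depth * (t[i_rec] - (o + timing$dynamic_s)) / recovery
  }

  x <- with_seed(seed, {
    phi0 <- runif(1) * 2 * pi
    pink_noise(n, sd = noise_sd) +
      osc_amp * env * sin(2 * pi * mean(erd_band) * t + phi0)
  })

  eeg_recording(matrix(x, nrow = 1), fs = fs, channel_names = "Cz",
                events = events_frame(onset = onsets,
                                      duration = rep(total - timing$prep_s, n_trials),
                                      trial_type = rep("dorsiflexion", n_trials)))
}

# 1/f-amplitude Gaussian noise via spectral shaping, rescaled to `sd`.
pink_noise <- function(n, sd = 1) {
  X <- stats::fft(rnorm(n))
  k <- c(1, seq_len(n - 1))        # guard DC
  k <- pmin(k, n - k + 1)          # mirror-symmetric frequency index
  x <- Re(stats::fft(X / sqrt(k), inverse = TRUE) / n)
  x / stats::sd(x) * sd
}

#' Simulate a phase-coupled channel pair with known synchronization
#'
#' Two sinusoidal channels `X` and `Y` share a common carrier phase; the
#' per-sample phase difference between them is Gaussian with standard
#' deviation `phase_jitter_sd` radians. The jitter is a band-limited
#' Gaussian process (standardized to the exact marginal sd), slowly varying
#' relative to the carrier, so a band-pass + Hilbert analysis recovers it;
#' the expected phase synchronization index of the pair is the wrapped
#' Gaussian resultant length `exp(-phase_jitter_sd^2 / 2)`.
#'
#' @param n_samples Number of samples (>= 16; shorter signals give no stable
#'   Hilbert phase).
#' @param carrier_hz Carrier frequency, Hz.
#' @param fs Sampling rate, Hz.
#' @param phase_jitter_sd Sd of the phase difference, radians (>= 0).
#' @param seed Integer seed.
#' @param jitter_bw_hz Approximate bandwidth of the jitter process, Hz. Keep
#'   well below `carrier_hz` so that the phase modulation stays within the
#'   analysis band.
#' @return An [eeg_recording()] with channels `"X"`, `"Y"`. The drawn phase
#'   difference is attached as attribute `"phase_diff"` (radians) for
#'   ground-truth checks.
#' @examples
#' rec <- simulate_phase_coupled_pair(5000, phase_jitter_sd = 0.5, seed = 2)
#' exp(-0.5^2 / 2)  # expected PSI of the pair
#' @export
simulate_phase_coupled_pair <- function(n_samples, carrier_hz = 10, fs = 100,
                                        phase_jitter_sd = 0.5, seed = 1,
                                        jitter_bw_hz = 2) {
  if (n_samples < 16)
    stop("`n_samples` must be >= 16 for a stable Hilbert phase", call. = FALSE)
  if (phase_jitter_sd < 0) stop("`phase_jitter_sd` must be >= 0", call. = FALSE)
  assert_band(c(carrier_hz / 2, carrier_hz), fs, "carrier band")
  tt <- (0:(n_samples - 1)) / fs
  sim <- with_seed(seed, {
    phi <- 2 * pi * carrier_hz * tt + runif(1) * 2 * pi
    d <- if (phase_jitter_sd == 0) numeric(n_samples)
         else phase_jitter_sd * smooth_gaussian_unit(n_samples, jitter_bw_hz, fs)
    list(x = cos(phi), y = cos(phi + d), d = d)
  })
  rec <- eeg_recording(rbind(sim$x, sim$y), fs = fs,
                       channel_names = c("X", "Y"))
  attr(rec, "phase_diff") <- sim$d
  rec
}

# Smoothed (band-limited) Gaussian process standardized to unit marginal sd.
smooth_gaussian_unit <- function(n, bw_hz, fs) {
  w <- rnorm(n)
  k <- ceiling(fs / bw_hz * 2)
  g <- exp(-seq(-3, 3, length.out = 2 * k + 1)^2 / 2)
  s <- as.numeric(stats::filter(w, g / sum(g), sides = 2, circular = TRUE))
  s / stats::sd(s)
}

#' Default fNIRS physiological-noise specification
#'
#' Cardiac, respiratory and Mayer-wave oscillations plus linear drift and
#' white noise, all configurable. The default frequencies are standard adult
#' physiology; amplitudes are micromolar-scale relative changes.
#'
#' @param cardiac_hz,resp_hz,mayer_hz Oscillation frequencies, Hz.
#' @param cardiac_amp,resp_amp,mayer_amp Oscillation amplitudes, micromolar.
#' @param drift_slope Linear drift, micromolar per second.
#' @param white_sd White-noise sd, micromolar.
#' @return A list of class `fnirs_noise`.
#' @export
fnirs_noise <- function(cardiac_hz = 1.1, cardiac_amp = 0.1,
                        resp_hz = 0.25, resp_amp = 0.1,
                        mayer_hz = 0.1, mayer_amp = 0.1,
                        drift_slope = 0.001, white_sd = 0.05) {
  structure(list(cardiac_hz = cardiac_hz, cardiac_amp = cardiac_amp,
                 resp_hz = resp_hz, resp_amp = resp_amp,
                 mayer_hz = mayer_hz, mayer_amp = mayer_amp,
                 drift_slope = drift_slope, white_sd = white_sd),
            class = "fnirs_noise")
}

#' Noise-free fNIRS noise specification
#' @return A `fnirs_noise` with every amplitude, drift and sd set to zero.
#' @export
fnirs_noise_none <- function() {
  fnirs_noise(cardiac_amp = 0, resp_amp = 0, mayer_amp = 0,
              drift_slope = 0, white_sd = 0)
}

#' The eight fNIRS channels over the sensorimotor leg area
#'
#' Source-detector pairs covering the region the hemoglobin features are
#' averaged over.
#' @return Character vector of eight channel labels.
#' @export
fnirs_default_channels <- function() {
  c("S2-D4", "S2-D2", "S7-D2", "S7-D4", "S7-D7", "S7-D5", "S5-D7", "S5-D5")
}

#' Canonical double-gamma hemodynamic response function
#'
#' SPM-convention kernel: response gamma peaking at 6 s minus an undershoot
#' gamma peaking at 16 s with 1/6 relative amplitude.
#'
#' @param t Time grid, seconds (>= 0).
#' @return Kernel values on `t` (unit peak not enforced).
#' @export
hrf_double_gamma <- function(t) {
  a1 <- 6; a2 <- 16; b <- 1; c <- 1 / 6
  g <- function(t, a) (t^(a - 1) * exp(-t / b)) / gamma(a)
  h <- g(pmax(t, 0), a1) - c * g(pmax(t, 0), a2)
  h[t < 0] <- 0
  h
}

#' Simulate an fNIRS session with HRF-shaped hemoglobin responses
#'
#' HBO on every channel is the double-gamma hemodynamic response function
#' convolved with a boxcar spanning each movement (onset to onset + 5.5 s,
#' the dynamic plus static phases), scaled so a single noiseless response
#' peaks at `amplitude_hbo`, plus sinusoidal physiological components,
#' linear drift and white noise. HBR is the `-1/3`-scaled mirror of the same
#' clean response with its own independent noise.
#'
#' @param timing A [trial_timing()].
#' @param n_trials Number of trials.
#' @param fs Sampling rate, Hz; must exceed twice the cardiac frequency or
#'   the cardiac component would alias.
#' @param amplitude_hbo Peak of the noiseless single-trial HBO response,
#'   micromolar (>= 0).
#' @param noise A [fnirs_noise()] specification.
#' @param seed Integer seed.
#' @param channel_names Channels to generate (default the eight
#'   sensorimotor channels of [fnirs_default_channels()]).
#' @param pre_roll_s,post_roll_s Rest padding, seconds (pre-roll must cover
#'   the 2 s epoch baseline; defaults are generous).
#' @return An [fnirs_recording()].
#' @export
simulate_fnirs_session <- function(timing = trial_timing(), n_trials = 50,
                                   fs = 20, amplitude_hbo = 1,
                                   noise = fnirs_noise(), seed = 1,
                                   channel_names = fnirs_default_channels(),
                                   pre_roll_s = 5, post_roll_s = 5) {
  stopifnot(inherits(timing, "trial_timing"), n_trials >= 1,
            inherits(noise, "fnirs_noise"))
  if (amplitude_hbo < 0) stop("`amplitude_hbo` must be >= 0", call. = FALSE)
  if (fs <= 2 * noise$cardiac_hz)
    stop(sprintf("fs = %g Hz would alias the %g Hz cardiac component (need fs > %g Hz)",
                 fs, noise$cardiac_hz, 2 * noise$cardiac_hz), call. = FALSE)
  if (post_roll_s < timing$prep_s)
    stop("`post_roll_s` must be >= prep_s", call. = FALSE)
  total <- timing_total(timing)
  dur <- pre_roll_s + n_trials * total + post_roll_s
  n <- round(dur * fs)
  t <- (0:(n - 1)) / fs
  onsets <- pre_roll_s + (0:(n_trials - 1)) * total + timing$prep_s
  task_s <- timing$dynamic_s + timing$static_s   # 5.5 s with defaults

  # Clean response: HRF (*) boxcar, peak-normalized on a single trial.
  hrf <- hrf_double_gamma(seq(0, 32, by = 1 / fs))
  box <- rep(0, n)
  for (o in onsets) box[t >= o & t < o + task_s] <- 1
  conv_full <- stats::convolve(box, rev(hrf), type = "open")[seq_len(n)]
  single <- stats::convolve(c(rep(1, round(task_s * fs)),
                              rep(0, length(hrf))),
                            rev(hrf), type = "open")
  scale <- max(single)
  clean <- if (scale > 0) amplitude_hbo * conv_full / scale else conv_full * 0

  nch <- length(channel_names)
  noise_draw <- function(spec, t) {
    spec$cardiac_amp * sin(2 * pi * spec$cardiac_hz * t + runif(1) * 2 * pi) +
      spec$resp_amp * sin(2 * pi * spec$resp_hz * t + runif(1) * 2 * pi) +
      spec$mayer_amp * sin(2 * pi * spec$mayer_hz * t + runif(1) * 2 * pi) +
      spec$drift_slope * t +
      if (spec$white_sd > 0) rnorm(length(t), 0, spec$white_sd) else 0
  }
  out <- with_seed(seed, {
    hbo <- t(sapply(seq_len(nch), function(i) clean + noise_draw(noise, t)))
    hbr <- t(sapply(seq_len(nch), function(i) -clean / 3 + noise_draw(noise, t)))
    list(hbo = hbo, hbr = hbr)
  })
  fnirs_recording(out$hbo, out$hbr, fs = fs, channel_names = channel_names,
                  events = events_frame(onset = onsets,
                                        duration = rep(task_s, n_trials),
                                        trial_type = rep("dorsiflexion", n_trials)))
}

#' Simulate a feature cohort from a known generating model
#'
#' Draws AGE, ERD and HBO uniformly from the stated ranges and generates
#' `BBS = b0 + b1 ERD + b2 HBO + b3 AGE + b4 HBO^2 + N(0, noise_sd)`. With
#' `noise_sd = 0` the downstream regression recovers `beta` exactly, which
#' is the ground truth the parameter-recovery tests rely on; for that reason
#' BBS is clipped to the clinical 0-56 range only when `clip_bbs = TRUE`.
#'
#' @param n_subjects Number of subjects (>= 3).
#' @param beta Length-5 generating coefficients, ordered (intercept, ERD,
#'   HBO, AGE, HBO^2).
#' @param noise_sd Residual sd in BBS points (>= 0).
#' @param age_range,erd_range,hbo_range Uniform sampling intervals.
#' @param seed Integer seed; fully determines the table.
#' @param clip_bbs Clip BBS into `[0, 56]` (default off).
#' @return A [feature_table()] with columns subject_id, AGE, ERD, HBO, BBS.
#' @export
simulate_cohort <- function(n_subjects = 8,
                            beta = c(30.6, -12.4, 37.3, -0.5, -10.6),
                            noise_sd = 5,
                            age_range = c(30, 75),
                            erd_range = c(-2, -0.3),
                            hbo_range = c(0.1, 3),
                            seed = 1, clip_bbs = FALSE) {
  if (n_subjects < 3) stop("`n_subjects` must be >= 3", call. = FALSE)
  if (length(beta) != 5) stop("`beta` must have length 5", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  df <- with_seed(seed, {
    age <- runif(n_subjects, age_range[1], age_range[2])
    erd <- runif(n_subjects, erd_range[1], erd_range[2])
    hbo <- runif(n_subjects, hbo_range[1], hbo_range[2])
    bbs <- beta[1] + beta[2] * erd + beta[3] * hbo + beta[4] * age +
      beta[5] * hbo^2 + rnorm(n_subjects, 0, noise_sd)
    data.frame(subject_id = sprintf("S%d", seq_len(n_subjects)),
               AGE = age, ERD = erd, HBO = hbo, BBS = bbs)
  })
  if (clip_bbs) df$BBS <- pmin(pmax(df$BBS, 0), 56)
  feature_table(df, enforce_bbs = clip_bbs)
}
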