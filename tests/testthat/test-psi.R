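test_that("instantaneous phase of a pure tone advances at the carrier rate", {
  fs <- 200
  t <- (0:(fs * 10 - 1)) / fs
  rec <- eeg_recording(matrix(cos(2 * pi * 10 * t), 1), fs, "Cz")
  ph <- instantaneous_phase(rec, band = c(8, 13))
  interior <- (ph$trim + 1):(ncol(ph$phase) - ph$trim)
  up <- unwrap_phase(ph$phase[1, interior])
  slope <- mean(diff(up)) * fs
  expect_equal(slope, 2 * pi * 10, tolerance = 0.01 * 2 * pi * 10)
})

test_that("analytic signal matches an explicit-DFT oracle on a small vector", {
  set.seed(3)
  x <- rnorm(32)
  got <- neurobalance:::analytic_signal(x)
  expect_equal(got, analytic_oracle(x), tolerance = 1e-10)
})

test_that("degenerate zero signals are rejected: their phase is undefined", {
  rec <- eeg_recording(matrix(0, 1, 1000), 100, "Cz")
  expect_error(instantaneous_phase(rec, band = c(8, 13)), "undefined")
})

test_that("PSI hand cases: full sync, half-turn split, quarter-turn split", {
  fs <- 10
  mk <- function(d) phase_series(rbind(d, rep(0, length(d))), fs = fs,
                                 channel_names = c("A", "B"))
  # identical channels: PSI = 1 exactly
  its <- runif(100, -pi, pi)
  same <- phase_series(rbind(its, its), fs = fs, channel_names = c("A", "B"))
  expect_equal(psi(same, c("A", "B"))$values, 1)
  # differences split evenly between 0 and pi: PSI = 0
  expect_equal(psi(mk(rep(c(0, pi), 50)), c("A", "B"))$values, 0,
               tolerance = 1e-12)
  # differences split between 0 and pi/2: PSI = sqrt(0.5)
  expect_equal(psi(mk(rep(c(0, pi / 2), 50)), c("A", "B"))$values,
               sqrt(0.5), tolerance = 1e-12)
})

test_that("PSI is symmetric, offset-invariant and bounded by [0, 1]", {
  set.seed(4)
  fs <- 100
  ph <- phase_series(rbind(runif(500, -pi, pi), runif(500, -pi, pi)),
                     fs = fs, channel_names = c("A", "B"))
  ab <- psi(ph, c("A", "B"))$values
  ba <- psi(ph, c("B", "A"))$values
  expect_equal(ab, ba)
  shifted <- ph
  shifted$phase[1, ] <- shifted$phase[1, ] + 1.3
  shifted <- phase_series(shifted$phase, fs, channel_names = c("A", "B"))
  expect_equal(psi(shifted, c("A", "B"))$values, ab, tolerance = 1e-12)
  for (s in 1:5) {
    p2 <- phase_series(matrix(runif(200, -pi, pi), 2), fs,
                       channel_names = c("A", "B"))
    v <- psi(p2, c("A", "B"))$values
    expect_gte(v, 0); expect_lte(v, 1)
  }
})

test_that("measured PSI follows the wrapped-Gaussian jitter law at moderate n", {
  for (s in c(0.5, 1.0)) {
    rec <- simulate_phase_coupled_pair(5e4, phase_jitter_sd = s, seed = 6)
    ph <- instantaneous_phase(rec, band = c(2, 18))
    expect_equal(psi(ph, c("X", "Y"))$values, exp(-s^2 / 2), tolerance = 0.02)
  }
  # near-uniform jitter: synchronization collapses
  rec <- simulate_phase_coupled_pair(1e5, carrier_hz = 60, fs = 250,
                                     phase_jitter_sd = 6, seed = 6,
                                     jitter_bw_hz = 1.5)
  ph <- instantaneous_phase(rec, band = c(2, 110))
  expect_lt(psi(ph, c("X", "Y"))$values, 0.1)
})

test_that("independent channels have near-zero synchronization", {
  set.seed(7)
  fs <- 100
  n <- 1e5
  rec <- eeg_recording(rbind(rnorm(n), rnorm(n)), fs, c("C3", "C4"))
  ph <- instantaneous_phase(rec, band = c(8, 13))
  expect_lt(psi(ph, c("C3", "C4"))$values, 0.05)
})

test_that("inter-hemispheric PSI validates pairs and averages homologues", {
  # common source driving both channels: near-perfect synchronization
  fs <- 200
  t <- (0:(fs * 20 - 1)) / fs
  src <- cos(2 * pi * 10 * t)
  rec <- eeg_recording(rbind(src, src), fs, c("C3", "C4"))
  res <- interhemispheric_psi(rec, band = c(8, 13),
                              homologous_pairs = list(c("C3", "C4")))
  expect_equal(res$inter_psi, 1, tolerance = 1e-2)
  expect_error(interhemispheric_psi(rec, homologous_pairs = list(c("Cz", "Cz"))),
               "not inter-hemispheric")
  expect_error(interhemispheric_psi(rec, band = c(8, 13),
                                    homologous_pairs = list(c("FC3", "FC4"))),
               "unknown channel")
})

test_that("group comparison matches the closed-form Welch computation", {
  a <- c(1, 2, 3); b <- a + 10
  got <- group_compare(a, b, test = "welch")
  want <- welch_oracle(a, b)
  expect_equal(got$statistic, want$statistic, tolerance = 1e-12)
  expect_equal(got$p_value, want$p, tolerance = 1e-12)
})

test_that("group comparison handles identical and degenerate groups", {
  x <- c(1, 2, 3)
  mw <- group_compare(x, x, test = "mann-whitney")
  expect_equal(mw$p_value, 1)
  expect_error(group_compare(c(1, 1), c(2, 2)), "zero variance")
  expect_error(group_compare(1, c(1, 2)), "at least 2")
})

test_that("p-value decreases as the group shift grows at the study's group sizes", {
  set.seed(8)
  base <- runif(8, 0.4, 0.6)
  other <- runif(6, 0.4, 0.6)
  ps <- vapply(c(0.05, 0.15, 0.4),
               function(sh) group_compare(base, other + sh)$p_value, 0)
  expect_true(all(diff(ps) < 0))
})
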