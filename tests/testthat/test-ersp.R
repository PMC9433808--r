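test_that("preprocessing removes DC, passes 10 Hz, and decimates by the rate ratio", {
  fs <- 1024
  n <- fs * 20
  t <- (0:(n - 1)) / fs
  mk <- function(x) eeg_recording(matrix(x, 1), fs, "Cz")
  # DC is outside the 0.05-35 Hz band (judged away from the edge transients)
  dc <- suppressMessages(preprocess_eeg(mk(rep(1, n))))
  n_out <- ncol(dc$samples)
  mid <- (n_out %/% 4):(3 * n_out %/% 4)
  expect_lt(max(abs(dc$samples[1, mid])), 0.05)
  # a 10 Hz unit sine is in the pass band
  sn <- suppressMessages(preprocess_eeg(mk(sin(2 * pi * 10 * t))))
  expect_equal(max(sn$samples[1, mid]), 1, tolerance = 0.05)
  # 1024 -> 256 Hz keeps every fourth sample
  expect_equal(ncol(sn$samples), n / 4)
  expect_equal(sn$fs, 256)
})

test_that("preprocessing validates rates and bands", {
  rec <- eeg_recording(matrix(rnorm(512), 1), 256, "Cz")
  expect_error(suppressMessages(preprocess_eeg(rec, fs_out = 512)),
               "must not exceed")
  expect_error(suppressMessages(preprocess_eeg(rec, band = c(0.05, 200))),
               "Nyquist")
})

test_that("epoching slices verbatim and drops events near the edges", {
  fs <- 100
  n <- 30 * fs
  ramp <- (0:(n - 1)) / fs            # x(t) = t
  ev <- data.frame(onset = c(2, 10, 29.8), duration = 0.1,
                   trial_type = "dorsiflexion")
  rec <- eeg_recording(matrix(ramp, 1), fs, "Cz", ev)
  expect_message(ep <- epoch_eeg(rec, window = c(-1, 5)), "dropped 1")
  expect_equal(nrow(ep$data), 2)
  expect_equal(ep$n_dropped, 1)
  # slice of the ramp equals the ramp restricted to the window
  expect_equal(ep$data[1, ], seq(2 - 1, by = 1 / fs, length.out = 6 * fs))
  expect_equal(ncol(ep$data), 6 * fs)
  expect_error(epoch_eeg(rec, channel = "C3"), "not present")
})

test_that("trial-averaged spectral power matches the windowed-DFT definition", {
  set.seed(1)
  fs <- 256
  data <- matrix(rnorm(4 * 512), nrow = 4)
  ep <- make_epochs(data, fs, window = c(0, 2))
  freqs <- c(8, 12.5, 15, 20, 23)
  grid <- compute_ersp(ep, freqs = freqs)
  expect_equal(grid$power, ersp_oracle(data, fs, freqs),
               tolerance = 1e-10)
  expect_equal(grid$n_trials, 4)
  expect_false(grid$normalized)
})

test_that("spectral estimator basics: zeros give zeros, identical trials average to one trial", {
  fs <- 128
  z <- make_epochs(matrix(0, 3, 256), fs, c(0, 2))
  expect_equal(max(compute_ersp(z, freqs = c(10, 20))$power), 0)
  one <- matrix(rnorm(256), 1)
  same <- make_epochs(one[rep(1, 5), ], fs, c(0, 2))
  g1 <- compute_ersp(make_epochs(one, fs, c(0, 2)), freqs = c(10, 20))
  g5 <- compute_ersp(same, freqs = c(10, 20))
  expect_equal(g5$power, g1$power, tolerance = 1e-12)
  expect_error(compute_ersp(z, freqs = c(10, 80)), "Nyquist")
})

test_that("concatenating trial sets averages power with trial-count weights", {
  set.seed(2)
  fs <- 128
  a <- matrix(rnorm(2 * 256), 2)
  b <- matrix(rnorm(3 * 256), 3)
  ga <- compute_ersp(make_epochs(a, fs, c(0, 2)), freqs = c(10, 20))$power
  gb <- compute_ersp(make_epochs(b, fs, c(0, 2)), freqs = c(10, 20))$power
  gc <- compute_ersp(make_epochs(rbind(a, b), fs, c(0, 2)), freqs = c(10, 20))$power
  expect_equal(gc, (2 * ga + 3 * gb) / 5, tolerance = 1e-12)
})

test_that("Morlet estimator is available and agrees qualitatively on a pure tone", {
  fs <- 256
  t <- (0:1023) / fs
  ep <- make_epochs(matrix(sin(2 * pi * 20 * t), 1), fs, c(0, 4))
  g <- compute_ersp(ep, freqs = c(10, 20, 30), method = "morlet")
  mid <- ncol(g$power) %/% 2
  expect_gt(g$power[2, mid], 10 * g$power[1, mid])
  expect_gt(g$power[2, mid], 10 * g$power[3, mid])
})

test_that("subtractive baseline normalization matches the hand-worked example", {
  # one frequency; baseline bins (2, 4), task bins (5, 1): baseline = 3
  grid <- make_grid(matrix(c(2, 4, 5, 1), 1), freqs = 10,
                    times = c(-0.75, -0.25, 0.25, 0.75))
  ng <- baseline_normalize(grid, baseline_window = c(-1, 0))
  expect_equal(as.numeric(ng$power), c(-1, 1, 2, -2))
  expect_equal(ng$baseline_per_freq, 3)
  expect_equal(ng$n_baseline_bins, 2)
  expect_true(ng$normalized)
  # a grid constant in time normalizes to all zeros
  cg <- make_grid(matrix(7, 3, 10), freqs = 1:3,
                  times = seq(-0.9, 0.9, length.out = 10))
  expect_equal(max(abs(baseline_normalize(cg)$power)), 0)
})

test_that("baseline normalization guards its preconditions", {
  grid <- make_grid(matrix(1, 1, 4), 10, c(-0.75, -0.25, 0.25, 0.75))
  ng <- baseline_normalize(grid)
  expect_error(baseline_normalize(ng), "already")
  expect_error(baseline_normalize(grid, baseline_window = c(5, 6)), "no time bins")
})

test_that("ERD index averages only the strictly negative rectangle bins", {
  grid <- make_grid(matrix(c(-2, -1, 0.5, 1), 1), freqs = 18,
                    times = c(0.1, 0.3, 0.5, 0.7))
  grid$normalized <- TRUE
  idx <- erd_index(grid, band = c(15, 23), window = c(0, 1))
  expect_equal(idx$value, -1.5)
  expect_equal(idx$n_negative_bins, 2)
  expect_false(idx$empty_flag)
  # all-positive rectangle: value 0 with the flag set
  pos <- make_grid(matrix(c(1, 2), 1), 18, c(0.2, 0.6))
  pos$normalized <- TRUE
  idx2 <- erd_index(pos)
  expect_equal(idx2$value, 0)
  expect_true(idx2$empty_flag)
  # empty rectangle is an error, distinct from the no-negative-bins case
  expect_error(erd_index(pos, band = c(30, 40)), "no grid bins")
  expect_error(erd_index(make_grid(matrix(1), 18, 0.5)), "normalized")
})

test_that("simulated desynchronization yields a strictly negative ERD index", {
  rec <- simulate_eeg_trials(n_trials = 50, erd_depth = 0.5, fs = 256, seed = 1)
  grid <- baseline_normalize(compute_ersp(epoch_eeg(rec), freqs = 15:23))
  expect_lt(erd_index(grid)$value, 0)
})
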