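make_fnirs <- function(hbo, hbr = -hbo / 3, fs = 20, chans = NULL,
                       events = NULL) {
  if (is.null(chans)) chans <- sprintf("S%d-D%d", seq_len(nrow(hbo)), seq_len(nrow(hbo)))
  if (is.null(events)) events <- data.frame(onset = numeric(), duration = numeric(),
                                            trial_type = character())
  fnirs_recording(hbo, hbr, fs = fs, channel_names = chans, events = events)
}

test_that("hemoglobin band-pass rejects cardiac, passes slow waves, preserves zero", {
  fs <- 20
  n <- fs * 400
  t <- (0:(n - 1)) / fs
  mid <- (n %/% 4):(3 * n %/% 4)
  card <- make_fnirs(matrix(sin(2 * pi * 1.1 * t), 1))
  out <- bandpass_hemo(card)
  expect_lt(max(abs(out$hbo[1, mid])), 0.05)
  slow <- make_fnirs(matrix(sin(2 * pi * 0.05 * t), 1))
  out2 <- bandpass_hemo(slow)
  expect_equal(max(abs(out2$hbo[1, mid])), 1, tolerance = 0.1)
  zero <- bandpass_hemo(make_fnirs(matrix(0, 1, n), hbr = matrix(0, 1, n)))
  expect_equal(max(abs(zero$hbo)), 0)
})

test_that("band-pass refuses recordings shorter than the filter settling scale", {
  short <- make_fnirs(matrix(rnorm(20 * 60), 1))
  expect_error(bandpass_hemo(short), "time constants")
})

test_that("epoching subtracts the per-trial baseline and materializes HBT", {
  fs <- 10
  n <- fs * 60
  ev <- data.frame(onset = c(10, 25, 40), duration = 5.5, trial_type = "flex")
  # constant channel: corrected epochs are identically zero
  const <- make_fnirs(matrix(5, 1, n), hbr = matrix(-2, 1, n), fs = fs,
                      chans = "S1-D1", events = ev)
  ep <- epoch_and_correct(const, channels = "S1-D1")
  expect_equal(max(abs(ep$hbo)), 0)
  expect_equal(max(abs(ep$hbt)), 0)
  # step channel: baseline mean 2 before onset, 5 after -> corrected 3
  on <- 10
  x <- rep(2, n)
  x[(on * fs + 1):((on + 10) * fs)] <- 5
  step <- make_fnirs(matrix(x, 1), fs = fs, chans = "S1-D1",
                     events = data.frame(onset = on, duration = 5.5,
                                         trial_type = "flex"))
  eps <- epoch_and_correct(step, channels = "S1-D1")
  task_val <- eps$hbo[1, eps$times > 1 & eps$times < 5, 1]
  expect_equal(unique(round(task_val, 10)), 3)
  # every baseline window is exactly zero-mean after correction
  bbin <- ep$times >= -2 & ep$times < 0
  expect_lt(max(abs(apply(ep$hbo[, bbin, , drop = FALSE], c(1, 3), mean))), 1e-12)
})

test_that("epoching names any missing channel instead of silently subsetting", {
  rec <- simulate_fnirs_session(n_trials = 3, seed = 1,
                                channel_names = c("S2-D4", "S2-D2"))
  expect_error(epoch_and_correct(rec), "S7-D2")
})

test_that("epoch bookkeeping: trials x samples x channels with zero-mean baselines", {
  rec <- simulate_fnirs_session(n_trials = 12, seed = 2)
  ep <- epoch_and_correct(rec)
  expect_equal(dim(ep$hbo), c(12, 12 * rec$fs, 8))
  expect_equal(ep$hbt, ep$hbo + ep$hbr)
  bbin <- ep$times >= -2 & ep$times < 0
  bl <- apply(ep$hbo[, bbin, , drop = FALSE], c(1, 3), mean)
  expect_lt(max(abs(bl)), 1e-10)
})

test_that("curve averaging: identical trials pass through, opposite trials cancel", {
  fs <- 10
  one <- sin(2 * pi * 0.1 * (0:119) / fs)
  ep <- structure(list(hbo = array(rep(one, each = 2), c(2, 120, 1)),
                       hbr = array(0, c(2, 120, 1)),
                       hbt = array(rep(one, each = 2), c(2, 120, 1)),
                       fs = fs, times = -2 + (0:119) / fs,
                       window = c(-2, 10), baseline_window = c(-2, 0),
                       channels_used = "S1-D1", n_dropped = 0L),
                  class = "hemo_epochs")
  expect_equal(average_curve(ep)$hbo, one)
  ep$hbo[2, , 1] <- -ep$hbo[1, , 1]
  expect_equal(max(abs(average_curve(ep)$hbo)), 0)
})

test_that("noiseless session average matches the generative HRF convolution", {
  fs <- 20
  n_trials <- 6
  rec <- simulate_fnirs_session(n_trials = n_trials, amplitude_hbo = 2,
                                noise = fnirs_noise_none(), seed = 1, fs = fs)
  cur <- average_curve(epoch_and_correct(rec))
  # oracle: explicit loop convolution of the boxcar train with the kernel,
  # same peak normalization, sliced and baseline-corrected the same way
  n <- ncol(rec$hbo)
  t <- (0:(n - 1)) / fs
  hrf <- hrf_double_gamma(seq(0, 32, by = 1 / fs))
  box <- rep(0, n)
  for (o in rec$events$onset) box[t >= o & t < o + 5.5] <- 1
  conv <- numeric(n)
  for (i in seq_len(n)) {
    jmax <- min(i, length(hrf))
    conv[i] <- sum(box[i - seq_len(jmax) + 1] * hrf[seq_len(jmax)])
  }
  single_box <- c(rep(1, round(5.5 * fs)), rep(0, length(hrf)))
  single <- numeric(length(single_box))
  for (i in seq_along(single_box)) {
    jmax <- min(i, length(hrf))
    single[i] <- sum(single_box[i - seq_len(jmax) + 1] * hrf[seq_len(jmax)])
  }
  clean <- 2 * conv / max(single)
  win <- round(-2 * fs):(round(10 * fs) - 1)
  segs <- sapply(rec$events$onset, function(o) {
    seg <- clean[round(o * fs) + win + 1]
    seg - mean(seg[seq_len(2 * fs)])
  })
  oracle <- rowMeans(segs)
  expect_lt(max(abs(cur$hbo - oracle)), 0.01 * max(oracle))
})

test_that("scalar features: triangle peak/area by hand, flat zero, homogeneity", {
  fs <- 10
  times <- -2 + (0:(12 * fs - 1)) / fs
  tri <- ifelse(times < 0, 0, ifelse(times <= 5, 0.4 * times, 2 - 0.4 * (times - 5)))
  mkcurve <- function(y) structure(list(hbo = y, hbr = -y / 3, hbt = 2 * y / 3,
                                        times = times, fs = fs, n_trials = 1),
                                   class = "hemo_curve")
  cur <- mkcurve(tri)
  expect_equal(hbo_scalar(cur, "peak"), 2, tolerance = 1e-9)
  expect_equal(hbo_scalar(cur, "area"), 10, tolerance = 0.1)
  zero <- mkcurve(rep(0, length(times)))
  expect_equal(hbo_scalar(zero, "peak"), 0)
  expect_equal(hbo_scalar(zero, "area"), 0)
  sc <- mkcurve(3 * tri)
  expect_equal(hbo_scalar(sc, "peak"), 3 * hbo_scalar(cur, "peak"))
  expect_equal(hbo_scalar(sc, "area"), 3 * hbo_scalar(cur, "area"))
  expect_error(hbo_scalar(cur, "median"), "arg")
  expect_error(hbo_scalar(cur, window = c(0, 50)), "outside")
})

test_that("peak amplitude is proportional to the simulated response amplitude", {
  amps <- c(0.5, 1, 1.5, 2, 2.5)
  peaks <- vapply(amps, function(a) {
    rec <- simulate_fnirs_session(n_trials = 5, amplitude_hbo = a,
                                  noise = fnirs_noise_none(), seed = 1)
    hbo_scalar(average_curve(epoch_and_correct(rec)))
  }, 0)
  fit <- lm(peaks ~ amps)
  expect_gt(summary(fit)$r.squared, 0.999)
})
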