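test_that("amplitude normalization follows the max-abs rule", {
  expect_equal(normalize_amplitude(c(2, -4, 1)), c(0.5, -1.0, 0.25))
  x <- c(0.25, -1, 0.5)
  expect_equal(normalize_amplitude(x), x) # idempotent on normalized input
  expect_error(normalize_amplitude(c(0, 0)), "all-zero")
  set.seed(1)
  y <- rnorm(100)
  expect_equal(max(abs(normalize_amplitude(y))), 1)
})

test_that("zero-phase Butterworth low-pass meets its frequency contract", {
  rate <- 4000
  t <- (0:39999) / rate
  # DC gain 1 (interior samples)
  const <- butterworth_lowpass(rep(2.5, 40000), rate)
  expect_lt(max(abs(const[2000:38000] - 2.5)), 1e-6)
  # 10 Hz passes within 1%
  s10 <- sin(2 * pi * 10 * t)
  r10 <- butterworth_lowpass(s10, rate)
  rms <- function(x) sqrt(mean(x^2))
  expect_equal(rms(r10[2000:38000]) / rms(s10[2000:38000]), 1, tolerance = 0.01)
  # 1000 Hz attenuated below 5% (two-pass magnitude)
  s1k <- sin(2 * pi * 1000 * t)
  r1k <- butterworth_lowpass(s1k, rate)
  expect_lt(rms(r1k[2000:38000]) / rms(s1k[2000:38000]), 0.05)
  expect_error(butterworth_lowpass(s10, rate, cutoff_hz = 2000), "rate/2")
})

test_that("the Hilbert envelope recovers amplitude and modulation", {
  rate <- 4000
  t <- (0:39999) / rate
  interior <- 2000:38000
  env <- hilbert_envelope(0.7 * sin(2 * pi * 50 * t), rate)
  expect_true(all(env$values >= 0))
  expect_lt(max(abs(env$values[interior] - 0.7)) / 0.7, 0.02)

  expect_true(all(hilbert_envelope(numeric(100), rate)$values == 0))

  modu <- 1 + 0.5 * cos(2 * pi * 2 * t)
  e <- hilbert_envelope(modu * sin(2 * pi * 100 * t), rate)$values
  rel <- sqrt(mean((e[interior] - modu[interior])^2)) /
    sqrt(mean(modu[interior]^2))
  expect_lt(rel, 0.05)
  expect_error(hilbert_envelope(1, rate), "length")
})

test_that("moving-average smoothing is causal, normalized and contractive", {
  expect_equal(smooth_moving_average(c(0, 0, 6, 0, 0), 3), c(0, 0, 2, 2, 2))
  expect_equal(smooth_moving_average(rep(1, 5), 3), c(1/3, 2/3, 1, 1, 1))
  x <- rnorm(50)
  expect_equal(smooth_moving_average(x, 1), x) # N = 1 is the identity
  expect_error(smooth_moving_average(x, 0), ">= 1")

  # total-variation contraction on random signals
  tv <- function(v) sum(abs(diff(v)))
  set.seed(8)
  for (i in 1:20) {
    z <- rnorm(200)
    n <- sample(c(2, 5, 20, 70), 1)
    expect_lte(tv(smooth_moving_average(z, n)), tv(z) + 1e-12)
  }
})

test_that("the envelope threshold is mean plus population deviation", {
  expect_equal(compute_threshold(c(1, 1, 1, 1)), 1.0)
  expect_equal(compute_threshold(c(0, 2, 0, 2)), 2.0)
  expect_equal(compute_threshold(c(0, 0, 3, 3, 0, 0)), 1 + sqrt(2))

  # independent two-pass oracle on 100 random envelopes
  set.seed(11)
  for (i in 1:100) {
    v <- abs(rnorm(sample(10:200, 1), sd = runif(1, 0.1, 5)))
    mu <- sum(v) / length(v)
    ss <- sum((v - mu)^2) / length(v)
    expect_equal(compute_threshold(v), mu + sqrt(ss), tolerance = 1e-9)
  }
})

test_that("boundary detection thresholds the envelope elementwise", {
  env <- c(0, 0, 3, 3, 0, 0)
  expect_equal(detect_fhs_boundaries(env, 1 + sqrt(2)), c(0L, 0L, 1L, 1L, 0L, 0L))
  expect_true(all(detect_fhs_boundaries(c(1, 2, 3), 0) == 1L))
  expect_true(all(detect_fhs_boundaries(env, 4) == 0L))
  expect_error(detect_fhs_boundaries(env, -1), ">= 0")

  # cleanup: sub-threshold blips and micro-gaps are repaired at a known rate
  e2 <- envelope_signal(c(rep(0, 100), rep(1, 100), 0, rep(1, 100),
                          rep(0, 100), 1, rep(0, 100)), 4000)
  m <- detect_fhs_boundaries(e2, 0.5)
  r <- rle(m)
  expect_equal(sum(r$values == 1L), 1L) # gap filled, stray spike removed
  expect_equal(sum(m), 201L)
})

test_that("channel splitting partitions the envelope exactly", {
  e <- abs(rnorm(100))
  expect_equal(split_channels(e, rep(1L, 100)), list(fhs = e, murmur = e * 0))
  expect_equal(split_channels(e, rep(0L, 100))$murmur, e)
  set.seed(3)
  for (i in 1:10) {
    v <- abs(rnorm(64))
    m <- sample(0:1, 64, replace = TRUE)
    ch <- split_channels(v, m)
    expect_identical(ch$fhs + ch$murmur, v)
  }
  expect_error(split_channels(e, c(1L, 0L)), "length")
})

test_that("the mel scale and filterbank are monotone and anchored", {
  expect_equal(mel_scale(0), 0)
  expect_equal(mel_scale(700), 2595 * log10(2))
  expect_equal(mel_scale(1400), 2595 * log10(3))
  expect_error(mel_scale(-1), "nonnegative")
  f <- seq(0, 2000, by = 10)
  expect_true(all(diff(mel_scale(f)) > 0))

  fb <- mel_filterbank(24, 256, 4000)
  expect_equal(dim(fb), c(24L, 129L))
  centers <- apply(fb, 1, which.max)
  expect_true(all(diff(centers) >= 0))
  wcenters <- apply(fb, 1, function(w) sum(w * seq_along(w)) / sum(w))
  expect_true(all(diff(wcenters) > 0))
})

test_that("the log-mel spectrogram has the documented framing and scale", {
  cfg <- mel_config() # window 512, hop 256, 140 mels, 4000 Hz
  x <- sin(2 * pi * 100 * (0:199999) / 4000) # 50 s
  lm <- log_mel_spectrogram(x, cfg)
  expect_equal(dim(lm), c(140L, 1L + (200000L - 512L) %/% 256L))
  expect_equal(dim(lm)[2], 780L)
  # ref = max puts the global maximum at 0 dB
  expect_equal(max(lm), 0)
  # a pure 100 Hz tone peaks in the mel band whose center is nearest 100 Hz
  fb <- mel_filterbank(cfg$n_mels, cfg$window, cfg$rate)
  bin_hz <- (0:(cfg$window / 2)) * cfg$rate / cfg$window
  centers <- apply(fb, 1, function(w) sum(w * bin_hz) / sum(w))
  peak_band <- which.max(rowMeans(lm))
  expect_lt(abs(centers[peak_band] - 100), 10)
  expect_error(log_mel_spectrogram(numeric(100), cfg), "window")
})

test_that("fix_duration crops long signals and tiles short ones", {
  rate <- 4000
  x50 <- rnorm(200000)
  expect_identical(fix_duration(x50, rate, 50), x50)
  x10 <- rnorm(40000)
  tiled <- fix_duration(x10, rate, 50)
  expect_length(tiled, 200000L)
  expect_identical(tiled, rep(x10, 5))
  x60 <- rnorm(240000)
  expect_identical(fix_duration(x60, rate, 50), x60[1:200000])
  # trim removes both ends before fitting (here 80 remain, cropped to 50)
  xt <- fix_duration(1:100, 10, 5, trim = 10)
  expect_identical(xt, as.numeric(11:60))
  # trimmed-short signals tile: 12 remain, tiled to 20
  xs <- fix_duration(1:16, 10, 2, trim = 2)
  expect_identical(xs, as.numeric(rep(3:14, length.out = 20)))
  expect_error(fix_duration(1:10, 10, 1, trim = 5), "trim")
})

test_that("mean peak interval recovers burst spacing and uses a sentinel", {
  rate <- 4000
  tr <- numeric(40000)
  burst <- sin(2 * pi * 80 * (0:399) / rate) *
    0.5 * (1 - cos(2 * pi * (0:399) / 399))
  for (k in 0:19) tr[(k * 2000 + 1):(k * 2000 + 400)] <- burst
  expect_equal(mean_peak_interval(tr, rate), 0.5, tolerance = 0.04)

  single <- numeric(8000)
  single[2001:2400] <- burst
  expect_equal(mean_peak_interval(single, rate), 2) # sentinel = duration
})

test_that("feature combinations produce the documented channels and scalars", {
  fx <- fixture_paired_recordings(1)
  rec <- fx$present[[1]]$recording
  mel <- reduced_mel()

  ft9 <- build_feature_tensor(rec, reduced_feature_set(9), mel)
  expect_equal(ft9$channel_names, c("spec", "murmurs"))
  expect_equal(dim(ft9$channels)[3], 2L)
  expect_equal(names(ft9$scalars), "mean_peak_interval")

  ft1 <- build_feature_tensor(rec, reduced_feature_set(1), mel)
  expect_equal(ft1$channel_names, "spec")
  expect_length(ft1$scalars, 1L)

  ft3 <- build_feature_tensor(rec, reduced_feature_set(3), mel)
  expect_equal(ft3$channel_names, c("spec", "s1s2", "murmurs"))

  ft12 <- build_feature_tensor(rec, reduced_feature_set(12), mel)
  expect_equal(ft12$channel_names, c("spec", "murmurs"))
  expect_length(ft12$scalars, 0L)

  expect_error(feature_set(feature_id = 2), "not provided")
  expect_error(feature_set(spec = FALSE), "spectrogram")

  # all channels share shape; frame count follows the framing formula
  expect_equal(dim(ft3$channels)[1:2],
               c(24L, 1L + (40000L - 256L) %/% 256L))
})

test_that("the murmur channel carries more energy when a murmur is present", {
  fx <- fixture_paired_recordings(3)
  mel <- reduced_mel()
  fs <- reduced_feature_set(5) # unsmoothed murmur channel
  for (i in 1:3) {
    fa <- build_feature_tensor(fx$absent[[i]]$recording, fs, mel)
    fp <- build_feature_tensor(fx$present[[i]]$recording, fs, mel)
    mur <- function(ft) mean(ft$channels[, , match("murmurs", ft$channel_names)])
    expect_lt(mur(fa), mur(fp))
  }
})

test_that("stronger smoothing reduces spurious boundary runs on noisy input", {
  res <- generate_recording(synth_spec(heart_rate_bpm = 90, n_seconds = 10,
                                       murmur = "none", snr_db = -6, seed = 33))
  runs <- vapply(c(20L, 40L, 70L), function(N) {
    m <- boundary_mask_for(res$recording$samples, smooth_n = N,
                           min_run_s = 0, max_gap_s = 0)
    sum(rle(m)$values == 1L)
  }, numeric(1))
  expect_true(all(diff(runs) <= 0))
  expect_lt(runs[3], runs[1])
})
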