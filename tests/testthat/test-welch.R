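cfg <- analysis_config()

test_that("welch PSD localises a sinusoid to its exact frequency bin", {
  fs <- 2500
  t <- seq(0, 60 - 1 / fs, 1 / fs)
  lfp <- make_lfp(sin(2 * pi * 100 * t))
  ps <- welch_psd(lfp, c(0, 60), cfg)
  expect_equal(ps$freqs[2] - ps$freqs[1], 0.25)
  expect_equal(ps$freqs[which.max(ps$power[, 1])], 100)
})

test_that("welch PSD conserves white-noise variance (Parseval)", {
  set.seed(4)
  x <- rnorm(2500 * 60, sd = 3)
  ps <- welch_psd(make_lfp(x), c(0, 60), cfg)
  integral <- sum(ps$power[, 1]) * 0.25
  expect_lt(abs(integral - var(x)) / var(x), 0.05)
})

test_that("off-grid sinusoid leaks to the nearest grid bins", {
  fs <- 2500
  t <- seq(0, 60 - 1 / fs, 1 / fs)
  ps <- welch_psd(make_lfp(sin(2 * pi * 100.1 * t)), c(0, 60), cfg)
  peak <- ps$freqs[which.max(ps$power[, 1])]
  expect_true(peak %in% c(100, 100.25))
  # oracle: direct windowed DFT of one segment at the two candidate bins
  w <- 0.5 * (1 - cos(2 * pi * (0:9999) / 10000))
  seg <- sin(2 * pi * 100.1 * t[1:10000]) * w
  amp <- vapply(c(100, 100.25), function(f)
    Mod(sum(seg * exp(-2i * pi * f * (0:9999) / fs)))^2, 0)
  expect_equal(peak, c(100, 100.25)[which.max(amp)])
})

test_that("blocks shorter than one welch window are rejected", {
  lfp <- make_lfp(rnorm(2500 * 10))
  expect_error(welch_psd(lfp, c(0, 2), cfg), class = "pfc_validation_error")
})

test_that("spectrogram is constant for stationary input and zero for silence", {
  fs <- 2500
  t <- seq(0, 120 - 1 / fs, 1 / fs)
  sg <- spectrogram(make_lfp(sin(2 * pi * 40 * t)), 1, cfg, window_s = 30)
  row40 <- sg$power[, sg$freqs == 40]
  expect_lt(diff(range(row40)) / mean(row40), 1e-6)
  sg0 <- spectrogram(make_lfp(numeric(2500 * 30)), 1, cfg, window_s = 30)
  expect_true(all(sg0$power == 0))
})

test_that("coherence is 1 for identical channels and near-bias for independent ones", {
  set.seed(8)
  x <- rnorm(2500 * 60)
  lfp <- make_lfp(cbind(x, x, rnorm(2500 * 60)))
  co_same <- coherence_spectrum(lfp, 1, 2, c(0, 60), cfg)
  expect_true(all(abs(co_same$coherence - 1) < 1e-9))
  co_ind <- coherence_spectrum(lfp, 1, 3, c(0, 60), cfg)
  expect_lt(mean(co_ind$coherence), 0.2)
  # bias shrinks roughly like 1/n_segments
  co_short <- coherence_spectrum(lfp, 1, 3, c(0, 20), cfg)
  expect_lt(mean(co_ind$coherence), mean(co_short$coherence))
  expect_lt(abs(mean(co_ind$coherence) - 1 / co_ind$n_segments), 0.05)
})

test_that("a shared narrowband component produces a coherence peak", {
  set.seed(9)
  fs <- 2500
  t <- seq(0, 60 - 1 / fs, 1 / fs)
  s <- sin(2 * pi * 40 * t + runif(1) * 2 * pi)
  lfp <- make_lfp(cbind(s + rnorm(length(t)), s + rnorm(length(t))))
  co <- coherence_spectrum(lfp, 1, 2, c(0, 60), cfg)
  expect_equal(co$freqs[which.max(co$coherence)], 40)
  expect_error(coherence_spectrum(make_lfp(cbind(t * 0, t)), 1, 2, c(0, 60),
                                  cfg),
               class = "pfc_validation_error")
})
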