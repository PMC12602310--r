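test_that("generator output is bit-identical under a fixed seed", {
  p <- sim_params(seed = 42, n_units_per_region = c(IL = 3, PL = 3, CG = 2),
                  block_length_s = 20)
  sch <- standard_schedule("r1", "psi_0.3", block_length_s = 20)
  ch <- standard_channels(c(IL = 2, PL = 1, CG = 1))
  l1 <- simulate_lfp(p, sch, ch)
  l2 <- simulate_lfp(p, sch, ch)
  expect_identical(l1$data, l2$data)
  u1 <- simulate_spikes(p, sch)
  u2 <- simulate_spikes(p, sch)
  expect_identical(u1$spikes, u2$spikes)
  expect_identical(u1$meta, u2$meta)
})

test_that("background PSD slope matches the 1/f exponent within 0.1", {
  for (beta in c(1.5, 2)) {
    p <- sim_params(seed = 3,
                    lfp_background = list(beta = beta, rms_uv = 100,
                                          band_components = list()))
    sch <- standard_schedule("r1", "saline", block_length_s = 60)
    lfp <- simulate_lfp(p, sch, standard_channels(c(IL = 1, PL = 1, CG = 1)))
    ps <- welch_psd(lfp, c(0, 420))
    sel <- ps$freqs >= 2 & ps$freqs <= 200
    fit <- stats::lm(log10(ps$power[sel, 1]) ~ log10(ps$freqs[sel]))
    expect_lt(abs(-stats::coef(fit)[2] - beta), 0.1)
  }
})

test_that("null drug effect leaves post/pre rates centred on 1 and no HFO", {
  de_null <- list(frac_decrease = 0, frac_increase = 0, frac_nochange = 1,
                  decrease_factor = 1, increase_factor = 1)
  p <- sim_params(seed = 9, block_length_s = 120,
                  drug_effect = list(saline = de_null, psi_0.3 = de_null,
                                     psi_1.0 = de_null),
                  entropy_drop = c(saline = 0, psi_0.3 = 0, psi_1.0 = 0),
                  hfo = list(center_hz = c(saline = NA, psi_0.3 = 100,
                                           psi_1.0 = 93),
                             bandwidth_hz = 0.5, amplitude_db = 0,
                             depth_center = 0.35, depth_sd = 0.4,
                             onset_s = 0))
  sch <- standard_schedule("r1", "psi_0.3", block_length_s = 120)
  u <- simulate_spikes(p, sch)
  pre <- schedule_blocks(sch, "pre", "rest")
  post <- schedule_blocks(sch, "post", "rest")
  ratios <- vapply(u$spikes, function(st) {
    a <- sum(st >= pre$t_start & st < pre$t_end) / sum(pre$t_end - pre$t_start)
    b <- sum(vapply(seq_len(nrow(post)), function(i)
      sum(st >= post$t_start[i] & st < post$t_end[i]), 0L)) /
      sum(post$t_end - post$t_start)
    b / a
  }, 0)
  expect_lt(abs(mean(ratios) - 1), 3 * sd(ratios) / sqrt(length(ratios)))

  # amplitude_db = 0: pre and post band power indistinguishable
  lfp <- simulate_lfp(p, sch, standard_channels(c(IL = 1, PL = 1, CG = 1)))
  sg <- spectrogram(lfp, 1, analysis_config(), window_s = 30)
  band <- sg$freqs >= 80 & sg$freqs <= 110
  bp <- rowMeans(sg$power[, band])
  pre_w <- sg$t < sch$injection_time_s
  pv <- stats::wilcox.test(bp[pre_w], bp[!pre_w])$p.value
  expect_gt(pv, 0.01)
})

test_that("mixture rate suppression matches its analytic expectation", {
  # half the units halved -> expected mean rate change -25%
  de <- list(frac_decrease = 0.5, frac_increase = 0, frac_nochange = 0.5,
             decrease_factor = 0.5, increase_factor = 1)
  p <- sim_params(seed = 21,
                  n_units_per_region = c(IL = 70, PL = 70, CG = 60),
                  drug_effect = list(saline = de, psi_0.3 = de, psi_1.0 = de),
                  entropy_drop = c(saline = 0, psi_0.3 = 0, psi_1.0 = 0),
                  block_length_s = 120)
  sch <- standard_schedule("r1", "psi_0.3", block_length_s = 120)
  u <- simulate_spikes(p, sch)
  pre <- schedule_blocks(sch, "pre", "rest")
  post <- schedule_blocks(sch, "post", "rest")
  chg <- vapply(u$spikes, function(st) {
    a <- sum(st >= pre$t_start & st < pre$t_end) / sum(pre$t_end - pre$t_start)
    b <- sum(vapply(seq_len(nrow(post)), function(i)
      sum(st >= post$t_start[i] & st < post$t_end[i]), 0L)) /
      sum(post$t_end - post$t_start)
    b / a - 1
  }, 0)
  se <- sd(chg) / sqrt(length(chg))
  expect_lt(abs(mean(chg) - (-0.25)), 3 * se)
})

test_that("make_experiment writes a session that round-trips through io", {
  dir <- tempfile()
  p <- sim_params(seed = 2, n_units_per_region = c(IL = 3, PL = 3, CG = 2),
                  block_length_s = 10)
  ex <- make_experiment(p, out_dir = dir)
  expect_s3_class(ex$lfp, "lfp_recording")
  back_lfp <- read_lfp(ex$paths$lfp)
  expect_equal(dim(back_lfp$data), dim(ex$lfp$data))
  back_u <- read_spikes(ex$paths$spikes, ex$paths$units,
                        span = schedule_span(ex$schedule))
  expect_equal(lengths(back_u$spikes), lengths(ex$units$spikes))
  back_s <- read_schedule(ex$paths$schedule)
  expect_equal(back_s$blocks, ex$schedule$blocks)
  unlink(dir, recursive = TRUE)
})
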