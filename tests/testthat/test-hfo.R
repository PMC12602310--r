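cfg <- analysis_config()

test_that("1/f baseline is exact on pure power laws of any exponent", {
  for (a in c(0, 1, 2, 3.5)) {
    ps <- make_ps(function(f, i) 5 * f^(-a))
    bl <- interpolate_1f_baseline(ps, cfg$hfo_band, cfg$hfo_flanks)
    raw <- ps$power[ps$freqs >= 80 & ps$freqs <= 110, 1]
    expect_lt(max(abs(bl$baseline[, 1] - raw) / raw), 1e-6)
  }
})

test_that("baseline under a band-confined bump recovers the pure power law", {
  bump <- function(f) 3 * exp(-(f - 95)^2 / (2 * 3^2))
  ps <- make_ps(function(f, i) 5 * f^(-2) * (1 + bump(f)))
  bl <- interpolate_1f_baseline(ps, cfg$hfo_band, cfg$hfo_flanks)
  pure <- 5 * bl$freqs^(-2)
  expect_lt(max(abs(bl$baseline[, 1] - pure) / pure), 0.01)
})

test_that("baseline errors on non-positive flank power", {
  ps <- make_ps(function(f, i) ifelse(f > 60 & f < 70, 0, f^(-2)))
  expect_error(interpolate_1f_baseline(ps, cfg$hfo_band, cfg$hfo_flanks),
               class = "pfc_validation_error")
})

test_that("hfo difference is ~0 dB on a power law and gain-invariant", {
  ps <- make_ps(function(f, i) 2 * f^(-2))
  prof <- hfo_power_difference(ps, cfg)
  expect_lt(abs(prof$hfo_diff_db), 0.1)
  # scaling the spectrum by any gain leaves the difference unchanged
  ps10 <- make_ps(function(f, i) 20 * f^(-2) * (1 + 2 * exp(-(f - 100)^2 / 2)))
  ps1 <- make_ps(function(f, i) 2 * f^(-2) * (1 + 2 * exp(-(f - 100)^2 / 2)))
  p10 <- hfo_power_difference(ps10, cfg)
  p1 <- hfo_power_difference(ps1, cfg)
  expect_equal(p10$hfo_diff_db, p1$hfo_diff_db, tolerance = 1e-12)
  expect_equal(p10$peak_freq_hz, p1$peak_freq_hz)
})

test_that("a +6 dB bump is recovered at its centre bin with positive difference", {
  for (ctr in c(100, 93)) {
    ps <- make_ps(function(f, i)
      4 * f^(-2) * (1 + (10^0.6 - 1) * exp(-(f - ctr)^2 / (2 * 0.5^2))))
    prof <- hfo_power_difference(ps, cfg)
    expect_equal(prof$peak_freq_hz, ctr)
    expect_gt(prof$hfo_diff_db, 0)
    expect_equal(prof$peak_diff_db, 6.02, tolerance = 0.01)
  }
})

test_that("region channels follow the selection rules", {
  channels <- data.frame(
    depth_um = c(200, 600, 400, 800, 1200, 100, 300, 700),
    region = c("IL", "IL", "PL", "PL", "PL", "CG", "CG", "CG"))
  channels$normalized_depth <- normalized_depth(
    channels, c(IL = 1000, PL = 1600, CG = 1400))
  # bump maximal on the second IL channel by construction
  ps <- make_ps(function(f, i) {
    d <- if (i == 2) 1 else 0.2
    f^(-2) * (1 + 3 * d * exp(-(f - 100)^2 / (2 * 0.5^2)))
  }, channels)
  sel <- select_region_channels(ps, cfg)
  expect_equal(unname(sel["IL"]), 2L)
  expect_equal(unname(sel["PL"]), 4L)   # nearest PL mid-depth (800 of 1600)
  expect_equal(unname(sel["CG"]), 7L)   # nearest 284 um above CG boundary
  # probe bypassing IL (as in one animal) is an explicit error
  ps_noil <- make_ps(function(f, i) f^(-2),
                     channels[channels$region != "IL", ])
  expect_error(select_region_channels(ps_noil, cfg),
               class = "pfc_region_error")
})

test_that("hfo time course is flat pre-injection and raised post", {
  p <- sim_params(seed = 31, block_length_s = 120)
  sch <- standard_schedule("r1", "psi_0.3", block_length_s = 120)
  lfp <- simulate_lfp(p, sch, standard_channels(c(IL = 1, PL = 0, CG = 0)))
  tc <- band_power_timecourse(lfp, 1, cfg, window_s = 120,
                              injection_time_s = sch$injection_time_s)
  pre <- tc$hfo_diff_db[tc$t_rel_injection_s < 0]
  post <- tc$hfo_diff_db[tc$t_rel_injection_s > 0]
  expect_lt(max(abs(pre)), 0.6)
  expect_gt(mean(post), mean(pre) + 0.1)

  # saline: flat throughout
  sch_s <- standard_schedule("r1", "saline", block_length_s = 120)
  lfp_s <- simulate_lfp(sim_params(seed = 31, block_length_s = 120), sch_s,
                        standard_channels(c(IL = 1, PL = 0, CG = 0)))
  tc_s <- band_power_timecourse(lfp_s, 1, cfg, window_s = 120,
                                injection_time_s = sch_s$injection_time_s)
  expect_lt(max(abs(tc_s$hfo_diff_db)), 0.6)
  # difference-of-conditions series is plain arithmetic on aligned grids
  expect_length(tc$hfo_diff_db - tc_s$hfo_diff_db, nrow(tc))
})
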