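mk_schedule <- function(block_length_s = 300) {
  standard_schedule("r1", "psi_0.3", block_length_s = block_length_s)
}

test_that("rate timecourse is centred on zero for a homogeneous unit", {
  set.seed(16)
  sch <- mk_schedule()
  u <- make_units(list(poisson_train(5, 0, schedule_span(sch))),
                  span = schedule_span(sch))
  rt <- rate_timecourse(u, sch, window_s = 60)
  expect_true(all(abs(rt$delta_hz) < 2))
  expect_lt(abs(mean(rt$delta_hz)), 0.5)
  # the window grid is anchored at the injection and drops partial windows
  expect_true(any(rt$t_rel_injection_s == -30))  # edge exactly on injection
  expect_true(all(rt$t_center_s + 30 <= schedule_span(sch) + 1e-9))
})

test_that("halved post rate shows as delta of minus half the baseline", {
  set.seed(17)
  sch <- mk_schedule()
  inj <- sch$injection_time_s
  st <- c(poisson_train(10, 0, inj),
          poisson_train(5, inj, schedule_span(sch)))
  u <- make_units(list(st), span = schedule_span(sch))
  rt <- rate_timecourse(u, sch, window_s = 60)
  post <- rt$delta_hz[rt$t_rel_injection_s > 0]
  expect_lt(abs(mean(post) - (-0.5 * 10)), 0.6)
})

test_that("rate-change classification combines significance with the twofold gate", {
  set.seed(18)
  pre_b <- data.frame(t_start = 0, t_end = 600)
  post_b <- data.frame(t_start = 600, t_end = 1200)
  # identical rates: no change
  null_u <- c(poisson_train(5, 0, 600), poisson_train(5, 600, 1200))
  expect_equal(classify_rate_change(null_u, pre_b, post_b)$label, "no_change")
  # fivefold suppression: decrease
  dec_u <- c(poisson_train(5, 0, 600), poisson_train(1, 600, 1200))
  r <- classify_rate_change(dec_u, pre_b, post_b)
  expect_equal(r$label, "decrease")
  expect_lt(r$p_value, 0.05)
  # significant but sub-twofold shift stays no_change
  sub_u <- c(poisson_train(5, 0, 600), poisson_train(3.5, 600, 1200))
  r2 <- classify_rate_change(sub_u, pre_b, post_b)
  expect_lt(r2$p_value, 0.05)
  expect_equal(r2$label, "no_change")
  # silent baseline: flagged, not an error
  sil <- classify_rate_change(poisson_train(3, 600, 1200), pre_b, post_b)
  expect_true(sil$zero_baseline)
  expect_error(classify_rate_change(c(1, 2), pre_b,
                                    data.frame(t_start = 600, t_end = 620)),
               class = "pfc_validation_error")
})

test_that("null label frequencies respect the alpha bound", {
  set.seed(19)
  pre_b <- data.frame(t_start = 0, t_end = 600)
  post_b <- data.frame(t_start = 600, t_end = 1200)
  labels <- replicate(150, {
    st <- poisson_train(4, 0, 1200)
    classify_rate_change(st, pre_b, post_b)$label
  })
  expect_lte(mean(labels != "no_change"), 0.05 + 3 * sqrt(0.05 * 0.95 / 150))
})

test_that("change proportions tabulate per stratum with degenerate flags", {
  cls <- data.frame(
    label = c(rep("decrease", 10), rep("no_change", 85), rep("increase", 5),
              rep("no_change", 4)),
    region = c(rep("IL", 100), rep("CG", 4)))
  pr <- change_proportions(cls, by = "region")
  il <- pr[pr$region == "IL", ]
  expect_equal(c(il$p_decrease, il$p_no_change, il$p_increase),
               c(0.10, 0.85, 0.05))
  expect_false(il$degenerate)
  expect_true(pr$degenerate[pr$region == "CG"])  # all one class
})

test_that("simulated dose difference in change proportions is chi-squared detectable", {
  set.seed(20)
  # drug 40% suppressed vs saline 5%: the 2x3 table separates reliably
  detect <- replicate(60, {
    n <- 80
    drug <- table(factor(sample(c("decrease", "no_change"), n, TRUE,
                                c(0.4, 0.6)),
                         levels = c("decrease", "no_change", "increase")))
    sal <- table(factor(sample(c("decrease", "no_change"), n, TRUE,
                               c(0.05, 0.95)),
                        levels = c("decrease", "no_change", "increase")))
    tab <- rbind(drug = drug, saline = sal)[, 1:2]
    chi_squared_proportions(tab, posthoc = FALSE)$p_value < 0.05
  })
  expect_gte(mean(detect), 0.95)
})
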