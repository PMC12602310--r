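test_that("scheirer_ray_hare handles degenerate and single-effect designs", {
  fa <- rep(1:3, each = 10)
  fb <- rep(rep(1:2, 5), 3)
  same <- scheirer_ray_hare(rep(2, 30), fa, fb)
  expect_true(all(same$statistic == 0))
  expect_true(all(same$p_value == 1))
  set.seed(33)
  v <- rnorm(30) + 3 * (fa == 2)   # pure factor-A shift
  s <- scheirer_ray_hare(v, fa, fb)
  expect_lt(s$p_value["A"], 0.01)
  expect_gt(s$p_value["B"], 0.05)
  expect_error(scheirer_ray_hare(v[fa != 1 | fb != 1],
                                 fa[fa != 1 | fb != 1], fb[fa != 1 | fb != 1]),
               class = "pfc_validation_error")
})

test_that("SRH sums of squares agree with a two-way ANOVA on the ranks", {
  set.seed(34)
  fa <- factor(rep(1:3, each = 20))
  fb <- factor(rep(rep(1:2, each = 10), 3))
  v <- rnorm(60) + as.numeric(fa) + 0.5 * (fa == 2 & fb == 1)
  s <- scheirer_ray_hare(v, fa, fb)
  r <- rank(v)
  av <- stats::aov(r ~ fa * fb)
  ss <- summary(av)[[1]][["Sum Sq"]]
  ms_total <- sum((r - mean(r))^2) / (length(r) - 1)
  expect_equal(unname(s$statistic),
               unname(ss[1:3] / ms_total), tolerance = 1e-9)
})

test_that("SRH main effect reduces to Kruskal-Wallis with one constant factor", {
  set.seed(35)
  g <- rep(1:3, each = 8)
  v <- rnorm(24) * 10  # continuous: no ties
  s <- scheirer_ray_hare(v, g, rep(1, 24))
  k <- kruskal_wallis(v, g)
  expect_equal(unname(s$statistic["A"]), unname(k$statistic["H"]),
               tolerance = 1e-9)
})

test_that("kruskal_wallis reproduces the hand-computable small-sample case", {
  k <- kruskal_wallis(c(1, 2, 3, 4, 5, 6), rep(1:2, each = 3))
  expect_equal(unname(k$statistic["H"]), 3.857, tolerance = 1e-3)
  ksame <- kruskal_wallis(rep(c(1, 2, 3), 2), rep(1:2, each = 3))
  expect_gt(ksame$p_value, 0.9)
  expect_error(kruskal_wallis(1:5, rep(1, 5)), class = "pfc_validation_error")
})

test_that("permutation test matches exhaustive enumeration and handles extremes", {
  set.seed(36)
  for (n in c(5, 8, 11)) {
    d <- rnorm(n, 0.3)
    for (tail in c("two", "less", "greater")) {
      p_pkg <- permutation_test(d, tail = tail, exact = TRUE)$p_value
      expect_equal(p_pkg, perm_oracle(d, tail), tolerance = 1e-12,
                   info = paste(n, tail))
    }
    # two-tailed = 2 x one-tailed, capped, for the symmetric null
    p2 <- permutation_test(d, tail = "two", exact = TRUE)$p_value
    p1 <- min(permutation_test(d, tail = "less", exact = TRUE)$p_value,
              permutation_test(d, tail = "greater", exact = TRUE)$p_value)
    expect_lt(abs(p2 - min(1, 2 * p1)), 2 / 2^n)
  }
  # constant negative deltas: one-tailed sampled p at the resolution floor
  set.seed(37)
  pe <- permutation_test(rep(-0.1, 50), B = 1000, tail = "less")
  expect_equal(pe$p_value, 1 / 1001)
  z <- permutation_test(rep(0, 10))
  expect_equal(z$p_value, 1)
  expect_true("all_deltas_zero" %in% z$flags)
})

test_that("chi-squared proportions: omnibus value, post-hocs, degeneracy", {
  tab <- rbind(c(20, 80), c(50, 50))
  r <- chi_squared_proportions(tab)
  expect_equal(unname(r$statistic["X2"]), 19.78, tolerance = 0.1)
  # proportional rows: statistic ~ 0
  prop <- chi_squared_proportions(rbind(c(10, 30), c(20, 60)))
  expect_lt(unname(prop$statistic["X2"]), 1e-9)
  # only one differing pair flagged post-hoc
  tab3 <- rbind(a = c(50, 50), b = c(52, 48), c = c(90, 10))
  r3 <- chi_squared_proportions(tab3, alpha = 0.05)
  expect_lt(r3$p_value, 0.05)
  ph <- vapply(r3$posthoc, function(x)
    x$p_value < x$correction$alpha_corrected, TRUE)
  expect_equal(unname(ph), c(FALSE, TRUE, TRUE))  # a-b same; c differs
  expect_warning(chi_squared_proportions(rbind(c(1, 0, 1), c(0, 2, 1)),
                                         posthoc = FALSE))
})

test_that("partial Bonferroni factor tracks the latent dimensionality", {
  set.seed(38)
  n <- 300
  base <- rnorm(n)
  X1 <- cbind(base, 2 * base, -0.5 * base)  # rank 1
  expect_equal(as.integer(partial_bonferroni_factor(X1)), 1L)
  X5 <- matrix(rnorm(n * 5), n)             # 5 equal-variance directions
  f5 <- partial_bonferroni_factor(X5)
  expect_equal(as.integer(f5), 5L)
  expect_equal(attr(f5, "alpha_corrected"), 0.01)
  for (r in c(2, 3)) {                       # r latent factors + tiny noise
    Z <- matrix(rnorm(n * r), n)
    A <- matrix(rnorm(r * 40), r)
    X <- Z %*% A + matrix(rnorm(n * 40, sd = 1e-4), n)
    expect_equal(as.integer(partial_bonferroni_factor(X)), r)
  }
  expect_error(partial_bonferroni_factor(matrix(1, 10, 3)),
               class = "pfc_validation_error")
})

test_that("cohens_d matches construction and simulation", {
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  set.seed(39)
  a <- rnorm(10000)
  b <- rnorm(10000, -0.8)
  expect_lt(abs(cohens_d(a, b) - 0.8), 0.05)
  expect_error(cohens_d(rep(1, 5), rep(1, 5)), class = "pfc_validation_error")
})

test_that("baseline contrast forms ratios and percent differences", {
  df <- expand.grid(condition = c("saline", "psi_0.3"),
                    phase = c("pre", "post"), kind = c("rest", "task"),
                    rep = 1:4, stringsAsFactors = FALSE)
  df$value <- 10
  df$value[df$condition == "psi_0.3" & df$phase == "post"] <- 12
  bc <- baseline_contrast(df)
  expect_equal(bc$percent_diff$percent_diff, c(20, 20))
  dfe <- df
  dfe$value[dfe$condition == "psi_0.3"] <- dfe$value[dfe$condition == "saline"]
  expect_equal(baseline_contrast(dfe)$percent_diff$percent_diff, c(0, 0))
  dfz <- df
  dfz$value[dfz$phase == "pre"] <- 0
  expect_error(baseline_contrast(dfz), class = "pfc_validation_error")
})

test_that("suppression recovery through the baseline-contrast arithmetic", {
  set.seed(40)
  # 30% post suppression under drug, none under saline, on noisy rates
  mk <- function(cond) {
    expand.grid(condition = cond, phase = c("pre", "post"),
                kind = c("rest", "task"), rep = 1:200,
                stringsAsFactors = FALSE)
  }
  df <- rbind(mk("saline"), mk("psi_1.0"))
  df$value <- rlnorm(nrow(df), log(5), 0.3)
  drop <- df$condition == "psi_1.0" & df$phase == "post"
  df$value[drop] <- df$value[drop] * 0.7
  bc <- baseline_contrast(df)
  expect_lt(max(abs(bc$percent_diff$percent_diff - (-30))), 6)
})

test_that("posthoc wilcoxon applies the requested correction", {
  set.seed(41)
  v <- c(rnorm(10), rnorm(10), rnorm(10) + 3)
  g <- rep(letters[1:3], each = 10)
  ph <- posthoc_wilcoxon(v, g)
  expect_length(ph, 3)
  expect_true(all(vapply(ph, function(x) x$correction$factor == 3L, TRUE)))
  expect_equal(ph[["a-c"]]$correction$alpha_corrected, 0.05 / 3)
  # identical paired samples give p = 1
  pp <- posthoc_wilcoxon(rep(v[1:10], 2), rep(c("x", "y"), each = 10),
                         paired = TRUE)
  expect_equal(pp[["x-y"]]$p_value, 1)
  # frequency-family correction via the PCA factor
  pf <- posthoc_wilcoxon(v, g, correction = "partial_bonferroni",
                         pb_factor = 7L)
  expect_equal(pf[[1]]$correction$alpha_corrected, 0.05 / 7)
})
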