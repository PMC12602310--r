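test_that("binarization follows the one-or-more and half-open conventions", {
  u <- make_units(list(c(0.055, 0.0551, 0.0552),  # 3 spikes, one bin
                       numeric(0),                # silent unit
                       c(0.08)),                  # exactly on a bin edge
                  span = 1)
  b <- binarize(u, c(0, 0.2), bin_s = 0.02)
  expect_equal(ncol(b$states), 10)
  expect_equal(sum(b$states[1, ]), 1)        # 3 spikes -> a single 1
  expect_equal(unname(b$states[1, 3]), 1L)   # bin [0.04, 0.06)
  expect_true(all(b$states[2, ] == 0))
  expect_equal(unname(b$states[3, 5]), 1L)   # 0.08 belongs to [0.08, 0.10)
  expect_equal(unname(b$states[3, 4]), 0L)
  expect_error(binarize(u, c(0, 0.01), bin_s = 0.02),
               class = "pfc_validation_error")
})

test_that("msd reproduces forced examples and stays within [0, 1]", {
  S <- matrix(0L, 3, 60)
  expect_true(all(msd(S, 1:10)$msd_t == 0))   # constant states
  # hand example: displacement 2 of 3 units
  S2 <- cbind(c(0L, 0L, 0L), c(1L, 0L, 1L))
  m2 <- msd(S2, n_range = 1)
  expect_equal(m2$msd_t, 2 / 3)
  set.seed(23)
  S3 <- matrix(rbinom(20 * 300, 1, 0.3), 20)
  m3 <- msd(S3, 1:50)
  expect_true(all(m3$msd_t >= 0 & m3$msd_t <= 1))
  # invariant to unit reordering
  expect_equal(msd(S3[sample(20), ], 1:50)$msd_t, m3$msd_t)
  expect_error(msd(S2, 1:5), class = "pfc_validation_error")
  expect_error(msd(matrix(2L, 3, 10), 1:2), class = "pfc_validation_error")
})

test_that("vectorised msd equals the per-definition triple-loop oracle", {
  set.seed(24)
  for (r in 1:10) {
    N <- sample(2:20, 1)
    Tn <- sample(80:400, 1)
    S <- matrix(rbinom(N * Tn, 1, runif(1, 0.05, 0.5)), N)
    expect_equal(msd(S, 1:50)$msd_t, msd_oracle(S, 1:50), tolerance = 1e-12)
  }
})

test_that("iid Bernoulli states give mean MSD near 2p(1-p)", {
  set.seed(25)
  for (p in c(0.1, 0.2, 0.5)) {
    means <- replicate(12, mean(msd(matrix(rbinom(20 * 800, 1, p), 20),
                                    1:50)$msd_t))
    se <- sd(means) / sqrt(length(means))
    expect_lt(abs(mean(means) - 2 * p * (1 - p)), 3 * se)
  }
})

test_that("msd contrast standardises against the pre distribution", {
  pre <- rnorm(500, 0.4, 0.05)
  expect_equal(msd_contrast(pre, pre)$delta, 0)
  shifted <- pre - 0.05  # exactly one pre-SD... constructed below
  sdp <- sd(pre)
  expect_equal(msd_contrast(pre, pre - sdp)$delta, -1, tolerance = 1e-9)
  # literal mean-subtraction-only variant leaves post in raw units
  lit <- msd_contrast(pre, pre - sdp, scale_post = FALSE)
  expect_equal(lit$delta, -sdp, tolerance = 1e-9)
  expect_error(msd_contrast(rep(0.5, 100), pre),
               class = "pfc_validation_error")
  # multi-block phases are pointwise averaged before pooling
  two <- msd_contrast(list(s1 = list(pre, pre)),
                      list(s1 = list(pre - sdp, pre + sdp)))
  expect_equal(two$delta, 0, tolerance = 1e-9)
})
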