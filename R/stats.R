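#' Uniform statistical-test report
#'
#' Container returned by every test in the statistics layer: test name,
#' statistic(s), degrees of freedom, p-value(s), optional effect size, and
#' the multiple-comparison correction applied (`alpha_corrected =
#' alpha / factor`).
#'
#' @param test Test name.
#' @param statistic Named numeric statistic(s).
#' @param df Degrees of freedom (named, may be NULL).
#' @param p_value p-value(s) in [0, 1].
#' @param effect_size Optional Cohen's d.
#' @param correction list(method, factor, alpha_corrected).
#' @param groups Optional group labels.
#' @param flags Optional character flags (e.g. "all_deltas_zero").
#' @export
stat_report <- function(test, statistic, df = NULL, p_value,
                        effect_size = NULL,
                        correction = list(method = "none", factor = 1,
                                          alpha_corrected = 0.05),
                        groups = NULL, flags = character(0)) {
  if (any(p_value < 0 | p_value > 1, na.rm = TRUE))
    pfc_abort("p-values must lie in [0, 1]", "pfc_validation_error")
  if (correction$factor < 1)
    pfc_abort("correction factor must be >= 1", "pfc_validation_error")
  structure(list(test = test, statistic = statistic, df = df,
                 p_value = p_value, effect_size = effect_size,
                 correction = correction, groups = groups, flags = flags),
            class = "stat_report")
}

#' @export
print.stat_report <- function(x, ...) {
  cat(sprintf("<stat_report> %s\n", x$test))
  for (i in seq_along(x$statistic))
    cat(sprintf("  %s = %.4g%s, p = %.4g\n",
                names(x$statistic)[i] %||% "stat", x$statistic[i],
                if (!is.null(x$df)) sprintf(" (df %s)",
                                            paste(x$df[[min(i, length(x$df))]],
                                                  collapse = ",")) else "",
                x$p_value[min(i, length(x$p_value))]))
  if (!is.null(x$effect_size))
    cat(sprintf("  Cohen's d = %.3f\n", x$effect_size))
  if (x$correction$method != "none")
    cat(sprintf("  correction: %s, factor %d, alpha %.4g\n",
                x$correction$method, x$correction$factor,
                x$correction$alpha_corrected))
  invisible(x)
}

#' Scheirer-Ray-Hare test (two-way ANOVA on ranks)
#'
#' All values are rank-transformed (ties get average ranks) and two-way
#' fixed-effects sums of squares are computed on the ranks; each effect's
#' H statistic is `SS_effect / MS_total` with `MS_total = SS_total/(N-1)`,
#' referred to a chi-squared distribution with the effect's degrees of
#' freedom. The interaction SS is `SS_cells - SS_A - SS_B`. No additional
#' tie correction is applied to MS_total (the classical definition). When
#' one factor has a single level the main-effect H equals Kruskal-Wallis'
#' H without tie correction.
#'
#' @param values Numeric response.
#' @param factor_a,factor_b Factors (coerced).
#' @return A [stat_report()] with H, df and p per effect (A, B, AB).
#' @export
scheirer_ray_hare <- function(values, factor_a, factor_b) {
  fa <- factor(factor_a)
  fb <- factor(factor_b)
  a <- nlevels(fa)
  b <- nlevels(fb)
  if (a < 1 || b < 1 || length(values) < a * b)
    pfc_abort("need n >= levels_A * levels_B observations",
              "pfc_validation_error")
  if (any(table(fa, fb) == 0))
    pfc_abort("empty cell in the two-way design", "pfc_validation_error")
  r <- rank(values)
  N <- length(r)
  rbar <- mean(r)
  ss <- function(f) {
    m <- tapply(r, f, mean)
    n <- tapply(r, f, length)
    sum(n * (m - rbar)^2)
  }
  ss_a <- ss(fa)
  ss_b <- ss(fb)
  ss_cells <- ss(interaction(fa, fb, drop = TRUE))
  ss_ab <- ss_cells - ss_a - ss_b
  ms_total <- sum((r - rbar)^2) / (N - 1)
  H <- if (ms_total == 0) c(A = 0, B = 0, AB = 0)
  else c(A = ss_a, B = ss_b, AB = ss_ab) / ms_total
  df <- c(A = a - 1, B = b - 1, AB = (a - 1) * (b - 1))
  p <- ifelse(df > 0, pchisq(H, df, lower.tail = FALSE), NA)
  stat_report("Scheirer-Ray-Hare", statistic = H, df = as.list(df),
              p_value = p, groups = list(A = levels(fa), B = levels(fb)))
}

#' Kruskal-Wallis test
#'
#' Standard Kruskal-Wallis H with tie correction (delegated to
#' [stats::kruskal.test()]), wrapped into the package's report container.
#'
#' @param values Numeric response.
#' @param groups Group labels.
#' @return A [stat_report()].
#' @export
kruskal_wallis <- function(values, groups) {
  g <- factor(groups)
  if (nlevels(g) < 2)
    pfc_abort("need at least 2 groups", "pfc_validation_error")
  k <- kruskal.test(values, g)
  stat_report("Kruskal-Wallis", statistic = c(H = unname(k$statistic)),
              df = list(unname(k$parameter)), p_value = unname(k$p.value),
              groups = levels(g))
}

#' Sign-flip permutation test on paired differences
#'
#' The statistic is the mean of the paired differences. Under the null the
#' sign of each difference is exchangeable, so signs are flipped at random
#' (`B` draws) or exhaustively (`exact = TRUE`, all 2^n patterns). Sampled
#' p-values include the observed statistic:
#' `p = (1 + #extreme) / (B + 1)`; exact p-values are exact proportions.
#'
#' @param deltas Paired differences.
#' @param B Number of random sign assignments.
#' @param tail "two", "less" or "greater".
#' @param exact Enumerate all sign patterns (n <= 25).
#' @return A [stat_report()]; all-zero deltas give p = 1 with flag
#'   `"all_deltas_zero"`.
#' @export
permutation_test <- function(deltas, B = 10000, tail = c("two", "less",
                                                         "greater"),
                             exact = FALSE) {
  tail <- match.arg(tail)
  d <- as.numeric(deltas)
  n <- length(d)
  if (n < 2) pfc_abort("need at least 2 paired differences",
                       "pfc_validation_error")
  t_obs <- mean(d)
  if (all(d == 0))
    return(stat_report("permutation (sign-flip)", c(mean_delta = 0),
                       p_value = 1, flags = "all_deltas_zero"))
  tol <- 1e-12 * max(1, abs(t_obs))
  if (exact) {
    if (n > 25) pfc_abort("exact enumeration limited to n <= 25",
                          "pfc_validation_error")
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    t_perm <- as.vector(signs %*% d) / n
    p <- switch(tail,
                two = mean(abs(t_perm) >= abs(t_obs) - tol),
                less = mean(t_perm <= t_obs + tol),
                greater = mean(t_perm >= t_obs - tol))
  } else {
    if (B < 1000) pfc_abort("B must be at least 1000", "pfc_validation_error")
    signs <- matrix(sample(c(-1, 1), B * n, replace = TRUE), B, n)
    t_perm <- as.vector(signs %*% d) / n
    p <- switch(tail,
                two = (1 + sum(abs(t_perm) >= abs(t_obs) - tol)) / (B + 1),
                less = (1 + sum(t_perm <= t_obs + tol)) / (B + 1),
                greater = (1 + sum(t_perm >= t_obs - tol)) / (B + 1))
  }
  stat_report("permutation (sign-flip)",
              statistic = c(mean_delta = t_obs), p_value = p,
              flags = if (exact) "exact" else character(0))
}

#' Chi-squared test on a contingency table of proportions
#'
#' Pearson chi-squared (no continuity correction) on the omnibus k x m
#' table, with optional pairwise post-hoc tests on every 2 x m condition
#' pair under a Bonferroni correction over the number of pairs. If any
#' expected cell count is below 1 a warning is issued and Fisher's exact
#' p-value is attached as a fallback.
#'
#' @param tab Matrix of counts, rows = conditions.
#' @param posthoc Run pairwise 2 x m sub-tables.
#' @param alpha Nominal level for the post-hoc correction.
#' @return A [stat_report()]; post-hoc reports in `$posthoc` (named list per
#'   row pair).
#' @export
chi_squared_proportions <- function(tab, posthoc = TRUE, alpha = 0.05) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) pfc_abort("counts must be non-negative",
                              "pfc_validation_error")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    pfc_abort("rows and columns must have positive totals",
              "pfc_validation_error")
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  flags <- character(0)
  exact_p <- NULL
  if (any(ct$expected < 1)) {
    warning("expected cell count < 1; Fisher exact p attached as fallback")
    flags <- "low_expected_counts"
    exact_p <- tryCatch(fisher.test(tab)$p.value, error = function(e) NULL)
  }
  rep <- stat_report("chi-squared",
                     statistic = c(X2 = unname(ct$statistic)),
                     df = list(unname(ct$parameter)),
                     p_value = unname(ct$p.value), flags = flags)
  if (!is.null(exact_p)) rep$exact_p <- exact_p
  if (posthoc && nrow(tab) > 2) {
    pairs <- utils::combn(nrow(tab), 2)
    k <- ncol(pairs)
    rep$posthoc <- lapply(seq_len(k), function(j) {
      sub <- tab[pairs[, j], , drop = FALSE]
      cs <- suppressWarnings(chisq.test(sub, correct = FALSE))
      stat_report("chi-squared (post-hoc pair)",
                  statistic = c(X2 = unname(cs$statistic)),
                  df = list(unname(cs$parameter)),
                  p_value = unname(cs$p.value),
                  correction = list(method = "bonferroni", factor = k,
                                    alpha_corrected = alpha / k),
                  groups = rownames(tab)[pairs[, j]] %||% pairs[, j])
    })
    names(rep$posthoc) <- apply(pairs, 2, paste, collapse = "-")
  }
  rep
}

#' Partial-Bonferroni correction factor from PCA
#'
#' For families of correlated frequency-wise comparisons: PCA on the
#' column-centred observations x variables matrix; the factor is the
#' smallest number of principal components whose cumulative explained
#' variance exceeds `threshold` (95%), and the corrected level is
#' `alpha / factor`. Covariance PCA by default; `scale = TRUE` uses the
#' correlation matrix, making the factor invariant to column rescaling.
#'
#' @param X Observations x variables matrix.
#' @param threshold Cumulative explained-variance threshold.
#' @param scale Standardise columns first.
#' @return Integer factor in `[1, min(dim(X))]`, with attribute
#'   `alpha_corrected` (0.05/factor).
#' @export
partial_bonferroni_factor <- function(X, threshold = 0.95, scale = FALSE) {
  X <- as.matrix(X)
  if (nrow(X) < 2) pfc_abort("need at least 2 observations",
                             "pfc_validation_error")
  if (any(!is.finite(X))) pfc_abort("X must be finite", "pfc_validation_error")
  v <- apply(X, 2, stats::var)
  if (sum(v) == 0) pfc_abort("zero total variance", "pfc_validation_error")
  if (scale) X <- X[, v > 0, drop = FALSE]
  pc <- prcomp(X, center = TRUE, scale. = scale)
  ev <- pc$sdev^2
  k <- which(cumsum(ev) / sum(ev) > threshold)[1]
  structure(as.integer(k), alpha_corrected = 0.05 / k)
}

#' Cohen's d between two groups
#'
#' `(mean(a) - mean(b)) / s_pooled` with the pooled SD weighted by n - 1.
#'
#' @param a,b Numeric samples (each n >= 2).
#' @return Numeric effect size.
#' @export
cohens_d <- function(a, b) {
  na <- length(a)
  nb <- length(b)
  if (na < 2 || nb < 2) pfc_abort("each group needs n >= 2",
                                  "pfc_validation_error")
  sp <- sqrt(((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2))
  if (sp == 0) pfc_abort("zero pooled SD", "pfc_validation_error")
  (mean(a) - mean(b)) / sp
}

#' Baseline-normalised change and percent difference between conditions
#'
#' For each condition and block kind, the change is the mean of the
#' post-injection values divided by the mean of the baseline values; the
#' percent difference of a drug against the reference condition is
#' `100 * (change_drug / change_reference - 1)`, computed separately for
#' rest and task.
#'
#' @param df data.frame with columns `value`, `condition`, `phase`
#'   ("pre"/"post") and `kind` ("rest"/"task").
#' @param reference Reference condition label (vehicle).
#' @return list with `change` (kind x condition data.frame of ratios) and
#'   `percent_diff` (kind x non-reference-condition data.frame).
#' @export
baseline_contrast <- function(df, reference = "saline") {
  need <- c("value", "condition", "phase", "kind")
  if (!all(need %in% names(df)))
    pfc_abort("df needs columns value, condition, phase, kind",
              "pfc_validation_error")
  conds <- unique(df$condition)
  kinds <- unique(df$kind)
  change <- expand.grid(kind = kinds, condition = conds,
                        stringsAsFactors = FALSE)
  change$ratio <- NA_real_
  for (i in seq_len(nrow(change))) {
    sel <- df$condition == change$condition[i] & df$kind == change$kind[i]
    base <- mean(df$value[sel & df$phase == "pre"])
    post <- mean(df$value[sel & df$phase == "post"])
    if (!is.finite(base) || base == 0)
      pfc_abort("zero or missing baseline average", "pfc_validation_error")
    change$ratio[i] <- post / base
  }
  others <- setdiff(conds, reference)
  pd <- expand.grid(kind = kinds, condition = others,
                    stringsAsFactors = FALSE)
  pd$percent_diff <- NA_real_
  for (i in seq_len(nrow(pd))) {
    cd <- change$ratio[change$kind == pd$kind[i] &
                         change$condition == pd$condition[i]]
    cr <- change$ratio[change$kind == pd$kind[i] &
                         change$condition == reference]
    pd$percent_diff[i] <- 100 * (cd / cr - 1)
  }
  list(change = change, percent_diff = pd)
}

#' Pairwise post-hoc Wilcoxon tests
#'
#' Signed-rank (paired) or rank-sum (unpaired) tests for every group pair,
#' with a Bonferroni correction over the number of pairs, a PCA-based
#' partial Bonferroni (supply `pb_factor`), or none.
#'
#' @param values Numeric response.
#' @param groups Group labels.
#' @param paired Use the signed-rank test (groups must align element-wise).
#' @param correction "bonferroni", "partial_bonferroni" or "none".
#' @param pb_factor Correction factor from [partial_bonferroni_factor()]
#'   (required for "partial_bonferroni").
#' @param alpha Nominal level.
#' @return Named list of [stat_report()]s, one per pair.
#' @export
posthoc_wilcoxon <- function(values, groups, paired = FALSE,
                             correction = c("bonferroni",
                                            "partial_bonferroni", "none"),
                             pb_factor = NULL, alpha = 0.05) {
  correction <- match.arg(correction)
  g <- factor(groups)
  lv <- levels(g)
  if (any(table(g) < 2)) pfc_abort("each group needs n >= 2",
                                   "pfc_validation_error")
  pairs <- utils::combn(lv, 2)
  k <- ncol(pairs)
  factor_used <- switch(correction,
                        bonferroni = k,
                        partial_bonferroni = {
                          if (is.null(pb_factor))
                            pfc_abort("pb_factor required", "pfc_validation_error")
                          pb_factor
                        },
                        none = 1)
  out <- lapply(seq_len(k), function(j) {
    x <- values[g == pairs[1, j]]
    y <- values[g == pairs[2, j]]
    w <- if (paired && all(x == y)) list(statistic = 0, p.value = 1)
    else suppressWarnings(wilcox.test(x, y, paired = paired))
    stat_report(if (paired) "Wilcoxon signed-rank" else "Wilcoxon rank-sum",
                statistic = c(W = unname(w$statistic)),
                p_value = unname(w$p.value),
                correction = list(method = correction,
                                  factor = as.integer(factor_used),
                                  alpha_corrected = alpha / factor_used),
                groups = pairs[, j])
  })
  names(out) <- apply(pairs, 2, paste, collapse = "-")
  out
}
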