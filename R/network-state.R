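#' Binarize spike trains into a network state matrix
#'
#' A units x time-bins 0/1 matrix over one block: bin k of unit i is 1 if
#' the unit fired at least once in the half-open bin
#' `[t_start + k*bin_s, t_start + (k+1)*bin_s)` (a spike exactly on a bin
#' edge belongs to the later bin). Column t of the matrix is the network's
#' N-bit state S_t.
#'
#' @param units A [unit_set()].
#' @param block One block row (`t_start`, `t_end`) or numeric
#'   `c(t_start, t_end)`.
#' @param bin_s Bin width, seconds (0.020 for MSD, 0.010 for LZC).
#' @return A `binary_state_matrix`: list with `states` (units x bins integer
#'   matrix), `bin_s`, `t0`, `unit_ids`.
#' @export
binarize <- function(units, block, bin_s = 0.020) {
  stopifnot(inherits(units, "unit_set"))
  if (n_units(units) == 0)
    pfc_abort("empty unit set", "pfc_validation_error")
  if (bin_s <= 0) pfc_abort("bin_s must be positive", "pfc_validation_error")
  block <- as_block_df(block)
  t0 <- block$t_start[1]
  nb <- floor((block$t_end[1] - t0) / bin_s)
  if (nb < 1) pfc_abort("block shorter than one bin", "pfc_validation_error")
  states <- matrix(0L, n_units(units), nb,
                   dimnames = list(units$meta$unit_id, NULL))
  for (i in seq_len(n_units(units))) {
    st <- units$spikes[[units$meta$unit_id[i]]]
    st <- st[st >= t0 & st < t0 + nb * bin_s]
    if (length(st))
      states[i, unique(floor((st - t0) / bin_s) + 1)] <- 1L
  }
  structure(list(states = states, bin_s = bin_s, t0 = t0,
                 unit_ids = units$meta$unit_id),
            class = "binary_state_matrix")
}

#' Mean-squared displacement of the network state
#'
#' For the binarized state S_t (one column per time bin),
#' `MSD_{n,t} = (1/N) * sum_i (s^i_{t+n dt} - s^i_t)^2` -- the Hamming
#' distance between the two states divided by the unit count -- and
#' `MSD_t` is the average of `MSD_{n,t}` over the lag range (1..50 by
#' default, spanning 1 s at 20 ms bins). Only t with all lags available are
#' kept (the tail is truncated). Values lie in [0, 1] and are invariant to
#' unit reordering.
#'
#' @param states A `binary_state_matrix` from [binarize()], or a plain 0/1
#'   units x bins matrix.
#' @param n_range Integer lag steps.
#' @return An `msd_series`: list with `msd_t` (one value per retained bin),
#'   `t` (bin start times, s), `bin_s`, `n_range`.
#' @export
msd <- function(states, n_range = 1:50) {
  if (inherits(states, "binary_state_matrix")) {
    S <- states$states
    bin_s <- states$bin_s
    t0 <- states$t0
  } else {
    S <- as.matrix(states)
    bin_s <- NA_real_
    t0 <- 0
  }
  n_range <- as.integer(n_range)
  nmax <- max(n_range)
  Tn <- ncol(S)
  if (Tn <= nmax)
    pfc_abort("lag range exceeds the number of time bins",
              "pfc_validation_error")
  storage.mode(S) <- "integer"
  msd_t <- tryCatch(.msd_core(S, n_range), error = function(e)
    pfc_abort(conditionMessage(e), "pfc_validation_error"))
  Tt <- Tn - nmax
  structure(list(msd_t = msd_t,
                 t = t0 + (seq_len(Tt) - 1) * bin_s,
                 bin_s = bin_s, n_range = n_range),
            class = "msd_series")
}

# Pointwise average of several MSD series (or numeric vectors), truncated to
# the shortest.
average_series <- function(xs) {
  vs <- lapply(xs, function(x) if (inherits(x, "msd_series")) x$msd_t
               else as.numeric(x))
  L <- min(lengths(vs))
  rowMeans(do.call(cbind, lapply(vs, function(v) v[seq_len(L)])))
}

as_series_list <- function(x) {
  if (inherits(x, "msd_series") || is.numeric(x)) list(x) else x
}

#' Pre/post contrast of MSD distributions
#'
#' Per subject, the pre-injection MSD distribution is z-scored and the
#' post-injection distribution is transformed with the same pre mean (and,
#' by default, the same pre SD, so both phases share units; set
#' `scale_post = FALSE` for mean-subtraction only). Multiple blocks within a
#' phase are pairwise (pointwise) averaged first. Standardized values are
#' then pooled across subjects by concatenation, and
#' `delta = mean(post') - mean(pre')`.
#'
#' @param pre,post Either a single subject's series (an `msd_series`,
#'   numeric vector, or list of them = blocks), or a named list of such
#'   entries, one per subject.
#' @param scale_post Divide the post distribution by the pre SD as well.
#' @return list with `pre_pooled`, `post_pooled`, `delta`, and `subjects`
#'   (per-subject pre mean/SD and delta).
#' @export
msd_contrast <- function(pre, post, scale_post = TRUE) {
  single <- inherits(pre, "msd_series") || is.numeric(pre) ||
    (is.list(pre) && length(pre) &&
       (inherits(pre[[1]], "msd_series") || is.numeric(pre[[1]])))
  if (single) {
    pre <- list(s1 = pre)
    post <- list(s1 = post)
  }
  if (!length(pre) || !length(post) ||
      !identical(sort(names(pre)), sort(names(post))))
    pfc_abort("pre and post must cover the same subjects",
              "pfc_validation_error")
  pre_pool <- post_pool <- numeric(0)
  subj <- list()
  for (s in names(pre)) {
    pv <- average_series(as_series_list(pre[[s]]))
    qv <- average_series(as_series_list(post[[s]]))
    mu <- mean(pv)
    sdv <- stats::sd(pv)
    if (!is.finite(sdv) || sdv == 0)
      pfc_abort(sprintf("pre-phase MSD has zero variance for subject %s", s),
                "pfc_validation_error")
    pz <- (pv - mu) / sdv
    qz <- (qv - mu) / if (scale_post) sdv else 1
    pre_pool <- c(pre_pool, pz)
    post_pool <- c(post_pool, qz)
    subj[[s]] <- data.frame(subject = s, pre_mean = mu, pre_sd = sdv,
                            delta = mean(qz) - mean(pz))
  }
  list(pre_pooled = pre_pool, post_pooled = post_pool,
       delta = mean(post_pool) - mean(pre_pool),
       subjects = do.call(rbind, subj))
}

#' Lempel-Ziv (LZ76) complexity of a binary sequence
#'
#' Phrase count of the exhaustive production history (the final, possibly
#' reproducible phrase counts as one), plus the normalisation
#' `c_norm = c_raw * log2(L) / L`, which tends to 1 for an unbiased random
#' sequence and lets blocks of unequal length be compared.
#'
#' @param sequence Integer/numeric vector of 0s and 1s, length >= 2.
#' @return list(c_raw, c_norm, L).
#' @export
lzc <- function(sequence) {
  s <- as.integer(sequence)
  if (length(s) < 2)
    pfc_abort("sequence must have length >= 2", "pfc_validation_error")
  if (anyNA(s) || !all(s %in% c(0L, 1L)))
    pfc_abort("sequence must be binary (0/1)", "pfc_validation_error")
  L <- length(s)
  c_raw <- .lz76_count(s)
  list(c_raw = c_raw, c_norm = c_raw * log2(L) / L, L = L)
}

#' Per-unit LZC over one block
#'
#' Binarizes each unit at `bin_s` (10 ms by default) over the block and
#' computes [lzc()] per unit.
#'
#' @inheritParams binarize
#' @return data.frame: `unit_id`, `c_raw`, `c_norm`, `L`.
#' @export
lzc_block <- function(units, block, bin_s = 0.010) {
  bsm <- binarize(units, block, bin_s)
  L <- ncol(bsm$states)
  c_raw <- vapply(seq_len(nrow(bsm$states)), function(i)
    .lz76_count(bsm$states[i, ]), 0L)
  data.frame(unit_id = bsm$unit_ids, c_raw = c_raw,
             c_norm = c_raw * log2(L) / L, L = L)
}

#' Pre/post contrast of per-unit LZC
#'
#' Units are matched by id; LZC values are first averaged across the blocks
#' of each phase (pairwise averaging across the post blocks), then
#' `delta = post - pre` per unit. The group-level test is a sign-flip
#' permutation test on the deltas ([permutation_test()]) and the effect size
#' a one-sample Cohen's d, `mean(delta)/sd(delta)`.
#'
#' @param pre,post data.frames as from [lzc_block()] (rows from several
#'   blocks may be stacked), with `unit_id` and `c_norm`.
#' @param value Column to contrast (`"c_norm"` or `"c_raw"`).
#' @param tail,B Passed to [permutation_test()].
#' @return list with `deltas` (named per unit), `report` (a `stat_report`),
#'   `cohens_d`.
#' @export
lzc_contrast <- function(pre, post, value = "c_norm", tail = "two",
                         B = 10000) {
  agg <- function(d) tapply(d[[value]], d$unit_id, mean)
  a <- agg(pre)
  b <- agg(post)
  ids <- intersect(names(a), names(b))
  if (!length(ids))
    pfc_abort("no units matched across phases", "pfc_validation_error")
  deltas <- b[ids] - a[ids]
  rep <- permutation_test(deltas, B = B, tail = tail)
  d_eff <- if (stats::sd(deltas) > 0) mean(deltas) / stats::sd(deltas)
  else NA_real_
  list(deltas = deltas, report = rep, cohens_d = d_eff)
}
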