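#' Firing-rate time course relative to baseline
#'
#' Spike counts per consecutive half-open window divided by the window
#' length, on a grid anchored at the injection time (a window edge falls on
#' the injection); a partial trailing window is dropped. The baseline is the
#' mean rate over the pre-injection phase (rest and task blocks pooled), and
#' `delta_hz` is rate minus baseline.
#'
#' @param units A [unit_set()].
#' @param schedule A [block_schedule()].
#' @param window_s Window length, seconds.
#' @return A `rate_timecourse` data.frame: one row per (unit, window) with
#'   `unit_id`, `t_center_s`, `t_rel_injection_s`, `rate_hz`,
#'   `baseline_hz`, `delta_hz`, and the block `kind`/`phase` the window
#'   centre falls in (NA between blocks).
#' @export
rate_timecourse <- function(units, schedule, window_s = 60) {
  stopifnot(inherits(units, "unit_set"), inherits(schedule, "block_schedule"))
  pre <- schedule_blocks(schedule, phase = "pre")
  if (schedule$day == 0 && nrow(pre) == 0)
    pfc_abort("no pre-injection baseline blocks", "pfc_validation_error")
  t0 <- min(schedule$blocks$t_start)
  t1 <- max(schedule$blocks$t_end)
  inj <- schedule$injection_time_s
  # anchor the grid so a window edge sits on the injection time
  start <- inj - ceiling((inj - t0) / window_s) * window_s
  edges <- seq(start, t1, by = window_s)
  edges <- edges[edges >= t0 - 1e-9]
  if (length(edges) < 2 || edges[length(edges)] + window_s > t1 + 1e-9)
    edges <- edges[seq_len(max(0, length(edges) - 1))]
  lo <- edges
  hi <- edges + window_s
  centers <- (lo + hi) / 2
  bi <- findInterval(centers, schedule$blocks$t_start)
  inside <- bi > 0 & centers < schedule$blocks$t_end[pmax(bi, 1)]
  kind <- ifelse(inside, schedule$blocks$kind[pmax(bi, 1)], NA)
  phase <- ifelse(inside, schedule$blocks$phase[pmax(bi, 1)], NA)
  pre_dur <- sum(pre$t_end - pre$t_start)
  rows <- lapply(units$meta$unit_id, function(u) {
    st <- units$spikes[[u]]
    counts <- vapply(seq_along(lo), function(i)
      sum(st >= lo[i] & st < hi[i]), 0L)
    base <- if (pre_dur > 0)
      sum(vapply(seq_len(nrow(pre)), function(b)
        sum(st >= pre$t_start[b] & st < pre$t_end[b]), 0L)) / pre_dur
    else NA_real_
    data.frame(unit_id = u, t_center_s = centers,
               t_rel_injection_s = centers - inj,
               rate_hz = counts / window_s, baseline_hz = base,
               delta_hz = counts / window_s - base,
               kind = kind, phase = phase)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("rate_timecourse", "data.frame")
  out
}

# Per-bin spike counts of one unit over a set of blocks (half-open bins;
# partial trailing bins within a block are dropped).
block_bin_counts <- function(spike_times, blocks, bin_s) {
  unlist(lapply(seq_len(nrow(blocks)), function(b) {
    t0 <- blocks$t_start[b]
    nb <- floor((blocks$t_end[b] - t0) / bin_s)
    if (nb < 1) return(integer(0))
    st <- spike_times[spike_times >= t0 & spike_times < t0 + nb * bin_s]
    tabulate(floor((st - t0) / bin_s) + 1, nb)
  }))
}

#' Classify one unit's firing-rate change
#'
#' Two-sided Wilcoxon rank-sum test on per-bin spike counts (10 s bins by
#' default) between the pre- and post-injection blocks, combined with a
#' twofold magnitude gate: a unit is labelled `increase` only when the test
#' is significant at `alpha` and the post/pre rate ratio is at least 2,
#' `decrease` when significant and the ratio is at most 0.5; anything else
#' (including significant sub-twofold shifts) is `no_change`. A zero pre
#' rate is guarded with a small epsilon and flagged.
#'
#' @param spike_times Ascending spike times, seconds.
#' @param pre_blocks,post_blocks Block data.frames (`t_start`, `t_end`).
#' @param alpha Per-cell significance level (no multiplicity correction).
#' @param bin_s Count-bin width, seconds.
#' @param eps Rate guard for silent baselines, Hz.
#' @return list(label, fold_change, p_value, pre_rate_hz, post_rate_hz,
#'   zero_baseline).
#' @export
classify_rate_change <- function(spike_times, pre_blocks, post_blocks,
                                 alpha = 0.05, bin_s = 10, eps = 1e-3) {
  pre <- block_bin_counts(spike_times, pre_blocks, bin_s)
  post <- block_bin_counts(spike_times, post_blocks, bin_s)
  if (length(pre) < 5 || length(post) < 5)
    pfc_abort("need at least 5 analysis bins per phase", "pfc_validation_error")
  pre_rate <- mean(pre) / bin_s
  post_rate <- mean(post) / bin_s
  zero_base <- pre_rate == 0
  fold <- (post_rate + if (zero_base) eps else 0) / max(pre_rate, eps)
  p <- if (all(pre == pre[1]) && all(post == post[1]) && pre[1] == post[1]) 1
  else suppressWarnings(wilcox.test(pre, post)$p.value)
  label <- "no_change"
  if (!is.na(p) && p < alpha) {
    if (fold >= 2) label <- "increase"
    if (fold <= 0.5) label <- "decrease"
  }
  list(label = label, fold_change = fold, p_value = p,
       pre_rate_hz = pre_rate, post_rate_hz = post_rate,
       zero_baseline = zero_base)
}

#' Classify rate changes for all units of a set
#'
#' @param units A [unit_set()].
#' @param schedule A [block_schedule()].
#' @param kind Block kind to compare ("rest" by default, per the pre- versus
#'   post-injection rest-block contrast).
#' @param ... Passed to [classify_rate_change()].
#' @return data.frame: unit_id, region, cell_class (if present), label,
#'   fold_change, p_value, pre/post rates.
#' @export
classify_rate_changes <- function(units, schedule, kind = "rest", ...) {
  pre <- schedule_blocks(schedule, phase = "pre", kind = kind)
  post <- schedule_blocks(schedule, phase = "post", kind = kind)
  rows <- lapply(units$meta$unit_id, function(u) {
    r <- classify_rate_change(units$spikes[[u]], pre, post, ...)
    data.frame(unit_id = u, label = r$label, fold_change = r$fold_change,
               p_value = r$p_value, pre_rate_hz = r$pre_rate_hz,
               post_rate_hz = r$post_rate_hz)
  })
  out <- do.call(rbind, rows)
  out <- cbind(out, units$meta[match(out$unit_id, units$meta$unit_id),
                               intersect(c("region", "cell_class"),
                                         names(units$meta)), drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Proportions of rate-change classes per stratum
#'
#' Counts and proportions of decrease / no_change / increase labels within
#' each stratum (e.g. region x cell class x drug). Strata with no units are
#' dropped with a message; a table where every unit falls in one class is
#' flagged degenerate.
#'
#' @param classes data.frame from [classify_rate_changes()] with a `label`
#'   column plus grouping columns.
#' @param by Character vector of grouping column names (may be empty).
#' @return data.frame of counts `n_decrease`, `n_no_change`, `n_increase`,
#'   matching proportions, and a `degenerate` flag, one row per stratum.
#' @export
change_proportions <- function(classes, by = character(0)) {
  lv <- c("decrease", "no_change", "increase")
  split_f <- if (length(by)) interaction(classes[by], drop = TRUE)
  else factor(rep("all", nrow(classes)))
  rows <- lapply(split(classes, split_f), function(d) {
    cnt <- table(factor(d$label, levels = lv))
    cbind(d[1, by, drop = FALSE],
          data.frame(n_decrease = cnt[[1]], n_no_change = cnt[[2]],
                     n_increase = cnt[[3]],
                     p_decrease = cnt[[1]] / nrow(d),
                     p_no_change = cnt[[2]] / nrow(d),
                     p_increase = cnt[[3]] / nrow(d),
                     degenerate = sum(cnt > 0) <= 1))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
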