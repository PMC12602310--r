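#' Run the full injection-day analysis for one session
#'
#' Orchestrates the day-0 pipeline on a session triple: unit QC and
#' filtering, RS/NS/WS classification, Welch spectra per phase and kind,
#' region channel selection, HFO 1/f power difference (profile and time
#' course), firing-rate time course and per-cell change classification,
#' MSD and per-unit LZC contrasts (rest and task analysed separately,
#' never pooled). If the probe misses the infralimbic cortex the HFO
#' topography is reported without IL and the result is flagged.
#'
#' @param lfp An [lfp_recording()].
#' @param units A [unit_set()] (raw; QC is computed here).
#' @param schedule A day-0 [block_schedule()].
#' @param cfg [analysis_config()]; `cfg$rng_seed` seeds the stochastic
#'   steps (permutation tests), making the run deterministic.
#' @return A `session_result` list: `hfo_profile_post`, `hfo_profile_pre`,
#'   `region_channels`, `hfo_timecourse`, `units` (filtered + classified),
#'   `rate_changes`, `change_proportions`, `msd` (per kind contrast),
#'   `lzc` (per kind contrast with permutation report and Cohen's d),
#'   `net_rate_change` (per kind population post/pre ratio), `flags`.
#' @export
run_day0 <- function(lfp, units, schedule, cfg = analysis_config()) {
  stopifnot(inherits(schedule, "block_schedule"), schedule$day == 0)
  with_seed(cfg$rng_seed, {
    flags <- character(0)
    units <- compute_qc(units,
                        n_epochs = max(1, min(100, round(units$span /
                                                           cfg$presence_epoch_s))))
    units <- filter_units(units)
    if (is.null(units$waveforms)) {
      # CSV spike containers carry no waveforms; analyses proceed unclassified
      message("no waveforms available; units left unclassified")
      units$meta$cell_class <- "unclassified"
      flags <- c(flags, "no_waveforms")
    } else {
      units <- classify_cells(units)
    }

    psd <- list()
    for (ph in c("pre", "post")) for (kd in c("rest", "task")) {
      blk <- schedule_blocks(schedule, phase = ph, kind = kd)
      psd[[paste(ph, kd, sep = "_")]] <-
        if (nrow(blk)) welch_psd(lfp, blk, cfg) else NULL
    }
    hfo_post <- hfo_power_difference(psd$post_rest, cfg)
    hfo_pre <- hfo_power_difference(psd$pre_rest, cfg)
    region_channels <- tryCatch(select_region_channels(psd$post_rest, cfg),
                                error = function(e) {
                                  if (inherits(e, "pfc_region_error")) NULL
                                  else stop(e)
                                })
    if (is.null(region_channels)) {
      flags <- c(flags, "missing_region_channel")
      tc_channel <- which.max(hfo_post$hfo_diff_db)
    } else tc_channel <- region_channels[["IL"]]
    hfo_tc <- band_power_timecourse(lfp, tc_channel, cfg,
                                    injection_time_s = schedule$injection_time_s)

    rates <- rate_timecourse(units, schedule, cfg$timecourse_window_s)
    changes <- classify_rate_changes(units, schedule, kind = "rest",
                                     alpha = cfg$alpha, bin_s = cfg$rate_bin_s)
    props <- change_proportions(changes,
                                by = intersect(c("region", "cell_class"),
                                               names(changes)))

    msd_res <- lzc_res <- net_rate <- list()
    for (kd in c("rest", "task")) {
      pre_b <- schedule_blocks(schedule, phase = "pre", kind = kd)
      post_b <- schedule_blocks(schedule, phase = "post", kind = kd)
      pre_m <- lapply(seq_len(nrow(pre_b)), function(b)
        msd(binarize(units, pre_b[b, ], cfg$msd_bin_s), cfg$msd_n_range))
      post_m <- lapply(seq_len(nrow(post_b)), function(b)
        msd(binarize(units, post_b[b, ], cfg$msd_bin_s), cfg$msd_n_range))
      msd_res[[kd]] <- msd_contrast(pre_m, post_m)
      pre_l <- do.call(rbind, lapply(seq_len(nrow(pre_b)), function(b)
        lzc_block(units, pre_b[b, ], cfg$lzc_bin_s)))
      post_l <- do.call(rbind, lapply(seq_len(nrow(post_b)), function(b)
        lzc_block(units, post_b[b, ], cfg$lzc_bin_s)))
      lzc_res[[kd]] <- lzc_contrast(pre_l, post_l)
      rate_of <- function(blocks) {
        dur <- sum(blocks$t_end - blocks$t_start)
        sum(vapply(units$spikes, function(st)
          sum(vapply(seq_len(nrow(blocks)), function(b)
            sum(st >= blocks$t_start[b] & st < blocks$t_end[b]), 0L)),
          0L)) / dur
      }
      net_rate[[kd]] <- rate_of(post_b) / rate_of(pre_b)
    }
    structure(list(
      subject = schedule$subject_id, drug = schedule$drug,
      hfo_profile_post = hfo_post, hfo_profile_pre = hfo_pre,
      region_channels = region_channels, hfo_timecourse = hfo_tc,
      units = units, rates = rates, rate_changes = changes,
      change_proportions = props, msd = msd_res, lzc = lzc_res,
      net_rate_change = net_rate, flags = flags),
      class = "session_result")
  })
}

#' @export
print.session_result <- function(x, ...) {
  cat(sprintf("<session_result> subject %s, %s; %d units\n", x$subject,
              x$drug, nrow(x$units$meta)))
  i <- which.max(x$hfo_profile_post$peak_diff_db)
  cat(sprintf("  HFO (post rest): peak 1/f difference %.2f dB at %.2f Hz [%s]\n",
              x$hfo_profile_post$peak_diff_db[i],
              x$hfo_profile_post$peak_freq_hz[i],
              x$hfo_profile_post$region[i]))
  for (kd in names(x$msd))
    cat(sprintf("  %s: dMSD = %+.3f, dLZC = %+.4f (p = %.3g), post/pre rate = %.3f\n",
                kd, x$msd[[kd]]$delta, mean(x$lzc[[kd]]$deltas),
                x$lzc[[kd]]$report$p_value, x$net_rate_change[[kd]]))
  invisible(x)
}

#' Longitudinal power and coherence changes across days
#'
#' For each recorded day, the rest-block power spectrum on each region's
#' selected channel and the IL-PL magnitude-squared coherence are referenced
#' to the day-0 pre-injection baseline as log ratios (post/baseline on the
#' same channel). When matching vehicle sessions are supplied the drug and
#' vehicle ratios are differenced per [baseline_contrast()] arithmetic.
#' Missing days yield a partial result with a message.
#'
#' @param sessions Named list (names = days "0", "1", "2", "6") of session
#'   triples `list(lfp, units, schedule)` for one subject and drug.
#' @param saline_sessions Optional vehicle sessions in the same layout.
#' @param cfg [analysis_config()].
#' @return list with `power` (day x region x frequency log2 power ratios,
#'   long data.frame), `coherence` (day x frequency IL-PL coherence change),
#'   and `days_missing`.
#' @export
run_longitudinal <- function(sessions, saline_sessions = NULL,
                             cfg = analysis_config()) {
  if (!"0" %in% names(sessions))
    pfc_abort("a day-0 session is required as the shared baseline",
              "pfc_validation_error")
  ratios <- function(sess) {
    s0 <- sess[["0"]]
    base_ps <- welch_psd(s0$lfp, schedule_blocks(s0$schedule, "pre", "rest"),
                         cfg)
    chans <- select_region_channels(
      welch_psd(s0$lfp, schedule_blocks(s0$schedule, "post", "rest"), cfg), cfg)
    base_coh <- coherence_spectrum(s0$lfp, chans[["IL"]], chans[["PL"]],
                                   schedule_blocks(s0$schedule, "pre", "rest"),
                                   cfg)
    pow <- list()
    coh <- list()
    for (d in names(sess)) {
      s <- sess[[d]]
      blk <- schedule_blocks(s$schedule, "post", "rest")
      ps <- welch_psd(s$lfp, blk, cfg)
      for (r in REGIONS)
        pow[[paste(d, r)]] <- data.frame(
          day = as.integer(d), region = r, freq_hz = ps$freqs,
          log2_power_ratio = log2(ps$power[, chans[[r]]] /
                                    base_ps$power[, chans[[r]]]))
      cs <- coherence_spectrum(s$lfp, chans[["IL"]], chans[["PL"]], blk, cfg)
      coh[[d]] <- data.frame(day = as.integer(d), freq_hz = cs$freqs,
                             coherence_change = cs$coherence - base_coh$coherence)
    }
    list(power = do.call(rbind, pow), coherence = do.call(rbind, coh))
  }
  drug <- ratios(sessions)
  out <- list(power = drug$power, coherence = drug$coherence)
  if (!is.null(saline_sessions)) {
    sal <- ratios(saline_sessions)
    m <- merge(drug$power, sal$power, by = c("day", "region", "freq_hz"),
               suffixes = c("_drug", "_saline"))
    m$log2_ratio_diff <- m$log2_power_ratio_drug - m$log2_power_ratio_saline
    out$power_vs_saline <- m
    mc <- merge(drug$coherence, sal$coherence, by = c("day", "freq_hz"),
                suffixes = c("_drug", "_saline"))
    mc$coherence_diff <- mc$coherence_change_drug - mc$coherence_change_saline
    out$coherence_vs_saline <- mc
  }
  out$days_missing <- setdiff(c("0", "1", "2", "6"), names(sessions))
  if (length(out$days_missing))
    message("longitudinal result missing day(s): ",
            paste(out$days_missing, collapse = ", "))
  rownames(out$power) <- NULL
  out
}
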