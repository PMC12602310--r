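#' Interpolated 1/f baseline under a band
#'
#' Fits a line to log10(power) versus log10(frequency) over the two flank
#' bands and evaluates it on the bins of the target band, per channel. This
#' is the power-law (1/f) baseline against which narrowband oscillations are
#' unmasked: on a pure power law of any exponent the baseline reproduces the
#' raw spectrum exactly.
#'
#' @param ps A `power_spectrum` from [welch_psd()].
#' @param band Numeric `c(lo, hi)` Hz, the band to evaluate the baseline on.
#' @param flanks List of two `c(lo, hi)` flank bands the fit uses.
#' @return list with `freqs` (band bins) and `baseline` (band-bins x channel
#'   matrix, same units as `ps$power`).
#' @export
interpolate_1f_baseline <- function(ps, band = c(80, 110),
                                    flanks = list(c(60, 80), c(110, 130))) {
  stopifnot(inherits(ps, "power_spectrum"))
  f <- ps$freqs
  in_flank <- Reduce(`|`, lapply(flanks, function(fl) f >= fl[1] & f <= fl[2]))
  in_band <- f >= band[1] & f <= band[2]
  for (fl in flanks)
    if (sum(f >= fl[1] & f <= fl[2]) < 4)
      pfc_abort("each flank band must contain at least 4 frequency bins",
                "pfc_validation_error")
  if (!any(in_band))
    pfc_abort("band contains no frequency bins", "pfc_validation_error")
  pf <- ps$power[in_flank, , drop = FALSE]
  if (any(pf <= 0))
    pfc_abort(paste("non-positive power in flank bins; add a small",
                    "regularisation epsilon to the spectrum first"),
              "pfc_validation_error")
  lx <- log10(f[in_flank])
  X <- cbind(1, lx)
  beta <- solve(crossprod(X), crossprod(X, log10(pf)))   # 2 x nchan
  lb <- cbind(1, log10(f[in_band])) %*% beta
  list(freqs = f[in_band], baseline = 10^lb)
}

#' 1/f power difference and HFO profile per channel
#'
#' Per channel, `diff(f) = 10 log10(raw/baseline)` over the HFO band, where
#' the baseline is the log-log linear interpolation fitted on the flanks
#' ([interpolate_1f_baseline()]). `hfo_diff_db` is the mean of `diff(f)` over
#' the band and `peak_freq_hz` the bin of maximum difference. The measure is
#' a power ratio, hence invariant to overall gain.
#'
#' @inheritParams interpolate_1f_baseline
#' @param cfg [analysis_config()] supplying `hfo_band` and `hfo_flanks`.
#' @return An `hfo_profile` data.frame: one row per channel with `channel`,
#'   `region`, `depth_um`, `normalized_depth`, `hfo_diff_db`, `peak_diff_db`
#'   (the difference at the peak bin) and `peak_freq_hz`.
#'   The per-bin differences are attached as attribute `diff_db`
#'   (band-bins x channels) with `freqs`.
#' @export
hfo_power_difference <- function(ps, cfg = analysis_config()) {
  bl <- interpolate_1f_baseline(ps, cfg$hfo_band, cfg$hfo_flanks)
  in_band <- ps$freqs >= cfg$hfo_band[1] & ps$freqs <= cfg$hfo_band[2]
  diff_db <- 10 * (log10(ps$power[in_band, , drop = FALSE]) -
                     log10(bl$baseline))
  peak_i <- apply(diff_db, 2, which.max)
  ch <- ps$channels
  out <- data.frame(
    channel = seq_len(ncol(diff_db)),
    region = ch$region, depth_um = ch$depth_um,
    normalized_depth = ch$normalized_depth %||% rep(NA_real_, nrow(ch)),
    hfo_diff_db = colMeans(diff_db),
    peak_diff_db = diff_db[cbind(peak_i, seq_along(peak_i))],
    peak_freq_hz = bl$freqs[peak_i])
  attr(out, "diff_db") <- diff_db
  attr(out, "freqs") <- bl$freqs
  class(out) <- c("hfo_profile", "data.frame")
  out
}

#' Select the analysis channel for each region
#'
#' IL: the channel with the largest 1/f power difference in the HFO band
#' (the ~100 Hz peak). PL: the channel nearest the region's mid-depth.
#' CG: the channel nearest `cfg$cg_offset_um` above the cingulate ventral
#' boundary. Sessions whose probe misses a region raise an error naming it.
#'
#' @param ps A `power_spectrum` (typically over post-injection rest blocks).
#' @param cfg [analysis_config()].
#' @return Named integer vector (IL, PL, CG) of channel indices.
#' @export
select_region_channels <- function(ps, cfg = analysis_config()) {
  ch <- ps$channels
  prof <- hfo_power_difference(ps, cfg)
  sel <- c(IL = NA_integer_, PL = NA_integer_, CG = NA_integer_)
  for (r in REGIONS) {
    idx <- which(ch$region == r)
    if (!length(idx))
      pfc_abort(sprintf("no channels in region %s", r), "pfc_region_error")
    sel[r] <- switch(r,
      IL = idx[which.max(prof$hfo_diff_db[idx])],
      PL = {
        nd <- ch$normalized_depth[idx]
        if (all(is.na(nd))) {
          mid <- (min(ch$depth_um[idx]) + max(ch$depth_um[idx])) / 2
          idx[which.min(abs(ch$depth_um[idx] - mid))]
        } else idx[which.min(abs(nd - 1.5))]
      },
      CG = idx[which.min(abs(ch$depth_um[idx] - cfg$cg_offset_um))])
  }
  sel
}

#' Time course of the HFO 1/f power difference
#'
#' [hfo_power_difference()] per consecutive non-overlapping window on one
#' channel, aligned to the injection time.
#'
#' @param lfp An [lfp_recording()].
#' @param channel Channel index.
#' @param cfg [analysis_config()].
#' @param window_s Window length, seconds.
#' @param injection_time_s Injection time on the recording clock, seconds.
#' @return data.frame with `t_center_s`, `t_rel_injection_s`, `hfo_diff_db`,
#'   `peak_freq_hz`.
#' @export
band_power_timecourse <- function(lfp, channel, cfg = analysis_config(),
                                  window_s = cfg$timecourse_window_s,
                                  injection_time_s = 0) {
  n <- nrow(lfp$data)
  nwin <- round(window_s * lfp$fs)
  starts <- seq(1, n - nwin + 1, by = nwin)
  rows <- lapply(starts, function(s) {
    sub <- lfp_recording(lfp$data[s:(s + nwin - 1), channel, drop = FALSE],
                         lfp$fs, lfp$channels[channel, , drop = FALSE])
    ps <- welch_psd(sub, c(0, nwin / lfp$fs), cfg)
    prof <- hfo_power_difference(ps, cfg)
    data.frame(t_center_s = (s - 1) / lfp$fs + window_s / 2,
               hfo_diff_db = prof$hfo_diff_db[1],
               peak_freq_hz = prof$peak_freq_hz[1])
  })
  out <- do.call(rbind, rows)
  out$t_rel_injection_s <- out$t_center_s - injection_time_s
  out[, c("t_center_s", "t_rel_injection_s", "hfo_diff_db", "peak_freq_hz")]
}
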