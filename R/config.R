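#' Analysis configuration
#'
#' Bundles the spectral, binning and statistical parameters shared across the
#' pipeline. Defaults follow the study protocol: 4 s non-overlapping Welch
#' windows giving 0.25 Hz bins at 2.5 kHz, an 80--110 Hz high-frequency
#' oscillation (HFO) band with 60--80 and 110--130 Hz interpolation flanks,
#' 20 ms state bins with lags 1--50 for mean-squared displacement (1 s
#' horizon), and 10 ms bins for Lempel-Ziv complexity.
#'
#' @param welch_window_s Welch segment length in seconds.
#' @param welch_overlap Fractional overlap between Welch segments (0 = none).
#' @param freq_resolution_hz Expected frequency-grid spacing in Hz; checked
#'   against `welch_window_s` (resolution is `1/welch_window_s`).
#' @param hfo_band Numeric length-2, Hz: band over which the 1/f power
#'   difference is summarised.
#' @param hfo_flanks List of two length-2 numeric vectors, Hz: flank bands the
#'   1/f baseline is fitted on; must not intersect `hfo_band`.
#' @param msd_bin_s State bin width for mean-squared displacement, seconds.
#' @param msd_n_range Integer lag steps over which MSD is averaged.
#' @param lzc_bin_s Bin width for Lempel-Ziv binarization, seconds.
#' @param timecourse_window_s Window length for band-power and firing-rate
#'   time courses, seconds.
#' @param rate_bin_s Bin width for per-cell pre/post rate comparison, seconds.
#' @param cg_offset_um Depth above the cingulate ventral boundary at which the
#'   cingulate channel is selected, micrometres.
#' @param presence_epoch_s Epoch duration for the presence-ratio QC metric,
#'   seconds. The full ~2 h protocol split into the conventional 100 epochs
#'   gives ~72 s epochs; holding the duration (not the count) fixed keeps the
#'   metric's timescale invariant under scaled-down schedules.
#' @param alpha Nominal significance level.
#' @param block_length_s Nominal block length, seconds (900 in the full
#'   protocol; scaled-down simulations use 60).
#' @param rng_seed Optional integer seed used by stochastic pipeline steps.
#' @return An object of class `pfc_config` (a validated list).
#' @export
#' @examples
#' cfg <- analysis_config()
#' cfg$hfo_band
analysis_config <- function(welch_window_s = 4,
                            welch_overlap = 0,
                            freq_resolution_hz = 0.25,
                            hfo_band = c(80, 110),
                            hfo_flanks = list(c(60, 80), c(110, 130)),
                            msd_bin_s = 0.020,
                            msd_n_range = 1:50,
                            lzc_bin_s = 0.010,
                            timecourse_window_s = 60,
                            rate_bin_s = 10,
                            cg_offset_um = 284,
                            presence_epoch_s = 72,
                            alpha = 0.05,
                            block_length_s = 900,
                            rng_seed = NULL) {
  cfg <- list(
    welch_window_s = welch_window_s, welch_overlap = welch_overlap,
    freq_resolution_hz = freq_resolution_hz,
    hfo_band = as.numeric(hfo_band), hfo_flanks = lapply(hfo_flanks, as.numeric),
    msd_bin_s = msd_bin_s, msd_n_range = as.integer(msd_n_range),
    lzc_bin_s = lzc_bin_s,
    timecourse_window_s = timecourse_window_s, rate_bin_s = rate_bin_s,
    cg_offset_um = cg_offset_um, presence_epoch_s = presence_epoch_s,
    alpha = alpha,
    block_length_s = block_length_s, rng_seed = rng_seed)
  validate_config(cfg)
}

validate_config <- function(cfg) {
  pos <- c("welch_window_s", "freq_resolution_hz", "msd_bin_s", "lzc_bin_s",
           "timecourse_window_s", "rate_bin_s", "presence_epoch_s", "alpha",
           "block_length_s")
  for (f in pos)
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 || cfg[[f]] <= 0)
      pfc_abort(sprintf("config field '%s' must be a positive scalar", f),
                "pfc_config_error")
  if (cfg$welch_overlap < 0 || cfg$welch_overlap >= 1)
    pfc_abort("welch_overlap must be in [0, 1)", "pfc_config_error")
  if (abs(1 / cfg$welch_window_s - cfg$freq_resolution_hz) > 1e-9)
    pfc_abort("freq_resolution_hz must equal 1/welch_window_s",
              "pfc_config_error")
  if (length(cfg$hfo_band) != 2 || diff(cfg$hfo_band) <= 0)
    pfc_abort("hfo_band must be an increasing [lo, hi] pair", "pfc_config_error")
  for (fl in cfg$hfo_flanks) {
    if (length(fl) != 2 || diff(fl) <= 0)
      pfc_abort("each hfo flank must be an increasing [lo, hi] pair",
                "pfc_config_error")
    if (fl[1] < cfg$hfo_band[2] && fl[2] > cfg$hfo_band[1])
      pfc_abort("hfo flanks must not overlap the interior of hfo_band",
                "pfc_config_error")
  }
  if (any(cfg$msd_n_range < 1)) pfc_abort("msd_n_range must be >= 1",
                                          "pfc_config_error")
  structure(cfg, class = "pfc_config")
}

#' @export
print.pfc_config <- function(x, ...) {
  cat("<pfc_config>\n")
  cat(sprintf("  Welch: %gs windows, overlap %g, %g Hz bins\n",
              x$welch_window_s, x$welch_overlap, x$freq_resolution_hz))
  cat(sprintf("  HFO band: %g-%g Hz; flanks %s\n", x$hfo_band[1], x$hfo_band[2],
              paste(vapply(x$hfo_flanks, function(f)
                sprintf("%g-%g", f[1], f[2]), ""), collapse = ", ")))
  cat(sprintf("  MSD: %g ms bins, lags %d-%d; LZC: %g ms bins\n",
              1000 * x$msd_bin_s, min(x$msd_n_range), max(x$msd_n_range),
              1000 * x$lzc_bin_s))
  invisible(x)
}
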