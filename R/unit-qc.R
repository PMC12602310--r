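#' Spike-sorting quality metrics for one unit
#'
#' Three standard post-sorting metrics:
#' \describe{
#' \item{isi_violations}{Ratio of observed refractory-period violations
#'   (inter-spike intervals below `isi_threshold_s`, censored below
#'   `min_isi_s`) to the number expected for a Poisson process at the unit's
#'   mean rate: `n_viol * T / (2 * n^2 * (t_r - t_c))`. Zero for a clean
#'   unit; values near 1 indicate chance-level contamination.}
#' \item{presence_ratio}{Fraction of `n_epochs` equal-length epochs spanning
#'   the recording that contain at least one spike.}
#' \item{amplitude_cutoff}{Estimated fraction of spikes missed below the
#'   detection threshold, from the symmetric-distribution assumption: the
#'   upper tail of the (smoothed, 500-bin) spike-amplitude histogram is
#'   matched against the height of the lowest bin; capped at 0.5.}
#' }
#'
#' @param spike_times Ascending spike times, seconds.
#' @param span Recording span, seconds.
#' @param amplitudes Optional per-spike amplitudes; without them
#'   `amplitude_cutoff` is NA.
#' @param isi_threshold_s Refractory threshold (default 1.5 ms).
#' @param min_isi_s Censoring floor for ISIs.
#' @param n_epochs Presence-ratio epochs.
#' @param n_bins Amplitude-histogram bins.
#' @return list(isi_violations, amplitude_cutoff, presence_ratio).
#' @export
qc_metrics <- function(spike_times, span, amplitudes = NULL,
                       isi_threshold_s = 0.0015, min_isi_s = 0,
                       n_epochs = 100, n_bins = 500) {
  if (!is.numeric(span) || span <= 0)
    pfc_abort("recording span must be positive", "pfc_validation_error")
  n <- length(spike_times)
  if (n < 2) {
    isi_viol <- 0
  } else {
    isi <- diff(spike_times)
    n_viol <- sum(isi >= min_isi_s & isi < isi_threshold_s)
    isi_viol <- n_viol * span / (2 * n^2 * (isi_threshold_s - min_isi_s))
  }
  edges <- seq(0, span, length.out = n_epochs + 1)
  occupied <- unique(pmin(n_epochs, findInterval(spike_times, edges,
                                                 left.open = FALSE)))
  presence <- length(setdiff(occupied, 0)) / n_epochs
  if (n == 0) presence <- 0
  cutoff <- if (is.null(amplitudes)) NA_real_ else
    amplitude_cutoff(amplitudes, n_bins)
  list(isi_violations = isi_viol, amplitude_cutoff = cutoff,
       presence_ratio = presence)
}

# Missed-spike fraction from the amplitude histogram, assuming a symmetric
# amplitude distribution truncated at the low end by the detection threshold:
# the mass of the upper tail beyond the point mirroring the lowest observed
# amplitude estimates the truncated mass. The tail/observed ratio m is
# converted to a fraction of the full distribution, m/(1+m).
amplitude_cutoff <- function(amplitudes, n_bins = 500, smooth_sd_bins = 3) {
  h <- graphics::hist(amplitudes, breaks = n_bins, plot = FALSE)
  pdf <- gauss_smooth(h$counts, smooth_sd_bins)
  peak <- which.max(pdf)
  if (peak >= length(pdf)) return(0.5)
  upper <- (peak + 1):length(pdf)
  g <- upper[which.min(abs(pdf[upper] - pdf[1]))]
  m <- sum(pdf[g:length(pdf)]) / sum(pdf)
  min(0.5, m / (1 + m))
}

gauss_smooth <- function(x, sd_bins) {
  if (sd_bins <= 0) return(x)
  k <- stats::dnorm(seq(-4 * sd_bins, 4 * sd_bins), sd = sd_bins)
  k <- k / sum(k)
  pad <- (length(k) - 1) / 2
  xp <- c(rep(x[1], pad), x, rep(x[length(x)], pad))
  as.numeric(stats::filter(xp, k, sides = 2))[(pad + 1):(pad + length(x))]
}

#' Compute QC metrics for every unit of a set
#'
#' @param units A [unit_set()].
#' @param amplitudes Optional named list of per-spike amplitude vectors.
#' @param ... Passed to [qc_metrics()].
#' @return The unit set with `isi_violations`, `amplitude_cutoff`,
#'   `presence_ratio` columns added to `meta`.
#' @export
compute_qc <- function(units, amplitudes = NULL, ...) {
  stopifnot(inherits(units, "unit_set"))
  qc <- lapply(units$meta$unit_id, function(u)
    qc_metrics(units$spikes[[u]], units$span, amplitudes[[u]], ...))
  units$meta$isi_violations <- vapply(qc, `[[`, 0, "isi_violations")
  units$meta$amplitude_cutoff <- vapply(qc, `[[`, 0, "amplitude_cutoff")
  units$meta$presence_ratio <- vapply(qc, `[[`, 0, "presence_ratio")
  units
}

#' Filter units on quality-control thresholds
#'
#' Retains units with `isi_violations < 0.5`, `amplitude_cutoff < 0.1` and
#' `presence_ratio > 0.9` (strict inequalities). Units with NA
#' amplitude_cutoff (no amplitudes available) are judged on the other two
#' metrics. Idempotent.
#'
#' @param units A [unit_set()] whose meta has QC columns (see [compute_qc()]).
#' @param max_isi_violations,max_amplitude_cutoff,min_presence_ratio
#'   Thresholds.
#' @return The filtered [unit_set()].
#' @export
filter_units <- function(units, max_isi_violations = 0.5,
                         max_amplitude_cutoff = 0.1,
                         min_presence_ratio = 0.9) {
  m <- units$meta
  if (is.null(m$isi_violations))
    pfc_abort("run compute_qc() before filter_units()", "pfc_validation_error")
  amp_ok <- is.na(m$amplitude_cutoff) | m$amplitude_cutoff < max_amplitude_cutoff
  keep <- m$isi_violations < max_isi_violations & amp_ok &
    m$presence_ratio > min_presence_ratio
  message(sprintf("filter_units: %d/%d units pass QC", sum(keep), length(keep)))
  subset_units(units, keep)
}
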