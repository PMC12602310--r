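#' Cell-classification parameters
#'
#' Thresholds for the waveform/autocorrelogram classifier: units with
#' trough-to-peak width below `narrow_width_us` are narrow-spiking putative
#' interneurons (NS); of the remaining broad units, those whose
#' autocorrelogram rise time exceeds `wide_tau_rise_ms` are wide-slow
#' spiking (WS) and the rest regular-spiking putative pyramidal cells (RS).
#'
#' @param narrow_width_us Trough-to-peak threshold, microseconds.
#' @param wide_tau_rise_ms Autocorrelogram tau-rise threshold, milliseconds.
#' @param acg_bin_ms,acg_window_ms Autocorrelogram bin width and half-window.
#' @param min_spikes Minimum spike count for the ACG fit.
#' @export
cell_class_params <- function(narrow_width_us = 425, wide_tau_rise_ms = 6,
                              acg_bin_ms = 0.5, acg_window_ms = 50,
                              min_spikes = 100) {
  stopifnot(narrow_width_us > 0, wide_tau_rise_ms > 0, acg_bin_ms > 0,
            acg_window_ms > acg_bin_ms)
  list(narrow_width_us = narrow_width_us, wide_tau_rise_ms = wide_tau_rise_ms,
       acg_bin_ms = acg_bin_ms, acg_window_ms = acg_window_ms,
       min_spikes = min_spikes)
}

#' Trough-to-peak spike width
#'
#' Width in microseconds from the waveform trough to the following peak,
#' measured after 10x cubic-spline upsampling for sub-sample resolution.
#' Scale-invariant by construction. Returns NA for flat waveforms.
#'
#' @param waveform Mean spike waveform (trough-negative).
#' @param waveform_fs Waveform sampling rate, Hz.
#' @export
spike_width_us <- function(waveform, waveform_fs = 30000) {
  if (length(waveform) < 4 || diff(range(waveform)) <
      1e-9 * max(abs(waveform), 1e-300) || all(waveform == 0))
    return(NA_real_)
  n <- length(waveform)
  up <- stats::spline(seq_len(n), waveform, n = 10 * n)
  trough <- which.min(up$y)
  if (trough >= length(up$y)) return(NA_real_)
  peak <- trough + which.max(up$y[(trough + 1):length(up$y)])
  (up$x[peak] - up$x[trough]) / waveform_fs * 1e6
}

#' Spike-train autocorrelogram
#'
#' Counts of spike pairs per lag bin over (0, window], 0.5 ms bins by
#' default (the zero-lag self-pairs are excluded).
#'
#' @param spike_times Ascending spike times, seconds.
#' @param bin_ms Bin width, ms.
#' @param window_ms Maximum lag, ms.
#' @return list with `lag_ms` (bin centres) and `count`.
#' @export
acg <- function(spike_times, bin_ms = 0.5, window_ms = 50) {
  w <- window_ms / 1000
  nb <- round(window_ms / bin_ms)
  counts <- numeric(nb)
  n <- length(spike_times)
  k <- 1
  while (TRUE) {
    if (k >= n) break
    d <- spike_times[(k + 1):n] - spike_times[1:(n - k)]
    d <- d[d <= w]
    if (!length(d)) break
    i <- pmin(nb, floor(d * 1000 / bin_ms) + 1)
    tb <- tabulate(i, nb)
    counts <- counts + tb
    k <- k + 1
  }
  list(lag_ms = (seq_len(nb) - 0.5) * bin_ms, count = counts)
}

# Autocorrelogram rise time tau (ms): the ACG is smoothed (2-bin Gaussian)
# and normalised by its plateau (mean over the upper half of the lag window),
# then a saturating-exponential rise p * (1 - exp(-(t - t0)/tau)) is fitted
# by Levenberg-Marquardt least squares. The fit is started from the
# missing-area estimate (integral of the normalised dip below the plateau,
# which equals tau exactly for an ideal exponential recovery) and falls back
# to it when the fit does not converge.
acg_tau_rise <- function(a) {
  t <- a$lag_ms
  if (sum(a$count) == 0) return(0)
  y <- gauss_smooth(a$count, 2)
  plateau <- mean(y[t > max(t) / 2])
  if (!is.finite(plateau) || plateau <= 0) return(0)
  yn <- y / plateau
  tau0 <- sum(pmax(0, 1 - yn[t <= max(t) / 2])) * (t[2] - t[1])
  fit <- tryCatch(
    minpack.lm::nlsLM(
      yn ~ p * (1 - exp(-(t - t0) / tr)),
      start = list(p = 1, tr = max(tau0, 0.3), t0 = 0),
      lower = c(0.2, 0.05, -2), upper = c(2, 60, 5),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(tau0)
  unname(stats::coef(fit)["tr"])
}

#' Classify one unit as RS, NS or WS
#'
#' Putative cell type from the waveform trough-to-peak width (narrow
#' interneurons below 425 us) and, for broad units, the autocorrelogram rise
#' time (wide-slow interneurons above 6 ms); the remainder are
#' regular-spiking putative pyramidal cells. Units with a flat waveform or
#' fewer than `params$min_spikes` spikes are `"unclassified"` (with a
#' warning for flat waveforms).
#'
#' @param waveform Mean spike waveform.
#' @param spike_times Ascending spike times, seconds.
#' @param params [cell_class_params()].
#' @param waveform_fs Waveform sampling rate, Hz.
#' @return One of `"RS"`, `"NS"`, `"WS"`, `"unclassified"`, with attributes
#'   `width_us` and `tau_rise_ms`.
#' @export
classify_cell <- function(waveform, spike_times,
                          params = cell_class_params(),
                          waveform_fs = 30000) {
  width <- spike_width_us(waveform, waveform_fs)
  if (is.na(width)) {
    warning("flat or degenerate waveform; unit left unclassified")
    return(structure("unclassified", width_us = NA_real_,
                     tau_rise_ms = NA_real_))
  }
  if (width < params$narrow_width_us)
    return(structure("NS", width_us = width, tau_rise_ms = NA_real_))
  if (length(spike_times) < params$min_spikes)
    return(structure("unclassified", width_us = width,
                     tau_rise_ms = NA_real_))
  tr <- acg_tau_rise(acg(spike_times, params$acg_bin_ms, params$acg_window_ms))
  cls <- if (tr > params$wide_tau_rise_ms) "WS" else "RS"
  structure(cls, width_us = width, tau_rise_ms = tr)
}

#' Classify every unit of a set
#'
#' @param units A [unit_set()] with waveforms.
#' @param params [cell_class_params()].
#' @return The unit set with `cell_class`, `width_us`, `tau_rise_ms` columns
#'   added to `meta`.
#' @export
classify_cells <- function(units, params = cell_class_params()) {
  stopifnot(inherits(units, "unit_set"))
  if (is.null(units$waveforms))
    pfc_abort("unit set has no waveforms", "pfc_validation_error")
  res <- lapply(units$meta$unit_id, function(u)
    classify_cell(units$waveforms[[u]], units$spikes[[u]], params,
                  units$waveform_fs))
  units$meta$cell_class <- vapply(res, as.character, "")
  units$meta$width_us <- vapply(res, attr, 0, "width_us")
  units$meta$tau_rise_ms <- vapply(res, attr, 0, "tau_rise_ms")
  units
}
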