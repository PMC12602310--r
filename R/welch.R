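# Periodic Hann window.
hann_window <- function(n) 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / n))

# Welch one-sided PSD (density scaling, constant detrend per segment) of a
# samples x channels matrix. Returns list(freqs, power [nfreq x nchan],
# n_segments). Also accumulates the averaged cross-spectrum of channel pairs
# when `cross = c(i, j)` is given.
welch_matrix <- function(x, fs, window_s, overlap = 0, cross = NULL) {
  nper <- round(window_s * fs)
  n <- nrow(x)
  if (n < nper)
    pfc_abort("signal shorter than one Welch window", "pfc_validation_error")
  step <- max(1, round(nper * (1 - overlap)))
  starts <- seq(1, n - nper + 1, by = step)
  w <- hann_window(nper)
  scale <- 1 / (fs * sum(w^2))
  nfreq <- nper %/% 2 + 1
  acc <- matrix(0, nfreq, ncol(x))
  acc_xy <- if (!is.null(cross)) complex(length.out = nfreq) else NULL
  for (s in starts) {
    seg <- x[s:(s + nper - 1), , drop = FALSE]
    seg <- sweep(seg, 2, colMeans(seg)) * w
    X <- stats::mvfft(seg)[seq_len(nfreq), , drop = FALSE]
    acc <- acc + Mod(X)^2 * scale
    if (!is.null(cross))
      acc_xy <- acc_xy + X[, cross[1]] * Conj(X[, cross[2]]) * scale
  }
  m <- length(starts)
  pow <- acc / m
  one_sided <- rep(2, nfreq)
  one_sided[1] <- 1
  if (nper %% 2 == 0) one_sided[nfreq] <- 1
  pow <- pow * one_sided
  out <- list(freqs = (seq_len(nfreq) - 1) * fs / nper, power = pow,
              n_segments = m)
  if (!is.null(cross)) out$cross_xy <- acc_xy / m * one_sided
  out
}

#' Welch power spectral density per block
#'
#' Averaged periodogram over consecutive Hann-windowed segments (4 s windows,
#' no overlap and hence 0.25 Hz bins at 2.5 kHz under the defaults), constant
#' detrend, one-sided density scaling (power integrates to variance). When
#' `block` has several rows the segments of all blocks are pooled.
#'
#' @param lfp An [lfp_recording()].
#' @param block One or more rows of a schedule's `blocks` data.frame (columns
#'   `t_start`, `t_end`), or a numeric `c(t_start, t_end)`.
#' @param cfg [analysis_config()].
#' @return A `power_spectrum`: list with `freqs` (Hz), `power`
#'   (frequency x channel matrix, uV^2/Hz), `channels`, `n_segments`.
#' @export
welch_psd <- function(lfp, block, cfg = analysis_config()) {
  stopifnot(inherits(lfp, "lfp_recording"))
  block <- as_block_df(block)
  nper <- round(cfg$welch_window_s * lfp$fs)
  step <- max(1, round(nper * (1 - cfg$welch_overlap)))
  w <- hann_window(nper)
  scale <- 1 / (lfp$fs * sum(w^2))
  nfreq <- nper %/% 2 + 1
  acc <- matrix(0, nfreq, ncol(lfp$data))
  m <- 0
  for (b in seq_len(nrow(block))) {
    idx <- block_samples(lfp, block$t_start[b], block$t_end[b])
    if (length(idx) < nper)
      pfc_abort("block shorter than one Welch window", "pfc_validation_error")
    res <- welch_matrix(lfp$data[idx, , drop = FALSE], lfp$fs,
                        cfg$welch_window_s, cfg$welch_overlap)
    acc <- acc + res$power * res$n_segments
    m <- m + res$n_segments
  }
  structure(list(freqs = res$freqs, power = acc / m, channels = lfp$channels,
                 n_segments = m, fs = lfp$fs),
            class = "power_spectrum")
}

as_block_df <- function(block) {
  if (is.numeric(block) && length(block) == 2)
    return(data.frame(t_start = block[1], t_end = block[2]))
  block <- as.data.frame(block)
  stopifnot(all(c("t_start", "t_end") %in% names(block)))
  block
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf("<power_spectrum> %d bins (%g-%g Hz, d=%g), %d channels, %d segments\n",
              length(x$freqs), min(x$freqs), max(x$freqs),
              x$freqs[2] - x$freqs[1], ncol(x$power), x$n_segments))
  invisible(x)
}

#' Spectrogram of one channel
#'
#' Welch PSD per consecutive non-overlapping window of `window_s` seconds
#' (each averaging its own 4 s segments); the time base is the window centre.
#'
#' @inheritParams welch_psd
#' @param channel Channel index.
#' @param window_s Spectrogram window length, seconds.
#' @return list with `t` (window centres, s), `freqs` (Hz), `power`
#'   (time x frequency matrix).
#' @export
spectrogram <- function(lfp, channel, cfg = analysis_config(),
                        window_s = cfg$timecourse_window_s) {
  stopifnot(inherits(lfp, "lfp_recording"))
  n <- nrow(lfp$data)
  nwin <- round(window_s * lfp$fs)
  if (nwin < round(cfg$welch_window_s * lfp$fs))
    pfc_abort("spectrogram window shorter than one Welch window",
              "pfc_validation_error")
  starts <- seq(1, n - nwin + 1, by = nwin)
  rows <- lapply(starts, function(s) {
    res <- welch_matrix(lfp$data[s:(s + nwin - 1), channel, drop = FALSE],
                        lfp$fs, cfg$welch_window_s, cfg$welch_overlap)
    res$power[, 1]
  })
  res <- welch_matrix(lfp$data[1:nwin, channel, drop = FALSE], lfp$fs,
                      cfg$welch_window_s, cfg$welch_overlap)
  list(t = (starts - 1) / lfp$fs + window_s / 2, freqs = res$freqs,
       power = do.call(rbind, rows))
}

#' Magnitude-squared coherence between two channels
#'
#' Welch cross-spectral estimate with the same window parameters as
#' [welch_psd()]: `C(f) = |<Sxy>|^2 / (<Sxx> <Syy>)`, averaged over segments.
#' Equals 1 at all frequencies when the channels are identical; for
#' independent signals it is positively biased by roughly 1/n_segments.
#'
#' @inheritParams welch_psd
#' @param chA,chB Channel indices.
#' @return A `coherence_spectrum`: list with `freqs`, `coherence` in [0, 1],
#'   `n_segments`.
#' @export
coherence_spectrum <- function(lfp, chA, chB, block, cfg = analysis_config()) {
  stopifnot(inherits(lfp, "lfp_recording"))
  block <- as_block_df(block)
  idx <- unlist(lapply(seq_len(nrow(block)), function(b)
    block_samples(lfp, block$t_start[b], block$t_end[b])))
  x <- lfp$data[idx, c(chA, chB), drop = FALSE]
  if (any(apply(x, 2, stats::sd) == 0))
    pfc_abort("zero-variance channel", "pfc_validation_error")
  res <- welch_matrix(x, lfp$fs, cfg$welch_window_s, cfg$welch_overlap,
                      cross = c(1, 2))
  coh <- Mod(res$cross_xy)^2 / (res$power[, 1] * res$power[, 2])
  coh[!is.finite(coh)] <- 0
  structure(list(freqs = res$freqs, coherence = pmin(coh, 1),
                 n_segments = res$n_segments),
            class = "coherence_spectrum")
}
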