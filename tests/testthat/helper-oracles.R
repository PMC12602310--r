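# Independent oracles, implemented by different routes than the package code.

# Exhaustive-history LZ76 parser via plain substring search: a phrase ending
# at q is an innovation when s[p..q] does not occur inside s[1..q-1].
lz76_oracle <- function(bits) {
  s <- paste(bits, collapse = "")
  n <- nchar(s)
  cc <- 0L
  p <- 1L
  while (p <= n) {
    q <- p
    while (q <= n) {
      if (!grepl(substr(s, p, q), substr(s, 1, q - 1), fixed = TRUE)) break
      q <- q + 1L
    }
    cc <- cc + 1L
    p <- q + 1L
  }
  cc
}

# Per-definition MSD: explicit loops over lag and time, mean over units.
msd_oracle <- function(S, n_range = 1:50) {
  N <- nrow(S)
  Tn <- ncol(S)
  nmax <- max(n_range)
  Tt <- Tn - nmax
  out <- numeric(Tt)
  for (t in seq_len(Tt)) {
    acc <- 0
    for (n in n_range) acc <- acc + sum((S[, t + n] - S[, t])^2) / N
    out[t] <- acc / length(n_range)
  }
  out
}

# Sign-flip permutation p by explicit bit-mask enumeration.
perm_oracle <- function(d, tail = "two") {
  n <- length(d)
  t_obs <- mean(d)
  tol <- 1e-12 * max(1, abs(t_obs))
  tp <- vapply(0:(2^n - 1), function(m) {
    sg <- ifelse(as.integer(intToBits(m))[1:n] == 1, 1, -1)
    mean(sg * d)
  }, 0)
  switch(tail,
         two = mean(abs(tp) >= abs(t_obs) - tol),
         less = mean(tp <= t_obs + tol),
         greater = mean(tp >= t_obs - tol))
}

# Homogeneous Poisson spike train on [t0, t1).
poisson_train <- function(rate, t0, t1) {
  n <- rpois(1, rate * (t1 - t0))
  sort(runif(n, t0, t1))
}

# Minimal unit_set from a list of spike-time vectors.
make_units <- function(trains, span, region = "IL", waveforms = NULL) {
  ids <- sprintf("u%02d", seq_along(trains))
  names(trains) <- ids
  if (!is.null(waveforms)) names(waveforms) <- ids
  unit_set(trains,
           data.frame(unit_id = ids,
                      region = rep_len(region, length(trains)),
                      depth_um = seq(100, 900, length.out = length(trains))),
           waveforms = waveforms, span = span)
}

# power_spectrum object on the standard 0.25 Hz grid with prescribed power.
make_ps <- function(power_fun, channels = NULL, fmax = 200) {
  freqs <- seq(0.25, fmax, by = 0.25)
  if (is.null(channels))
    channels <- data.frame(depth_um = 500, region = "IL",
                           normalized_depth = 0.5)
  pw <- sapply(seq_len(nrow(channels)), function(i) power_fun(freqs, i))
  structure(list(freqs = freqs, power = as.matrix(pw), channels = channels,
                 n_segments = 1, fs = 2500),
            class = "power_spectrum")
}

# Single- or multi-channel lfp_recording from a samples x channels matrix.
make_lfp <- function(x, fs = 2500, region = "IL") {
  x <- as.matrix(x)
  make_ch <- data.frame(depth_um = seq(100, 900, length.out = ncol(x)),
                        region = rep_len(region, ncol(x)),
                        normalized_depth = seq(0.1, 0.9,
                                               length.out = ncol(x)))
  lfp_recording(x, fs, make_ch)
}
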