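#' Simulation parameters
#'
#' Parameters of the synthetic session generator. The generator emulates the
#' statistical structure the pipeline assumes: 1/f^beta LFP background with a
#' region-localised narrowband high-frequency oscillation appearing after
#' injection, heterogeneous dose-dependent Poisson firing-rate changes (net
#' suppression with a minority of increases), lower task-block rates, and a
#' post-drug reduction in spiking entropy implemented as common-input
#' correlation plus refractory lengthening.
#'
#' @param n_units_per_region Named integer vector (IL, PL, CG); the default
#'   260 units per session matches the scale of a chronic Neuropixels mPFC
#'   recording (a median of ~280 stable units per session), with prelimbic
#'   cortex contributing the most units.
#' @param baseline_rate_lognormal `c(meanlog, sdlog)` of the per-unit base
#'   firing rate, Hz.
#' @param task_rate_factor Multiplicative rate factor in task blocks (< 1:
#'   rates are lower during the operant task than at rest).
#' @param drug_effect Named list per drug; each entry has `frac_decrease`,
#'   `frac_increase`, `frac_nochange` (proportions summing to 1) and
#'   `decrease_factor`, `increase_factor` (post-injection multiplicative rate
#'   factors for responding units).
#' @param task_attenuation In task blocks the drug rate factor is moved this
#'   fraction of the way back toward 1 (drug effects are stronger at rest).
#' @param hfo List: `center_hz` per drug (100 Hz at 0.3 mg/kg, 93 Hz at
#'   1 mg/kg, none for saline), `bandwidth_hz`, `amplitude_db` (peak height
#'   above the local 1/f background), `depth_center`/`depth_sd` (Gaussian
#'   profile on the normalized-depth axis, peaking inside IL), `onset_s`
#'   after injection.
#' @param lfp_background List: `beta` (1/f exponent), `rms_uv` (target rms
#'   within the 1--200 Hz band, length-invariant), and
#'   `band_components` (list of `c(center_hz, width_hz, db)` stationary bumps).
#' @param entropy_drop Named numeric per drug in `[0, 1)`: strength of the
#'   post-injection common-envelope correlation that lowers network-state MSD
#'   and per-unit Lempel-Ziv complexity.
#' @param cell_class_probs Named proportions of RS/NS/WS units.
#' @param fs LFP sampling rate, Hz.
#' @param block_length_s Block length used by [make_experiment()]; the
#'   default 60 s is a scaled stand-in for the protocol's 15 min blocks.
#' @param seed Integer seed; all generator output is seed-deterministic.
#' @return A `sim_params` object.
#' @export
sim_params <- function(n_units_per_region = c(IL = 70, PL = 140, CG = 50),
                       baseline_rate_lognormal = c(meanlog = log(2), sdlog = 0.6),
                       task_rate_factor = 0.85,
                       drug_effect = list(
                         saline  = list(frac_decrease = 0.05, frac_increase = 0.05,
                                        frac_nochange = 0.90,
                                        decrease_factor = 0.5, increase_factor = 2),
                         psi_0.3 = list(frac_decrease = 0.35, frac_increase = 0.10,
                                        frac_nochange = 0.55,
                                        decrease_factor = 0.4, increase_factor = 2),
                         psi_1.0 = list(frac_decrease = 0.50, frac_increase = 0.10,
                                        frac_nochange = 0.40,
                                        decrease_factor = 0.3, increase_factor = 2)),
                       task_attenuation = 0.5,
                       hfo = list(center_hz = c(saline = NA, psi_0.3 = 100,
                                                psi_1.0 = 93),
                                  bandwidth_hz = 0.5, amplitude_db = 6,
                                  depth_center = 0.35, depth_sd = 0.4,
                                  onset_s = 0),
                       lfp_background = list(beta = 2, rms_uv = 100,
                                             band_components = list(c(7, 2, 6))),
                       entropy_drop = c(saline = 0, psi_0.3 = 0.45, psi_1.0 = 0.6),
                       cell_class_probs = c(RS = 0.80, NS = 0.15, WS = 0.05),
                       fs = 2500,
                       block_length_s = 60,
                       seed = 1L) {
  for (d in names(drug_effect)) {
    de <- drug_effect[[d]]
    fr <- c(de$frac_decrease, de$frac_increase, de$frac_nochange)
    if (any(fr < 0) || any(fr > 1) || abs(sum(fr) - 1) > 1e-9)
      pfc_abort("drug_effect proportions must lie in [0,1] and sum to 1",
                "pfc_validation_error")
    if (de$decrease_factor <= 0 || de$increase_factor <= 0)
      pfc_abort("drug rate factors must be positive", "pfc_validation_error")
  }
  if (any(exp(baseline_rate_lognormal[1]) <= 0))
    pfc_abort("rates must be positive", "pfc_validation_error")
  if (any(!is.na(hfo$center_hz) & hfo$center_hz >= fs / 2))
    pfc_abort("hfo center must lie below the Nyquist frequency",
              "pfc_parameter_error")
  structure(list(
    n_units_per_region = n_units_per_region,
    baseline_rate_lognormal = baseline_rate_lognormal,
    task_rate_factor = task_rate_factor, drug_effect = drug_effect,
    task_attenuation = task_attenuation, hfo = hfo,
    lfp_background = lfp_background, entropy_drop = entropy_drop,
    cell_class_probs = cell_class_probs, fs = fs,
    block_length_s = block_length_s, seed = as.integer(seed)),
    class = "sim_params")
}

#' Standard probe channel map
#'
#' Evenly spaced channels through IL, PL and CG (ventral to dorsal), with
#' depths measured upward from each region's ventral boundary.
#'
#' @param n_per_region Named integer vector of channel counts.
#' @param region_sizes_um Named micrometre extents of the regions.
#' @return data.frame with `depth_um`, `region`, `normalized_depth`.
#' @export
standard_channels <- function(n_per_region = c(IL = 3, PL = 3, CG = 3),
                              region_sizes_um = c(IL = 1000, PL = 1600,
                                                  CG = 1400)) {
  rows <- lapply(REGIONS, function(r) {
    n <- n_per_region[[r]]
    if (is.null(n) || n == 0) return(NULL)
    d <- region_sizes_um[[r]] * (seq_len(n) - 0.5) / n
    data.frame(depth_um = d, region = r)
  })
  ch <- do.call(rbind, rows)
  ch$normalized_depth <- normalized_depth(ch, region_sizes_um)
  ch
}

# Frequency-domain synthesis of one coloured-noise trace: half-spectrum
# amplitude profile `amp` (length floor(n/2)), random phases, Hermitian
# symmetric inverse FFT. Exact spectral control is the point: recovery tests
# downstream compare against the injected profile.
synth_noise <- function(n, amp) {
  nf <- length(amp)
  z <- complex(real = rnorm(nf), imaginary = rnorm(nf)) * amp
  full <- complex(length.out = n)
  full[2:(nf + 1)] <- z
  if (n %% 2 == 0) {
    full[nf + 1] <- complex(real = rnorm(1) * Mod(amp[nf]), imaginary = 0)
    full[(nf + 2):n] <- Conj(rev(z[-nf]))
  } else {
    full[(nf + 2):n] <- Conj(rev(z))
  }
  Re(fft(full, inverse = TRUE)) / sqrt(n)
}

hfo_center_for <- function(params, drug) {
  ctr <- params$hfo$center_hz
  if (drug %in% names(ctr)) ctr[[drug]] else NA_real_
}

#' Simulate a multi-channel LFP session
#'
#' Per channel: 1/f^beta coloured noise (plus stationary band components)
#' spanning the whole schedule; after the injection an additive narrowband
#' component at the dose's HFO centre frequency, whose power is
#' `amplitude_db` above the local 1/f background scaled by a Gaussian
#' depth profile that peaks inside the infralimbic cortex. Seed-deterministic.
#'
#' @param params [sim_params()].
#' @param schedule [block_schedule()].
#' @param channels Channel map as from [standard_channels()].
#' @return An [lfp_recording()].
#' @export
simulate_lfp <- function(params, schedule, channels = standard_channels()) {
  stopifnot(inherits(params, "sim_params"), inherits(schedule, "block_schedule"))
  fs <- params$fs
  n <- round(schedule_span(schedule) * fs)
  nf <- floor(n / 2)
  freqs <- (1:nf) * fs / n
  bg <- params$lfp_background
  pow <- freqs^(-bg$beta)
  for (bc in bg$band_components)
    pow <- pow * (1 + (10^(bc[3] / 10) - 1) *
                    exp(-(freqs - bc[1])^2 / (2 * bc[2]^2)))
  amp_bg <- sqrt(pow)

  center <- hfo_center_for(params, schedule$drug)
  has_hfo <- schedule$day == 0 && !is.na(center) && params$hfo$amplitude_db > 0
  if (has_hfo) {
    if (center >= fs / 2)
      pfc_abort("hfo center must lie below the Nyquist frequency",
                "pfc_parameter_error")
    gain <- 10^(params$hfo$amplitude_db / 10) - 1
    i_on <- min(n, 1 + round((schedule$injection_time_s + params$hfo$onset_s) *
                               fs))
    # the oscillation is generated over the post window on its own frequency
    # grid; the synthesised density depends only on the amplitude profile, so
    # its level relative to the background is exact regardless of length
    n2 <- n - i_on + 1
    f2 <- (1:floor(n2 / 2)) * fs / n2
    amp_bg2 <- sqrt(f2^(-bg$beta))
    bump_rel <- gain * exp(-(f2 - center)^2 / (2 * params$hfo$bandwidth_hz^2))
  }

  # deterministic gain: rms_uv is the target rms within the 1-200 Hz band,
  # so the density level does not depend on recording length (the 1/f^beta
  # variance is dominated by arbitrarily slow components otherwise)
  in_band <- freqs >= 1 & freqs <= 200
  gain_uv <- bg$rms_uv / sqrt(sum(2 * pow[in_band] / fs) * fs / n)

  with_seed(params$seed, {
    data <- matrix(0, n, nrow(channels))
    for (ch in seq_len(nrow(channels))) {
      x <- synth_noise(n, amp_bg)
      if (has_hfo) {
        nd <- channels$normalized_depth[ch]
        dfac <- if (is.na(nd)) 0 else
          exp(-(nd - params$hfo$depth_center)^2 / (2 * params$hfo$depth_sd^2))
        if (dfac > 1e-3)
          x[i_on:n] <- x[i_on:n] + synth_noise(n2, amp_bg2 * sqrt(bump_rel * dfac))
      }
      data[, ch] <- x * gain_uv
    }
    lfp_recording(data, fs, channels)
  })
}

# Assign each unit a drug response and post-injection rate factor.
assign_drug_response <- function(n, de) {
  lab <- sample(c("decrease", "increase", "no_change"), n, replace = TRUE,
                prob = c(de$frac_decrease, de$frac_increase, de$frac_nochange))
  fac <- ifelse(lab == "decrease", de$decrease_factor,
                ifelse(lab == "increase", de$increase_factor, 1))
  list(label = lab, factor = fac)
}

# Biphasic waveform template: trough then peak separated by `width_us`.
waveform_template <- function(width_us, waveform_fs = 30000, n_samp = 82) {
  t_us <- (seq_len(n_samp) - 1) / waveform_fs * 1e6
  t_trough <- 800
  w <- -exp(-(t_us - t_trough)^2 / (2 * 90^2)) +
    0.5 * exp(-(t_us - (t_trough + width_us))^2 / (2 * (0.45 * width_us)^2))
  w
}

class_pars <- function(cls) {
  switch(cls,
         RS = list(width_us = 550, tau_rise_ms = 1.5),
         NS = list(width_us = 300, tau_rise_ms = 1.0),
         WS = list(width_us = 550, tau_rise_ms = 12))
}

# One spike train over [t0, t1): Poisson at rate * max(env), thinned by the
# shared envelope and by an exponential-recovery hazard (tau_rise_ms).
gen_train <- function(t0, t1, rate, tau_rise_ms, env = NULL) {
  env_max <- if (is.null(env)) 1 else max(env$v)
  lam <- rate * env_max / (1 - 1e-3)   # slight overdraw for hazard losses
  n <- rpois(1, lam * (t1 - t0))
  if (n == 0) return(numeric(0))
  tt <- sort(runif(n, t0, t1))
  if (!is.null(env)) {
    p <- env$v[pmin(length(env$v), floor((tt - t0) / env$dt) + 1)] / env_max
    tt <- tt[runif(n) < p]
  }
  if (!length(tt)) return(numeric(0))
  tt[.hazard_thin(tt, runif(length(tt)), tau_rise_ms / 1000)]
}

# Shared binary telegraph envelope with mean 1: low = 1-e, high = 1-e + e/p_on.
telegraph_env <- function(t0, t1, e, dt = 0.01, tau_s = 0.2, p_on = 0.3) {
  nb <- ceiling((t1 - t0) / dt)
  flip <- runif(nb) < dt / tau_s
  state <- logical(nb)
  s <- runif(1) < p_on
  for (i in seq_len(nb)) {
    if (flip[i]) s <- runif(1) < p_on
    state[i] <- s
  }
  list(v = (1 - e) + e * state / p_on, dt = dt)
}

#' Simulate a session's spike trains
#'
#' Units are split across IL/PL/CG with lognormal base rates and RS/NS/WS
#' classes (waveforms drawn from narrow/wide templates; autocorrelogram rise
#' time set by the class's recovery hazard). Rates are base x
#' `task_rate_factor` in task blocks x the unit's assigned drug factor in
#' post-injection blocks (attenuated by `task_attenuation` during task).
#' A positive `entropy_drop` adds a shared on/off envelope in post blocks,
#' correlating units and lowering spiking entropy at a preserved mean rate.
#' Seed-deterministic.
#'
#' @inheritParams simulate_lfp
#' @return A [unit_set()]; `meta` carries the ground-truth columns
#'   `true_class`, `base_rate_hz`, `true_response`, `drug_factor`.
#' @export
simulate_spikes <- function(params, schedule) {
  stopifnot(inherits(params, "sim_params"), inherits(schedule, "block_schedule"))
  with_seed(params$seed + 1000003L, {
    npr <- params$n_units_per_region
    region <- rep(names(npr), npr)
    n <- length(region)
    sizes <- c(IL = 1000, PL = 1600, CG = 1400)
    depth <- runif(n, 0, sizes[region])
    cls <- sample(names(params$cell_class_probs), n, replace = TRUE,
                  prob = params$cell_class_probs)
    base <- rlnorm(n, params$baseline_rate_lognormal[1],
                   params$baseline_rate_lognormal[2])
    de <- params$drug_effect[[schedule$drug]]
    if (is.null(de)) de <- list(frac_decrease = 0, frac_increase = 0,
                                frac_nochange = 1,
                                decrease_factor = 1, increase_factor = 1)
    resp <- assign_drug_response(n, de)
    e_drop <- if (schedule$drug %in% names(params$entropy_drop))
      params$entropy_drop[[schedule$drug]] else 0

    ids <- sprintf("u%03d", seq_len(n))
    blocks <- schedule$blocks
    spikes <- vector("list", n)
    names(spikes) <- ids
    for (i in seq_len(n)) spikes[[i]] <- numeric(0)
    for (b in seq_len(nrow(blocks))) {
      post <- blocks$phase[b] == "post"
      task <- blocks$kind[b] == "task"
      e_eff <- if (task) e_drop * (1 - params$task_attenuation) else e_drop
      env <- if (post && e_eff > 0)
        telegraph_env(blocks$t_start[b], blocks$t_end[b], e_eff) else NULL
      for (i in seq_len(n)) {
        r <- base[i]
        if (task) r <- r * params$task_rate_factor
        if (post) {
          fac <- resp$factor[i]
          if (task) fac <- 1 + (fac - 1) * (1 - params$task_attenuation)
          r <- r * fac
        }
        cp <- class_pars(cls[i])
        tau <- cp$tau_rise_ms * if (post && e_eff > 0) 1 + e_eff else 1
        spikes[[i]] <- c(spikes[[i]],
                         gen_train(blocks$t_start[b], blocks$t_end[b], r,
                                   tau, env))
      }
    }
    waveforms <- lapply(seq_len(n), function(i) {
      cp <- class_pars(cls[i])
      waveform_template(cp$width_us) * runif(1, 80, 150)
    })
    names(waveforms) <- ids
    meta <- data.frame(unit_id = ids, region = region, depth_um = depth,
                       true_class = cls, base_rate_hz = base,
                       true_response = resp$label, drug_factor = resp$factor)
    unit_set(spikes, meta, waveforms = waveforms,
             span = schedule_span(schedule))
  })
}

#' Simulate and optionally write a full session
#'
#' Composes [standard_schedule()] (scaled blocks), [simulate_lfp()] and
#' [simulate_spikes()] into one session triple, optionally written to disk
#' through the package's readers/writers (`lfp.h5`, `spikes.csv`, `units.csv`,
#' `schedule.yaml`).
#'
#' @param params [sim_params()].
#' @param drug Drug condition for the session.
#' @param subject_id Subject label.
#' @param day Protocol day (0, 1, 2, 6).
#' @param out_dir Optional output directory.
#' @param channels Channel map.
#' @return list with `lfp`, `units`, `schedule` (and `paths` if written).
#' @export
make_experiment <- function(params = sim_params(), drug = "psi_0.3",
                            subject_id = "sim1", day = 0, out_dir = NULL,
                            channels = standard_channels()) {
  schedule <- standard_schedule(subject_id, drug, day = day,
                                block_length_s = params$block_length_s)
  lfp <- simulate_lfp(params, schedule, channels)
  units <- simulate_spikes(params, schedule)
  out <- list(lfp = lfp, units = units, schedule = schedule)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(lfp = file.path(out_dir, "lfp.h5"),
                  spikes = file.path(out_dir, "spikes.csv"),
                  units = file.path(out_dir, "units.csv"),
                  schedule = file.path(out_dir, "schedule.yaml"))
    write_lfp(lfp, paths$lfp)
    write_spikes(units, paths$spikes, paths$units)
    write_schedule(schedule, paths$schedule)
    out$paths <- paths
  }
  out
}
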