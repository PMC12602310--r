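---
title: "Methods: spectral unmasking, cell classification and network-state complexity in pfcdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectral unmasking, cell classification and network-state complexity in pfcdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pfcdyn)
```

`pfcdyn` analyses multi-channel electrophysiology from rat medial prefrontal
cortex (mPFC) in pharmacological block designs: sessions alternate 15-min
rest and operant-task blocks around a systemic injection (vehicle or one of
two psilocybin doses), with follow-up recordings on later days. The package
covers the full chain from validated containers (LFP, sorted spike times,
block schedules) through spectral and spike-train analysis to a
nonparametric statistical layer, and ships a synthetic-session generator so
that every stage can be exercised and calibrated without recorded data.

## Spectral analysis and HFO unmasking

Power spectral densities are Welch averages of Hann-windowed, constant-
detrended segments: 4 s windows with no overlap, which at the 2.5 kHz LFP
sampling rate gives 10,000-sample segments and an exact 0.25 Hz frequency
grid. One-sided density scaling is used throughout, so the integral of the
PSD over frequency reproduces the signal variance (this Parseval property is
tested). Magnitude-squared coherence uses the same segmentation via averaged
cross-spectra; for independent signals its small-sample bias is approximately
the reciprocal of the segment count, which the tests verify.

A narrowband high-frequency oscillation (HFO) near 100 Hz rides on a steep
1/f background and is quantified by *unmasking*: a line is fitted to
log10(power) versus log10(frequency) over two flank bands (60--80 and
110--130 Hz by default) and evaluated across the 80--110 Hz target band,
giving a power-law baseline that is exact on pure 1/f^&beta; spectra of any
exponent. The per-bin difference is expressed in decibels,
`10*log10(raw/baseline)`, making the measure invariant to overall gain;
`hfo_diff_db` summarises a channel by the mean difference over the band,
`peak_diff_db` and `peak_freq_hz` by the maximum and its frequency. The
flank choice and the dB convention are package conventions: the band
edges of the target band are fixed by the analysis (80--110 Hz), the flanks
must bracket it while staying clear of line noise and the gamma band, and a
ratio-based difference is the only gain-invariant option. A linear
difference is available by working directly on the returned per-bin matrix.

One channel per subregion feeds the channel-level analyses: infralimbic (IL)
is the channel with the strongest HFO unmasking (the ~100 Hz peak), prelimbic
(PL) the channel nearest the region's mid-depth, and cingulate (CG) the
channel nearest a fixed 284 um above the region's ventral boundary. Depths
are measured upward from each region's ventral boundary and mapped to a
normalized [0, 3) axis (IL = [0,1), PL = [1,2), CG = [2,3)) for topographic
plots. A probe that misses IL (which happens in practice) raises a flagged
condition and the pipeline continues without that region.

## Unit quality control and cell-type classification

Three conventional post-sorting metrics gate all unit analyses, with the
conventional thresholds applied as strict inequalities: inter-spike-interval
violation ratio < 0.5 (observed refractory violations at 1.5 ms relative to
the Poisson expectation), amplitude cutoff < 0.1 (estimated missed-spike
fraction from the symmetric tail of a smoothed 500-bin amplitude histogram,
converted from tail/observed to a fraction of the full distribution and
capped at 0.5), and presence ratio > 0.9 (fraction of equal epochs with at
least one spike). The presence-ratio epoch *duration* is held at the
full-protocol value (~72 s, i.e. the conventional 100 epochs over a ~2 h
session) rather than the epoch count, so the metric keeps its timescale on
scaled-down sessions; otherwise short synthetic sessions would reject
strongly drug-suppressed units purely as an artefact of scaling.

Cell types use two thresholds applied to all units regardless of location:
trough-to-peak waveform width below 425 us marks narrow-spiking putative
interneurons (NS); among broad units, an autocorrelogram (ACG) rise time
above 6 ms marks wide-slow-spiking cells (WS), the remainder being
regular-spiking putative pyramidal cells (RS). Width is measured after 10x
cubic-spline upsampling on the mean waveform, making it scale-invariant and
robust to sampling rate. The ACG (0.5 ms bins, 50 ms window) is smoothed,
normalised by its plateau, and a saturating exponential
`p*(1 - exp(-(t - t0)/tau))` is fitted by Levenberg--Marquardt least
squares, started from the missing-area estimate (the integral of the dip
below the plateau, which equals tau exactly for an ideal exponential
recovery and serves as the fallback if the fit fails). A fuller
rise-times-decay model proved numerically unstable at realistic spike
counts; only the rise time is consumed by the 6 ms threshold, so the
simpler model is preferred. Units with flat waveforms or fewer than 100
spikes stay unclassified.

## Firing-rate change analysis

Rate time courses are spike counts in consecutive half-open windows anchored
so that a window edge falls on the injection time, expressed as differences
from the mean rate over the pooled pre-injection baseline; partial trailing
windows are dropped. Per-cell change classification combines a two-sided
Wilcoxon rank-sum test on 10 s bin counts (pre versus post blocks of one
kind) with a twofold magnitude gate: only units that are both significant at
the per-cell alpha = 0.05 (no per-cell multiplicity correction) *and* at
least doubled or halved are labelled increase/decrease — a significant
sub-twofold drift is "no change". The magnitude gate means the null
label rate is far below alpha, which the calibration tests exploit. Silent
baselines are guarded with a small epsilon and flagged rather than erroring.
Label proportions per region x cell class feed the chi-squared layer.

## Network-state MSD and Lempel-Ziv complexity

Spike trains are binarized into a units x time-bins matrix: a bin is 1 if
the unit fired at least once in the half-open bin (bin edges belong to the
later bin). With N units, column t is the network's N-bit state S_t. The
mean-squared displacement across a lag of n bins is

MSD(n, t) = (1/N) * sum_i (s\^i_{t+n} - s\^i_t)\^2,

the Hamming distance between the two states divided by N, and MSD_t averages
this over lags n = 1..50; at the 20 ms bin width that horizon is 1 s. Only
times with all lags available are kept, so the series has no edge bias.
MSD_t lies in [0, 1], is invariant to unit order, and for independent
Bernoulli(p) units has expectation 2p(1-p) — all verified, including exact
agreement with a literal triple-loop implementation of the definition.

For the pre/post contrast, each subject's pre-injection MSD distribution is
z-scored and the post distribution is transformed with the *same* pre mean
and (by default) the same pre SD, so both phases are in pre-SD units; the
mean-subtraction-only behaviour is available via `scale_post = FALSE`. The
default divides post by the pre SD as well because otherwise pre and post
are in different units and their difference is not interpretable as a
standardised shift. Multiple blocks within a phase are pointwise averaged
before pooling, and subjects are pooled by concatenating standardized
values.

Lempel-Ziv complexity is computed per unit on 10 ms binarized trains as the
LZ76 exhaustive-history phrase count: a phrase ends at the first position
where the current phrase is no longer a substring of the preceding history,
and the final (possibly reproducible) phrase counts as one. The
implementation answers the substring queries with an online suffix
automaton, which is linear-time where the textbook scan is quadratic on
long low-entropy spike sequences; it is verified against a brute-force
substring parser on every binary string up to length 15 and on random
length-1000 strings. Because block lengths may differ, contrasts use the
normalisation `c_norm = c_raw * log2(L) / L`, which tends to 1 for an
unbiased random sequence; the raw count is also reported. Per-unit deltas
(post mean minus pre mean, units matched by id) are tested with a sign-flip
permutation test and summarised by a one-sample Cohen's d
(`mean(delta)/sd(delta)`).

## Statistical layer

The Scheirer--Ray--Hare test rank-transforms all values (average ranks for
ties) and computes two-way fixed-effects sums of squares on the ranks; each
effect's H = SS_effect / MS_total is referred to chi-squared with the
effect's df, with the interaction as SS_cells - SS_A - SS_B and no extra tie
correction of MS_total (the classical construction). With a constant second
factor the main effect reduces exactly to Kruskal--Wallis H without tie
correction. Null calibration at the 3x2, n = 60 design is verified by
simulation (rejection close to the nominal 5% for all three effects).

The permutation test is a sign-flip test on paired differences with the
mean as statistic — the natural choice for the paired pre/post unit deltas,
and flagged as a package convention. Sampled p-values include the observed
statistic, `p = (1 + #extreme)/(B + 1)` with B = 10,000 by default; an
exact mode enumerates all 2^n sign patterns and is tested against
independent enumeration. Chi-squared tests on label-proportion tables use
the Pearson statistic without continuity correction, with pairwise 2 x m
post-hoc sub-tables Bonferroni-corrected over the number of pairs and a
Fisher fallback flagged when expected counts drop below 1.

Because frequency-resolved comparisons involve hundreds of highly correlated
variables, a *partial Bonferroni* factor is used instead of the raw test
count: PCA on the column-centred observations x frequencies matrix, with the
correction factor the smallest number of components whose cumulative
explained variance exceeds 95%, and alpha_corrected = 0.05/factor.
Covariance PCA is the default (the criterion is phrased in explained
variance); correlation PCA is available and makes the factor invariant to
per-column rescaling. Baseline contrasts divide mean post-injection values
by mean baseline values per condition and kind, and percent differences
divide the drug change by the vehicle change.

## The synthetic-session generator

The generator produces sessions with the statistical structure the analysis
assumes, not a biophysical simulation:

* **LFP**: coloured noise synthesised in the frequency domain (random
  phases, amplitude proportional to f^(-beta/2), beta = 2 by default, plus a
  stationary theta bump), giving exact spectral control. The overall gain is
  set analytically so the 1--200 Hz band rms is fixed (100 uV) independent
  of recording length — an empirical-SD normalisation would couple the
  density level to duration through the diverging low-frequency variance.
  After the injection, an additive narrowband component appears whose power
  is a Gaussian profile *relative to the local 1/f background*, peaking
  `amplitude_db` (default +6 dB) above it at the dose's centre frequency
  (100 Hz for the low dose, 93 Hz for the high dose). The component is
  spectrally narrow (0.5 Hz) by design so that recovery tests are sharp:
  the true peak bin is unambiguous and the injected depth profile (Gaussian
  on the normalized-depth axis, centred inside IL with SD 0.4) determines
  the topography. Real HFOs are broader; the narrowband choice trades
  physiological texture for exact recoverability of the injected parameters.
* **Spikes**: per-unit inhomogeneous Poisson trains with lognormal base
  rates (median 2 Hz), a task-block factor of 0.85 (rest rates are higher),
  and per-dose response mixtures (e.g. at the high dose half the units are
  suppressed to 0.3x, a tenth doubled) attenuated by half during task
  blocks, emulating rest-dominant drug effects. A recovery hazard
  `1 - exp(-t/tau)` after each spike sets the ACG rise time per cell class
  (RS/NS fast, WS 12 ms), and waveforms come from narrow (300 us) and broad
  (550 us) biphasic templates.
* **Entropy reduction**: the post-drug drop in MSD and LZC is produced by a
  shared on/off telegraph envelope (common input) with mean 1 plus
  refractory lengthening, strength `entropy_drop` (0 / 0.45 / 0.6 for
  vehicle / low / high dose). This is a stand-in mechanism chosen because it
  lowers state-transition rates and per-unit entropy at a preserved mean
  rate; no claim is made that it is the biological mechanism.

Everything is deterministic given the seed. The default schedule is the
day-0 protocol shape (rest+task baseline, injection, then
rest/task/rest/task/rest) with 60 s blocks standing in for 15 min; all
analysis parameters are unchanged under this scaling except the
presence-ratio epoch rule discussed above. The default unit count (260 per
session, prelimbic-dominant) matches the scale of a chronic Neuropixels
mPFC session (median ~280 stable units); the remaining test problem sizes
are chosen to keep the full suite fast at desk scale: 9 channels per
session, 20-seed recovery sweeps, 2000-replicate SRH calibration,
50-replicate end-to-end direction checks.

What passing tests on these sessions shows is that the *pipeline* recovers
known injected structure — band frequencies and topography, mixture rate
effects, complexity reductions, calibrated test levels. What they cannot
show is robustness to everything real recordings add: spike-sorting errors
correlated with drug state, non-stationary artefacts, movement, volume
conduction, broader HFOs, and slow drift. The QC metrics and the 1/f
baseline address some of these, but claims about real data require real
data.

## Known limitations

* The Scheirer--Ray--Hare chi-squared reference is asymptotic; small or
  very unbalanced designs inherit its approximation.
* The ACG rise-time threshold separates well-sampled units (hundreds of
  spikes); sparse units fall back to RS/unclassified conservatively.
* The amplitude-cutoff estimator assumes a symmetric amplitude
  distribution; skewed distributions bias it (as they do for the
  conventional estimator it follows).
* The MSD lag average uses only times with all lags available, so the last
  second of each block is not scored.
* Multi-day contrasts assume stable channel geometry across days; no
  drift correction is attempted.
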