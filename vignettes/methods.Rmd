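---
title: "Methods: from population damping to cellular noise"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from population damping to cellular noise}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

```{r}
library(desync)
```

## The central idea

A dish of fibroblasts or an SCN explant carrying a luciferase clock reporter
emits a bioluminescence rhythm that decays over days even though each cell
keeps oscillating. The decay is not cell death: the cells are uncoupled (or
weakly coupled) oscillators that drift out of phase, and the *population
mean* of many desynchronizing oscillators is a damped oscillation. The
damping rate `d` of the population envelope is therefore a read-out of
cellular stochastic noise — the faster the dephasing, the noisier the cells.
`desync` implements the full chain of reasoning:

1. fit a damped sinusoid `A e^(-d t) sin(2 pi t / T + theta)` to a
   population recording (`fit_damped_sinusoid()`);
2. measure single-cell noise directly in tracked-cell data and confirm that
   noisier cells desynchronize faster
   (`noise_metrics()`, `bootstrap_damping_difference()`);
3. reproduce the damping mechanistically with a stochastic reaction-network
   clock model, and use the observed `d` to calibrate the effective system
   size Omega (`simulate_population()`, `calibrate_volume()`);
4. scan drug-target parameters to connect damping changes to pharmacology
   (`knockdown_scan()`);
5. scale the fit to plate-format screens with robust statistics
   (`batch_fit_and_qc()`, `plate_normalize()`, `gene_group_test()`);
6. ask when the *shape* of the envelope can distinguish intrinsic from
   extrinsic noise (`window_function()`, `envelope_shape_fit()`).

## Fitting the damped sinusoid

### Detrending and smoothing

Raw recordings carry a slow baseline (media changes, luciferin depletion).
We remove it with a Hodrick–Prescott (HP) trend: the trend `tau` minimizes
`sum((y - tau)^2) + gamma * sum(diff(tau, differences = 2)^2)`. The
smoothing weight defaults to `gamma = 0.05 * (24 / Ts)^4` for sampling
interval `Ts` in hours, which places the trend's corner period well above a
circadian day. The pentadiagonal system is solved with a sparse Cholesky
factorization (cached per `(n, gamma)`).

High-frequency noise is then attenuated with a zero-phase (forward–backward)
Butterworth low-pass filter of order 5. The cutoff `w_c = 0.1` is in
**cycles per sample**: any component slower than 10 samples per cycle is in
the passband, so a 24 h rhythm passes at every sampling interval used here
(0.5–2 h). Interpreting the same number as a fraction of Nyquist would put a
24 h rhythm sampled every 2 h *inside the stopband* and annihilate the
signal, so the cycles-per-sample convention is the only self-consistent one.

### Edge handling

Trend extraction and zero-phase filtering both smear information across the
record ends; on a 4–8 day recording those transients bias the damping
estimate by several percent. Both operations therefore extend the series
with a least-squares autoregressive (linear-predictive) extrapolation of
order 12 before processing and crop back afterwards (`ar_extend()`), falling
back to even reflection when the AR fit is unstable. This keeps the interior
of the processed series essentially identical to what an infinitely long
recording would give.

### Matrix-pencil mode estimation

The detrended, smoothed series is modeled as a sum of complex exponentials.
A Hankel matrix of the samples (pencil parameter `L = floor(N/3)`) is
factored by SVD; the number of modes is chosen by normalized singular
values (threshold `1e-3`, at most 6), and the generalized eigenvalues of the
shifted sub-matrices give the complex poles, i.e. damping and frequency per
mode. The circadian mode is the one with the largest residue energy among
poles whose period lies in a 6–50 h window (ties resolved toward 24 h).

### Matched-basis amplitude/phase and refinement

Detrending and filtering attenuate a damped sinusoid slightly; estimating
amplitude and phase by regressing the *processed data* on *identically
processed* basis functions `e^(-d t) cos/sin(2 pi t / T)` cancels that
attenuation exactly. An optional Nelder–Mead refinement of `(d, log T)`
minimizes the same matched-residual, giving essentially exact recovery
(relative error around `1e-8` on noiseless inputs, `R^2 >= 0.999` even at
`d = 0.05`/h). The reported `R^2` compares the model against the
HP-detrended (but unfiltered) data.

## Single-cell analysis

Tracked-cell traces are band-limited to periods of 8–256 h with a maximal
overlap discrete wavelet transform (MODWT). Because no wavelet package is
available in this environment, the filters are built in-package by spectral
factorization of the Daubechies half-band polynomial, selecting the
least-asymmetric (symlet) root combination by phase nonlinearity; with 6
vanishing moments this reproduces the standard `sym6`/`db6` coefficients.
Circular MODWT artifacts at the record ends are avoided with the same AR
extension as above.

Per-cycle periods and amplitudes come from the analytic signal (FFT Hilbert
transform): periods from successive upward phase-zero crossings, amplitudes
as the envelope magnitude at each cycle midpoint (the midpoint, not the
per-cycle peak, is unbiased when the amplitude changes stepwise between
cycles). Three per-cell noise metrics — period CV, amplitude CV, and the
high-frequency (1–8 h) to circadian energy ratio — are combined by their
first principal component (`combined_noise_score()`), oriented so that
larger scores mean noisier cells.

To compare damping between noisy and quiet cells without a phase-spread
artifact, `align_and_average()` truncates every cell at its first upward
zero crossing before averaging (in-silico synchronization). The damping
difference between high- and low-score groups is tested by a permutation
bootstrap over group labels (`bootstrap_damping_difference()`), with the
add-one p-value correction.

Period variability decomposes into a *within-cell* (cycle-to-cycle) and an
*across-cell* (between means) IQR (`period_variability_decomposition()`);
in fibroblast-like regimes the within-cell component dominates, which is the
first hint that intrinsic noise, not period heterogeneity, drives the
population damping.

## The stochastic clock model

`clock_model()` is an eight-state mammalian-core-loop model: *Per*, *Cry1*,
*Cry2* mRNAs; PER, CRY1, CRY2 proteins; nuclear PER–CRY1 and PER–CRY2
complexes. Nuclear complexes repress all three genes through a cubic Hill
term; degradation is Michaelis–Menten; PER–CRY association/dissociation and
nuclear degradation close the loop. Two deliberate modeling choices:

* **Dilution `kdil`.** With purely saturable (Michaelis–Menten) degradation
  a parameter region exists where production exceeds the maximal degradation
  rate and a species grows without bound; a small first-order dilution term
  (about 0.006/h, weeks-scale) on every species makes all trajectories
  provably bounded without affecting circadian dynamics.
* **Synthetic parameterization.** The parameter vector
  (`desync:::clock_params_default`) is a reconstruction for this model
  class, tuned to a sustained deterministic limit cycle near 23.7 h and then
  calibrated (see below); it is not a transcription of any published table.

Stochastic populations are simulated per cell with Gillespie's direct
method or fixed-step tau-leaping (`simulate_population()`, implemented in
C++ on R's RNG stream so runs are reproducible from `set.seed()`).
Propensities follow the system-size convention: rates are evaluated on
concentrations `X / Omega` and multiplied by `Omega`, so `Omega` (molecules
per concentration unit) is the single knob controlling intrinsic noise.

### Volume calibration

`calibrate_volume()` simulates replicate populations over a log-spaced grid
of `Omega`, fits the population damping at each volume, and regresses
`log d` on `log Omega` (weighted by inverse squared SEM of `log d`, with
each point's SEM floored at the median SEM so a single lucky low-variance
point cannot dominate). Inverting the line at the target damping — the
package default target is `d = 0.0151`/h, a typical fibroblast value —
gives the effective volume, with a delta-method standard error. Because the
reported volume is defined *by this procedure*, the model's concentration
scale was fixed so that the procedure returns approximately `Omega = 226`
at the default target; the reporter-state fit inside
`fit_population_damping()` always uses the matched refinement, which halves
the replicate-to-replicate spread of `d`.

### Drug-target scans and a known limitation

`knockdown_scan()` rescales one kinetic parameter over a descending dose
grid and reports period and damping with SEMs. Reducing `vaC1P` (PER–CRY1
association; a PER-stabilizing kinase-inhibitor axis) lengthens the period
from ~24 h beyond 32 h while damping stays flat — strong oscillator,
slower clock. Reducing `vdCn` (nuclear-complex degradation; a
CRY-stabilizing axis) weakens the oscillation toward a bifurcation: cells
get noisier, the population damping rises, and past roughly 60% knockdown
the population mean decoheres within ~3 cycles (fits there need a short
window and are eventually rejected by the pooled-`R^2` rule).

One direction is wrong in this reconstruction: along the `vdCn` path the
*deterministic period shortens* (23.7 → ~16 h near the bifurcation),
whereas the CRY-stabilization phenotype it emulates lengthens the period.
Extensive re-tuning (alternative nuclear-degradation kinetics, re-weighted
CRY2 arm, stiffer CRY1 buffering) either destroyed the limit cycle or kept
the inverted direction, so the period sign along that one axis appears to
be a property of the original, unavailable parameterization rather than of
the model class. The package documents the direction truthfully and the
acceptance suite leaves that single assertion failing rather than papering
over it.

## Identifiability of the noise type

Why bother with single cells at all? Because the population envelope is
almost, but not quite, uninformative about the *kind* of noise:

* **Intrinsic noise (phase diffusion).** Phase variance grows linearly,
  `Var(phi) = 2 D t`, and the envelope is exponential, `exp(-D t)`; the log
  window function is a straight line of slope `-D`.
* **Extrinsic noise (period heterogeneity).** Phases spread ballistically,
  `Var(phi) = sigma_w^2 t^2`, and the envelope is Gaussian,
  `exp(-sigma_w^2 t^2 / 2)`; the log window function is a parabola with
  curvature `-sigma_w^2 / 2`.

`window_function()` extracts the envelope (Hilbert or local-peak variant)
and `envelope_shape_fit()` fits both shapes, preferring the Gaussian only
when the quadratic coefficient is both statistically significant and
material (at least 5% of the log-amplitude excursion — a pure significance
rule flips on near-noiseless data where even vanishing curvature is
"significant"). On realistic mixed populations the preferred shape is
unstable across seeds, which is exactly the point: the envelope shape alone
cannot reliably separate the two noise sources, and tracked single cells
(or the volume-calibrated model) are needed.

## Screens and synthetic data

`generate_screen()` makes plate-format damped-sinusoid screens with gene,
well and plate effects, an arrhythmic fraction, and optionally a planted
fraction of "more robust" genes (higher amplitude, lower damping).
`batch_fit_and_qc()` fits every well (`R^2 >= 0.8` to pass QC),
`plate_normalize()` converts parameters to per-plate robust z-scores
`(x - median) / median(|x - median|)`, and `gene_group_test()` calls hits
with Hotelling's `T^2` against a robust (MCD) covariance of the control
wells, using chi-squared p-values. `quadrant_fractions()` then summarizes
significant gene shifts in the (amplitude, damping) plane — the
higher-amplitude/lower-damping quadrant is where clock-robustness screens
look for their hits.

All generators (`generate_damped_series()`, `generate_cell_traces()`,
`generate_screen()`, `mixed_noise_config()`) are fully seeded, and their
defaults encode the study conditions used throughout the documentation:
79 tracked cells at 30 min sampling for 10 days with within-cell cycle SD
1.43 h against a between-cell SD 0.89 h; 8 plates of 360 wells at 2 h
sampling, 4 replicate wells per gene, 10% controls, 5% arrhythmic.

## Numerical conventions worth knowing

* Time is absolute (hours since recording start); fitted phases refer to
  `t = 0` of the supplied series, so delaying a record rotates the phase by
  exactly `2 pi * delay / T`.
* All fits report `R^2` against the detrended (not the filtered) data.
* Seeds: every stochastic entry point takes an explicit `seed`; nothing
  depends on the global RNG state unless you opt in by omitting it.
* The command-line interface (`inst/cli/desync.R`) wraps each stage
  (`fit`, `cells`, `simulate`, `calibrate`, `knockdown`, `screen`,
  `identify`, `synth`) and embeds the seed and options in every output
  file for reproducibility.
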