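---
title: "Blood-pressure variability and the reproducibility of dynamic cerebral autoregulation estimates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Blood-pressure variability and the reproducibility of dynamic cerebral autoregulation estimates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcarepro)
```

## The problem

Dynamic cerebral autoregulation (DCA) describes how the cerebral vasculature
buffers cerebral blood flow against fluctuations in arterial pressure. It is
estimated from simultaneous recordings of mean arterial blood pressure (MABP)
and transcranial-Doppler cerebral blood flow velocity (CBFV), typically 5
minutes of spontaneous supine rest resampled to 10 Hz beat-to-beat series.
Test–retest reproducibility of these estimates is notoriously poor, which
blocks clinical adoption.

A plausible mechanism is input starvation: every DCA estimator is a
pressure-to-flow system identification, so when spontaneous blood-pressure
variability is low there is little input signal to identify from, and the
estimate becomes noisy. `dcarepro` implements the complete analysis chain for
testing that mechanism:

1. quantify MABP variability as Welch band power (PSD-MABP) in the
   very-low-frequency (VLF, 0.02–0.07 Hz) and low-frequency (LF, 0.07–0.2 Hz)
   bands;
2. correlate the absolute test–retest difference of each DCA variable with
   the *lowest* of the two sessions' band powers (Spearman);
3. remove subjects below percentile cut-offs of the lowest-of-pair power and
   track the one-way intraclass correlation coefficient (ICC) across the
   cut-off grid;
4. test the linear trend of ICC across cut-offs with a repeated-measures
   contrast, and compare methods with a Monte Carlo ICC-difference test;
5. extrapolate base reliability to longer recordings with the Spearman–Brown
   prophecy formula.

## Models and estimators

### Spectral estimation

`welch_psd()` averages modified periodograms over Hann-windowed segments of
100 s with 50% overlap (11 segments for a 600-s recording; 0.01 Hz
resolution). One-sided density scaling is used so the integral of the PSD
over frequency recovers the variance; thresholds are therefore in
mmHg²/Hz. Segments are detrended by mean removal — the protocol is silent on
detrending, but mean removal is standard for physiological spectra and
protects the VLF bins from DC leakage. Band power (`band_power()`) is the
arithmetic mean of the PSD at grid frequencies inside the closed band
interval; the shared 0.07 Hz edge belongs to both bands (a config-free
consequence of reading "0.02–0.07" and "0.07–0.2" as closed intervals).

### Reference DCA estimators

Multi-center DCA methods fall into three output categories, and the package
implements one transparent reference per category rather than any center's
proprietary variant:

* **Transfer function analysis** (`tfa_gain_phase()`, category 1):
  `H(f) = Sxy/Sxx` from the same Welch configuration; gain and phase are
  band averages. The complex `H` is averaged over band bins before taking
  modulus and angle — robust at low coherence — with a polar (separate
  gain/unwrapped-phase averaging) alternative available. Positive phase
  means CBFV leads MABP. No coherence-based bin exclusion is applied by
  default; a threshold option exists.
* **Autoregulation index** (`tiecks_ari()`, category 2): the classical
  10-grade second-order model. Grade constants (T, D, K) are the canonical
  table from the model literature; they are not study parameters. MABP is
  normalised as fractional change about its recording mean, without a
  critical closing pressure offset — the dimensionless form keeps the
  package free of a parameter the data cannot identify, and the estimator is
  used comparatively (grades are fitted and generated under the same
  convention). The index is the residual-minimising grade with optional
  parabolic interpolation, clipped to [0, 9].
* **Correlation index** (`mx_index()`, category 3): Pearson correlation of
  10-s block means computed per 300-s epoch and averaged, the Mx convention.

### Reproducibility statistics

`icc_oneway_single()` implements the one-way random-effects, single-measures
ICC — `(MSB − MSW)/(MSB + (k−1)MSW)` — matching the "one-way" setting of
mainstream statistical packages; session order carries no meaning for
duplicate resting measurements. Before ICC, each (method, variable) is
Box-Cox transformed (`boxcox_fit()`), with the power parameter fitted once by
profile likelihood on the pooled sessions *before any case removal* and
reused at every cut-off level, so both sessions always receive the same
transformation. Variables that can be non-positive (phase, correlation
indices) are shifted by `−min + 1e−6·range` first; the shift is monotone
affine, so orderings are preserved.

Percentile cut-offs (`percentile_cutoffs()`) default to the
linear-interpolation definition (R type 7), with an SPSS-compatible weighted
average (type 6) as an option; the 0th percentile is the minimum and removes
nobody. Retention is `lowest_pair_psd >= cutoff` (ties retained), and the
grids are computed once per band on the whole cohort so every method sees the
same retained-case set at each level. VLF variables filter on VLF power and
LF variables on LF power; LF variables additionally get a secondary
VLF-filtered curve. Variables without an intrinsic band (ARI, correlation
index) filter on VLF, the band in which advisory power thresholds for those
variables are expressed.

The linear-trend test (`rm_anova_linear_trend()`) treats analysis methods as
repeated-measures subjects and computes the F for the orthogonal-polynomial
linear contrast across cut-off levels. Because a single contrast is tested,
this F needs no sphericity correction; with a grouping factor it also
reports the group main effect (on method mean ICC) and the group × trend
interaction. Levels whose ICC is missing for all methods (fewer than 10
retained subjects) are dropped, so a 10-level grid typically contributes 9
usable levels at cohort size 75.

The Monte Carlo ICC-difference test (`mc_icc_difference_test()`) is a
reconstruction — the original's simulation details are not published in the
main text. Null model: both methods share the pooled ICC, taken as the mean
of the two single-measures estimates; each replicate draws two independent
sets of n bivariate-normal session pairs at that intraclass correlation and
records the absolute ICC difference; `p` is the proportion of null
differences at least as large as observed. A 5000-trial calibration run
(n = 75, true ICC 0.5, 2000 replicates) measured a type-I error of 0.047 at
α = 0.05.

### Duration prophecy

`spearman_brown()` implements `ICC_SB = n·ICC/(1 + (n−1)·ICC)` and
`required_duration()` its inverse, rounded up to whole multiples of the 5-min
base recording. Summaries use the median ICC across methods per variable at
cut-off level 0, i.e. reliability before any case removal. The prophecy
assumes autoregulation is stationary over the extended recording — an
assumption the package cannot test.

## The synthetic world

Two generators make every stage testable without access to the study data.
Their defaults are the stated measurement conditions, chosen once:

* `signal_gen_config()` / `gen_cohort()`: 75 subjects × 2 sessions of 600 s
  at 10 Hz; MABP mean 90 mmHg with band-limited Gaussian noise synthesised
  in the frequency domain (random phases) so the realised Welch band means
  hit per-subject targets within 15%; targets are lognormal across subjects
  with medians at the advisory thresholds (29 mmHg²/Hz VLF, 10 LF; spread
  0.8 on the log scale, roughly a factor-2 interquartile spread) so default
  cohorts straddle them. Because the two analysis bands share the 0.07 Hz
  edge bin, the two synthesis levels are solved from a 2×2 system so both
  band *means* are unbiased even when the band targets are very unequal.
  CBFV (mean 55 cm/s) is generated through the grade model at a true grade
  drawn from 3–7 (the healthy mid-range) with 10% white measurement noise;
  EtCO2 is 5 kPa plus small noise. Generated recordings pass the validation
  rules by construction.
* `table_gen_config()` / `gen_estimate_table()`: duplicate estimates with
  per-subject truth ~ Normal(μ, σ_b²) and session noise whose SD scales as
  `(psd/median)^γ` with the subject's lowest-of-pair band power, rescaled so
  the population ICC stays at its configured value. Negative γ (default
  −0.3) reproduces the mechanism under study: |difference| shrinking with
  power, negative Spearman correlations, rising ICC curves; γ = 0 gives flat
  curves. Default true ICCs are the study-scale reliabilities implied by the
  published duration analysis (gain LF 0.60, phase LF 0.43, gain VLF 0.34,
  ARI 0.28, phase VLF 0.18; the correlation index, absent from that
  analysis, is set to 0.30).

What a green test does **not** establish: the generators contain no beat
morphology, no genuine nonstationarity, no EtCO2 dynamics, and session noise
that is exactly Gaussian — so passing tests validate the statistical
machinery and the mechanism's direction, not the numerical values any real
cohort would produce.

## Numerical choices and degenerate inputs

* Validation bounds (mean CBFV > 30 cm/s; EtCO2 in (3, 7) kPa; MABP in
  (40, 160) mmHg; ≥ 300 s) are checked per sample by default ("at all
  times"); a mean-scope switch exists for EtCO2 because the protocol wording
  is ambiguous. Step/drift detection (jumps > 20 units between adjacent 1-s
  medians; |slope| > 5 units/min) is advisory only, mirroring visual
  inspection.
* ICC is reported missing (with a reason) at zero total variance; curve
  levels retaining fewer than 10 subjects report `NA` rather than an
  unstable estimate.
* Spearman rows where all |differences| tie are reported missing, not forced
  to zero.
* The trend test treats an exactly constant curve matrix as F = 0, p = 1
  (floating-point residue in the contrast scores is zeroed below
  `1e-10 · max|ICC|`).
* `required_duration()` guards the exact-integer inverse with a 1e−12
  ceiling tolerance, reports ICC ≥ target as the base duration, and ICC ≤ 0
  as unattainable.
* All generators and the Monte Carlo test run in private RNG streams and
  restore the caller's `.Random.seed`.

## Known limitations

* The reference estimators are deliberately plain; they will not reproduce
  any particular center's numbers (wavelet, Volterra/Laguerre, multi-input
  ARX and similar variants are out of scope).
* The Monte Carlo null is a reconstruction (see above); it is mildly
  anticonservative in principle because the pooled ICC is a plug-in
  estimate, though measurement puts the realised type-I error within a point
  of nominal at n = 75.
* The published aggregate results of the multi-center study can only be
  reproduced from its deposited supplementary tables; the package reads such
  tables (`read_estimate_table()`) but does not ship them.
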