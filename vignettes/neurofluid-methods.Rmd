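---
title: "Methods: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurofluidr)
```

This vignette documents the models the package implements, the parameters
that matter, what the synthetic-data generators do and do not emulate, and
the numerical decisions taken where the design was genuinely open. It
states no empirical result that the test suite or `scripts/acceptance.R`
does not itself compute.

## BOLD–CSF coupling

Slow (0.01–0.1 Hz) oscillations of the cortical BOLD signal are
anticorrelated with the flow-related CSF inflow signal measured in a
ventricular voxel at the edge of the imaging slab: when neural/vascular
activity dips, cerebral blood volume falls and CSF flows in. The analysis
quantifies this with the time-domain lagged cross-correlation

$$ r(\ell) = \mathrm{corr}\big(b(t-\ell),\, c(t)\big), \qquad
   \ell = -L,\dots,L, $$

so a **negative** lag means BOLD precedes CSF. Three scalars summarise it:

* **coupling strength** — $r$ at a fixed reference lag, a parameter with
  presets −1 scan (human, TR 2.68 s) and 0 (mouse, TR 0.3 s). It is a
  parameter because both conventions are legitimate and must not be
  hard-coded. For the mouse the reference 0 follows the observation that
  the mouse anticorrelation peaks at zero lag at that much finer temporal
  resolution; whether per-animal optimal lags would be preferable is an
  open question, so the knob is exposed.
* **optimal lag** — the $\ell$ minimising $r(\ell)$ (strongest
  anticorrelation). Ties break to the smallest $|\ell|$, then to the
  negative lag: the physiological prior is that BOLD leads.
* **amplitude** — the sample SD of the cleaned series.

Each lag's correlation uses the overlapping segments' own means and SDs
(a true per-lag Pearson coefficient, bounded by 1 at every lag), rather
than normalising once by the full-series moments. Censored frames
propagate as pair-wise deletion inside each lag's overlap.

### Preprocessing

`preprocess()` applies, in order: truncation to the first `keep_first`
frames (human sessions use the initial 150 of 446 frames because motion
accumulates late in a session), polynomial detrend (default order 2),
zero-phase ideal band-pass, and edge trimming (default 5 frames per end
for the human TR; 250 per end for the mouse's 0.3 s TR). Scrubbing is done
before filtering: the order filtering↔scrubbing is not dictated by the
analysis definition, so it is fixed here as truncate → scrub → detrend →
bandpass → trim and documented — reproducibility over claimed optimality.
Scrubbed frames are dropped, never interpolated; with `action = "na"` they
stay in place as `NA` for lag-aware pair-wise deletion.

Frame-wise displacement is the backward-difference convention: the sum of
absolute differences of the six rigid-body parameters with rotations
converted to arc length on a sphere (default radius 50 mm for human heads;
5 mm suits a mouse). The censoring threshold is 0.35 mm, and "larger than"
is strict: a frame at exactly 0.35 mm is kept.

The band-pass is an ideal (boxcar) frequency-domain mask with zero phase.
This makes the filter a projection (idempotent), gives exact band
additivity of variance (Parseval), and matches the spectral definitions
used in the pulsation module. The trade-off — ringing near sharp edges for
signals with strong out-of-band energy — is acceptable for these smooth
physiological signals and is why the edge-trimming step exists.

## Glymphatic tracer kinetics

Dynamic T1-weighted volumes after intracisternal Gd infusion are
normalized per voxel by the mean of the 3 pre-injection baseline frames
and expressed as fractional signal change. The descriptors:

* **AUC** — the sum of signal change over post-injection frames; dividing
  by the whole-brain AUC removes animal-to-animal variation in delivered
  contrast. The division is applied to the AUC map only, not to the curve
  before kinetic extraction: the time-based parameters (arrival, TTP,
  Decay) are invariant to an overall amplitude scale, so dividing the
  curve first would change nothing they measure.
* **arrival time** — the first post-injection frame whose value strictly
  exceeds 20% of the maximum post-injection signal change, reported at
  frame resolution (3.33 min per frame); no sub-frame interpolation,
  because the definition is a threshold crossing on sampled frames.
  Strict (>) rather than non-strict inequality is a documented choice;
  at frame resolution the two differ only when a frame lands exactly on
  the threshold.
* **time-to-peak** — time of the global post-injection maximum; a plateau
  of equal maxima resolves to the earliest frame.
* **effective TTP** — TTP − arrival, an exact identity, useful because a
  late-arriving bolus shifts both.
* **influx rate** — the least-squares slope of signal change versus time
  over all frames in [arrival, TTP]; a regression because single frames
  are noisy (a two-point endpoint slope is available via
  `method = "two_point"`).
* **efflux** — nonlinear least squares of $A e^{-(t-t_{peak})/Decay} + C$
  on the post-peak frames. The clock starts at the peak frame, which
  removes the degeneracy between $A$ and the absolute time origin.

Numerical details of the decay fit: Levenberg–Marquardt
(`minpack.lm::nls.lm`) on the analytic residual, $Decay$ bounded positive,
initialization $C_0$ = last value, $A_0$ = peak − last,
$Decay_0$ = the half-fall time divided by $\ln 2$ (fallback: half the
post-peak span), plus two fallback starts; the best converged start by RSS
wins. Convergence tolerances are set to machine-level (1e−15 relative) so
that noiseless round trips recover parameters to better than 1e−6
relative. Failures are flagged (`converged = FALSE`) rather than silently
returning NaN, and per-voxel failures in `kinetic_maps()` appear in a QC
map and stay `NA` — never interpolated.

**Identifiability.** With the 40-volume (132 min) protocol, decay
constants around 60 min are at the edge of what the post-peak window can
identify at SNR 20: the profiled RSS in $Decay$ can develop a competing
minimum at small $Decay$ / large $C$. The monotonicity property in the
test suite (higher true Decay ⇒ higher estimate, paired on shared noise)
is therefore exercised with the 50-volume (166 min) acquisition, where the
window identifies the parameter for every replicate. Users fitting slow
decays should prefer the longer protocol or fix $C$.

## Arterial pulsation power

Fast single-slice EPI (TR 70 ms) resolves the cardiac waveform in voxels
containing arteries. The series is divided by its temporal mean (making
the measure invariant to receive gain and baseline intensity), the DC term
removed, and the one-sided power spectrum computed with powers scaled so
that they sum to the temporal variance (population convention, divisor
$n$) — Parseval's identity then holds to 1e−10 and a grid-frequency
sinusoid of amplitude $a$ carries $a^2/2$.

The cardiac peak is the maximum inside a physiological search band,
default 2.5–5.8 Hz = 150–350 beats/min (the monitored physiological
range); an external pulse-oximetry prior restricts the search to ±1 Hz
around it. Pulsation power is the variance of the signal after a
zero-phase ideal band-pass of **2 Hz total width** (±1 Hz) centred on the
peak. "Width" is read as total width; a half-width reading doubles the
band and is available via `width_mode = "half"`. At TR 70 ms the Nyquist
frequency is 7.14 Hz, so the first harmonic of a 4.58 Hz heart rate
(9.16 Hz) aliases to $|9.16 - 1/0.07| \approx 5.13$ Hz — inside the band.
The harmonic is not deliberately folded into the band; it contributes
exactly when it lands there naturally, and its folded location is always
recorded. The variance is taken of the band-passed signal itself, not of
its envelope.

## pCASL CBF quantification

The single-compartment quantification

$$ \mathrm{CBF} \;=\; \frac{\lambda\,(SI_C - SI_L)\,e^{PLD/T1_b}}
   {2\,\alpha\; T1_t\; SI_{PD}\,\big(1 - e^{-LT/T1_t}\big)},
   \qquad SI_{PD} = \frac{SI_C}{1 - e^{-TR/T1_t}} $$

with defaults λ = 0.9 ml/g (water partition coefficient), T1b = 2430 ms
(arterial blood at 9.4 T), LT = 3000 ms, PLD = 450 ms. With λ in ml/g and
times in ms the raw value is ml/g/ms; the package converts to the field's
conventional ml/100 g/min via the factor 100 × 60000, and the conversion
is pinned by a dimensional-analysis test. The formula is invariant to a
common rescaling of $SI_C$ and $SI_L$ and linear in their difference —
both asserted as tests.

Labeling efficiency comes from carotid signal in non-labeled vs labeled
images, $\alpha = (SI_{NL} - SI_L)/(2\,SI_{NL})$; when the labeling phase
is arrayed, the maximum α across settings is used, because the phase is
tuned to maximise inversion. Values outside [0, 1] (noise, failed
labeling) are clipped with a warning.

Tissue T1 is fitted per voxel with the magnitude inversion-recovery model
$|s_0(1 - b\,e^{-TI/T1})|$ with the inversion factor $b$ free rather than
fixed at 2: real inversion pulses are imperfect, and the extra degree of
freedom costs little with 12 inversion times (30–8000 ms).
Initialization: $b_0 = 2$, $s_{0,0}$ = signal at the longest TI, $T1_0$ =
TI nearest the magnitude minimum divided by $\ln 2$.

## Statistical toolkit

* `auto_compare()` gates on Shapiro–Wilk at p < 0.05 per group (the gate
  threshold is a convention fixed here, not derived): both normal →
  pooled-variance two-sample t (Welch behind a flag); otherwise Wilcoxon
  rank-sum. One-tailed directions must always be supplied by the caller —
  inferring the direction from the data would invalidate the p-value.
* `correlate()` wraps Pearson/Spearman with t-approximation p-values;
  `partial_correlation()` correlates the least-squares residuals of both
  variables on the covariates, with $n - 2 - k$ degrees of freedom. A
  degenerate x-residual (covariate collinear with x) errors; a degenerate
  y-residual returns estimate 0 (nothing of y is left to correlate).
* `holm_bonferroni()` is the step-down adjustment (identical to
  `p.adjust(method = "holm")`, exposed under the analysis's name).
* `joint_linear_models()` compares OLS models across predictor sets and
  reports each predictor's unique contribution as the R² drop when it is
  removed.
* `voxelwise_test()` computes pooled two-sample t per voxel, binarises at
  the voxel-level p (two-sided), labels 26-connected components, and
  keeps clusters at or above an extent threshold. The threshold is either
  user-set or calibrated as the 95th percentile of the maximum null
  cluster size under group-label permutation — a self-contained,
  assumption-light replacement for Gaussian-random-field Monte-Carlo
  cluster correction, exchangeability being the only assumption.

## The synthetic-data module

The generators are first-class, tested code; they define the conditions
under which every downstream claim is validated.

* `gen_coupled_bold_csf()` — BOLD is white Gaussian noise filtered with an
  ideal boxcar mask in the frequency domain (exact band control,
  deterministic), standardised to unit SD; CSF is
  $-a \cdot \mathrm{bold}(t + \ell_{true}) + \sigma\,\varepsilon(t)$, the
  lag applied by integer circular shift on an extended series with the
  wrapped segment discarded, so the true lag is exact with no edge
  transient. Defaults (dt = 2.68 s, 150 frames, 0.01–0.1 Hz, lag −1,
  noise SD 0.3 of the unit signal SD) are the human-like simulation
  conditions.
* `gen_motion_trace()` — slow sinusoidal drift plus persistent
  translation steps at chosen frames; the fixture for scrubbing tests.
* `gen_gd_curve()` — flat baseline, linear rise (sigmoid behind a flag,
  for robustness checks) from arrival to peak, then an exact
  $A e^{-t/Decay} + C$ tail, plus white noise. Defaults put arrival and
  peak on the 3.33 min frame grid (arrival 6.66 min, TTP 39.96 min, peak
  0.8, A 0.75, Decay 40 min, C 0.05 over 40 frames) so that noiseless
  curves lie exactly on the model — the basis of the round-trip tests.
  The infusion dose itself is not modelled, only signal shape (the
  published dose arithmetic is internally inconsistent, and no kinetic
  quantity here depends on absolute dose).
* `gen_pulsatile_signal()` — sinusoids at the cardiac frequency (default
  4.58 Hz) and its first harmonic generated in continuous time and
  sampled at dt, so the harmonic aliases naturally; plus respiration
  (1.5 Hz ≈ 90 breaths/min), a vasomotion line inside 0.01–0.1 Hz, white
  noise, and unit mean. Fractional amplitudes (0.05 cardiac, 0.02
  harmonic, 0.03 respiratory, 0.02 vasomotion) are typical of arterial
  voxels at 9.4 T.
* `gen_asl_dataset()` — constant positive control signal; label computed
  by the exact algebraic inverse of the quantification formula at the
  requested true CBF, with a per-voxel T1 map. Quantification on
  generated data is therefore an identity up to floating point.

One master integer seed; each generator derives an independent substream
by a fixed offset (and a per-subject stride), so identical configurations
are bit-identical across runs while streams stay independent.

What the generators do **not** emulate: scanner physics (k-space, T2\*
decay), partial-volume effects, registration error, physiological
non-stationarity (heart-rate drift, varying coupling), 1/f noise, or
spatially correlated noise. Passing tests therefore demonstrate
correctness of the estimators under the stated signal models — recovery of
known ground truth, agreement with brute-force oracles, calibration under
exchangeable nulls — not robustness to every artifact of real data.

## Problem sizes

The validation suites use sizes chosen to make the statistical assertions
meaningful at desk scale: 20 subjects × 150 frames for lag recovery, 100
noisy curves (SNR 20) for kinetic recovery, 2000 null draws (n = 8 + 8)
for the type-I-error calibration, and 500 null simulations on a 6×6×4
grid with 60 label permutations each for the cluster false-positive rate.
The permutation count trades resolution of the null quantile against
runtime; 60 permutations resolve the 95th percentile of the maximum
cluster size adequately on such a grid because the distribution is
discrete with few mass points.

## Known limitations

* The ideal band-pass assumes stationarity over the series; strong
  non-stationarities leak.
* Arrival time at frame resolution carries a ±1-frame (3.33 min)
  quantisation; sub-frame estimates would require interpolation the
  definition avoids.
* The decay fit's parameters are jointly identifiable only when the
  post-peak window spans a reasonable multiple of the decay constant (see
  the identifiability note above).
* Cluster inference assumes group exchangeability; it does not model
  spatial autocorrelation explicitly (the permutation null inherits it
  from the data).
* No image registration, denoising, or distortion correction is provided;
  inputs are assumed spatially aligned.
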