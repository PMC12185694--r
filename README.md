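# neurofluidr

Quantitative analysis of neurofluid MRI in R: coupling between cortical
BOLD oscillations and ventricular CSF inflow, glymphatic tracer kinetics
from dynamic Gd-enhanced MRI, cardiac-band arterial pulsation power with
explicit alias handling, and cerebral blood flow (CBF) from
pseudo-continuous arterial spin labeling (pCASL) — together with the
statistical procedures that link them and a synthetic-data module that
generates every input with known ground truth.

The package is for researchers studying CSF dynamics, glymphatic clearance
and neurovascular physiology with MRI, who need the quantitative core of
such a study as tested, reusable, scriptable functions. Everything takes and
returns tibbles, so analyses compose with the pipe; fitted objects support
`tidy()`/`glance()` and result types have `autoplot()` methods.

## The quantities it computes

**BOLD–CSF coupling.** With `b(t)` a cleaned regional BOLD series and
`c(t)` the CSF inflow signal, the lagged cross-correlation is the Pearson
correlation of the overlapping segments

  r(ℓ) = corr( b(t − ℓ), c(t) ),  ℓ = −L … L (frames),

so negative lags mean BOLD precedes CSF. Coupling strength is `r` read at a
species-specific reference lag (−1 scan human, 0 mouse); the optimal lag
minimises `r(ℓ)` (strongest anticorrelation); oscillation amplitude is the
temporal SD of the cleaned series. Preprocessing follows the resting-state
convention: second-order polynomial detrend, zero-phase ideal bandpass to
0.01–0.1 Hz, motion scrubbing at frame-wise displacement > 0.35 mm, edge
trimming.

**Glymphatic kinetics.** An enhancement curve, normalized to the mean of
the pre-injection baseline frames, is summarised by its post-injection AUC
(optionally normalized by the whole-brain AUC), arrival time (first frame
strictly above 20% of the maximum signal change), time-to-peak, effective
time-to-peak (TTP − arrival), influx rate (least-squares rising slope
between arrival and peak), and the efflux fit
`A·exp(−(t − t_peak)/Decay) + C` by nonlinear least squares.

**Pulsation power.** The signal is divided by its temporal mean and Fourier
transformed; the cardiac peak is located in a physiological search band
(default 2.5–5.8 Hz, i.e. 150–350 bpm); a zero-phase ideal bandpass of 2 Hz
total width around the peak is applied and the variance of the filtered
signal is the pulsation power. Frequencies above Nyquist fold as
`f_alias = |f − round(f·dt)/dt|`; at dt = 70 ms a 4.58 Hz heart rate puts
the first harmonic (9.16 Hz) at ≈ 5.13 Hz, inside the cardiac band.

**pCASL CBF.** Per voxel,

  CBF = λ (SI_C − SI_L) e^{PLD/T1b} / ( 2 α T1_t SI_PD (1 − e^{−LT/T1_t}) ),
  SI_PD = SI_C / (1 − e^{−TR/T1_t}),

with λ = 0.9 ml/g, T1b = 2430 ms, labeling efficiency
α = (SI_NL − SI_L)/(2 SI_NL) from carotid labeling data, and tissue T1 from
a magnitude inversion-recovery fit `|s0 (1 − b e^{−TI/T1})|`. Output is in
ml/100 g/min.

**Statistics.** Shapiro-Wilk-gated group comparisons (pooled t vs Wilcoxon
rank-sum), Pearson/Spearman correlation with explicit one-tailed
directions, partial correlation by residualization, Holm-Bonferroni
step-down adjustment, linear-model comparison with per-predictor unique
R², and voxel-wise two-sample t-maps with 26-connected cluster-extent
correction calibrated by label permutation.

## Worked example

```r
library(neurofluidr)

cfg <- sim_config(seed = 42, true_lag = -1, noise_sd = 0.3)   # human-like
sim <- gen_coupled_bold_csf(cfg, subject = 1)
bold <- preprocess(sim$bold, detrend_order = 2, band = c(0.01, 0.1), trim = c(5, 5))
csf  <- preprocess(sim$csf,  detrend_order = 2, band = c(0.01, 0.1), trim = c(5, 5))
bold_csf_coupling(bold, csf, max_lag = 10, reference_lag = -1)
#> # A tibble: 1 × 4
#>   strength optimal_lag optimal_r amplitude
#>      <dbl>       <int>     <dbl>     <dbl>
#> 1   -0.979          -1    -0.979     0.986
```

The simulated subject was built with its CSF signal anticorrelated to BOLD
one scan later, and the analysis recovers exactly that: the strongest
anticorrelation (−0.979) falls at lag −1, and the coupling strength read at
the human reference lag −1 equals it. The amplitude column is the temporal
SD of the cleaned BOLD series (arbitrary units; ≈ 1 because the generator
standardises the BOLD process).

Tracer kinetics from a noisy synthetic enhancement curve (SNR 20):

```r
curve <- gen_gd_curve(cfg, noise_sd = 0.04)$curve
gd_kinetics(curve)
#> # A tibble: 1 × 10
#>     auc arrival_time   ttp effective_ttp influx_rate     A Decay     C fit_rss
#>   <dbl>        <dbl> <dbl>         <dbl>       <dbl> <dbl> <dbl> <dbl>   <dbl>
#> 1  13.3         16.6  40.0          23.3      0.0283 0.718  31.3 0.119  0.0291
```

Arrival (16.6 min), time-to-peak (40 min) and effective TTP (23.3 min) are
in minutes since injection; the influx rate is fractional signal change per
minute; `Decay` (31.3 min, true value 40) is the efflux time constant of
the post-peak exponential fit at this noise level.

Pulsation power and CBF close the loop the same way:

```r
pl   <- gen_pulsatile_signal(sim_config(seed = 42, n_frames = 2500, dt = 0.07))
spec <- normalize_and_spectrum(pl$ts)
pulsation_power(pl$ts, cardiac = detect_cardiac_peak(spec))
#> # A tibble: 1 × 7
#>   cardiac_freq band_lo band_hi   power temporal_sd harmonic_alias harmonic_in_band
#> 1         4.58    3.58    5.58 0.00146      0.0462           5.12 TRUE

asl <- gen_asl_dataset(sim_config(seed = 42, asl = list(cbf_true = 120)))
mean(quantify_cbf(asl$control, asl$label, asl$t1_map, asl$params))
#> [1] 120
```

The detected cardiac line sits at 4.58 Hz, its aliased first harmonic at
5.12 Hz falls inside the 2 Hz band and contributes to the power
(variance of the filtered mean-normalized signal); the ASL round trip
returns the generating CBF exactly.

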