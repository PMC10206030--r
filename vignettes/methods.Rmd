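---
title: "Detecting compensatory movements from muscle NIRS: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting compensatory movements from muscle NIRS: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirscomp)
```

## The problem

Stroke survivors recovering upper-limb function often recruit trunk muscles
to substitute for the impaired arm — leaning the trunk forward instead of
reaching (LF), rotating it instead of reaching sideways (TR), or hiking the
shoulder instead of reaching upward (SE). These compensatory patterns feel
efficient but hinder long-term recovery, so rehabilitation systems want to
detect them automatically and tell the patient which muscles are doing the
compensating.

Muscle near-infrared spectroscopy (NIRS) measures each muscle's hemodynamics
optically: every sensor yields two concentration-change series,
deoxyhemoglobin ($Hb$) and oxyhemoglobin ($HbO_2$). `nirscomp` implements a
complete detection chain over six trunk muscles (left/right obliquus externus
abdominis, descending trapezius, erector spinae — LOEA/ROEA, LDT/RDT,
LES/RES) sampled at 16 Hz, classifying each trial as NC (no compensation),
LF, TR or SE.

## Signal model and the two improvement transforms

Two physiological drivers move the chromophore pair. Blood-flow changes move
$Hb$ and $HbO_2$ **together**; oxygen consumption moves them **apart**. The
differential-based signal improvement (DBSI) separates the two with a fixed
linear bijection:

$$CMS = \tfrac12(HbO_2 + Hb), \qquad DMS = \tfrac12(HbO_2 - Hb)$$

The common-mode signal (CMS) tracks blood flow, the differential-mode signal
(DMS) tracks oxygen consumption, and `dbsi_inverse()` reconstructs the pair
exactly. The older correlation-based signal improvement (CBSI) instead
assumes perfect anti-correlation of the pair and splits it as

$$\alpha = \frac{\mathrm{std}(HbO_2)}{\mathrm{std}(Hb)}, \qquad
  TNS = \tfrac12(HbO_2 + \alpha Hb), \qquad
  TFS = \tfrac12(HbO_2 - \alpha Hb)$$

with the true functional signal (TFS) as its output of interest and the true
noise signal (TNS) treated as nuisance. Standard deviations use the
population (divisor-$n$) convention, and $\alpha$ is computed per channel per
trial; pooling $\alpha$ across trials would let one trial's amplitude leak
into another's transform.

```{r transforms}
s <- dbsi(hb = c(0, 1), hbo2 = c(2, 3))
rbind(CMS = s$series_a, DMS = s$series_b)
```

## Synthetic study conditions

The study's subject recordings are not publicly deposited, so the package
ships a generator (`generate_trial()`, `generate_dataset()`) that emulates
the statistical structure the analysis assumes, with ground truth exposed for
every stage. Clean trials are built in (CMS, DMS) space and mapped to
$(Hb, HbO_2)$ through the inverse DBSI map, which makes the DBSI round trip
an exact oracle for the generator.

Default conditions, chosen once as representative of seated reaching trials:

* 10 s trials at 16 Hz; activation onset at 20% and offset at 80% of the
  trial, logistic ramps of `rise_time = 2` s (hemoglobin takes a few seconds
  to reach a new plateau);
* a class-by-channel activation map (`default_activation_map()`): ROEA
  dominates LF and TR (with RDT/LES secondaries distinguishing TR), RDT and
  RES dominate SE, and NC engages the executing side mildly. Amplitudes are
  in arbitrary concentration-change units (no µM calibration is assumed);
  DMS amplitudes are $-0.3\times$ CMS, since activation extracts oxygen;
* slow drift: a sinusoid of period 120 s (sensor/temperature drift is
  minutes-scale) at amplitude 0.3 plus a random linear term;
* cardiac interference at 1.2 Hz entering both chromophores with the same
  sign (pulsatile blood volume is common mode), amplitude 0.1;
* white noise (SD 0.05) and 2% dropped samples (never within the first
  four samples, so the padding rule always has a complete prefix);
* per-subject lognormal amplitude jitter (log-SD 0.1), making
  cross-validation across subjects non-degenerate.

What the generator does **not** emulate: motion artifacts (spikes), optode
coupling changes, inter-trial fatigue trends, and the biophysics from raw
optical densities to concentrations. Passing tests therefore demonstrate the
pipeline's correctness and its behavior under the modeled artifact classes,
not clinical performance on real recordings.

## Preprocessing

Per channel and chromophore, in order:

1. **Padding.** Each dropped sample is replaced by the mean of the four
   preceding values, already-filled values counting as available
   (`pad_missing()`); a dropout within the first four samples is an error
   rather than a guess.
2. **Low-pass filtering.** Zero-phase (forward–backward) 6th-order
   Butterworth at 0.5 Hz (`lowpass()`). Offline analysis has no latency
   constraint, and zero-phase filtering preserves segment timing for the
   slope analysis. At this cutoff (1/16 of Nyquist) the order-6 polynomial
   transfer function is numerically ill-conditioned, so the filter is built
   as cascaded second-order sections from analytically placed Butterworth
   poles, with odd-reflection padding and steady-state initial conditions to
   suppress edge transients.
3. **Baseline removal.** Empirical mode decomposition (`emd()`: cubic-spline
   envelope sifting with mirrored boundary extrema) estimates the slow
   baseline, which is subtracted (`remove_baseline()`).

### Which EMD components form the "baseline"?

This is the one genuinely open design point in preprocessing. On long,
multi-activation records the standard choice is the EMD residual (optionally
plus the lowest-frequency IMF). On a 10-s record holding a **single**
activation, that choice is wrong in a structural way: an intrinsic mode
function must oscillate, so a lone plateau can never be extracted as an IMF
and always ends up in the residual — subtracting the full residual flattens
the activation the pipeline is meant to measure, and in our experiments
collapsed both the activation-level summaries and end-to-end accuracy.

The default rule `residual_trend` therefore subtracts only the **linear
trend of the residual**: within a trial, drift (a sinusoid with period at
least an order of magnitude above the trial length, plus a linear term) is
linear to about 1%, while a plateau centered in the trial is orthogonal to a
linear trend and survives. Both classical rules remain available
(`preprocess_config(emd_baseline_rule = ...)`) for long-record use. A
consequence worth knowing: the operation removes the series' own mean and
slope even on clean input, so preprocessed series are trend-free rather than
identical to clean input.

When a series is not oscillatory enough to sift at all (e.g. noise-free
simulated input after filtering), `remove_baseline()` falls back to plain
linear detrending with a warning.

## Activation segments via the linear fitting slope

The linear fitting slope (LFS) of a window is the ordinary least-squares
slope of the signal against time,

$$\mathrm{LFS} = \frac{\sum_i (t_i - \bar t)(x_i - \bar x)}
                     {\sum_i (t_i - \bar t)^2},$$

computed over 500 ms windows (8 samples) with 250 ms stride (4 samples).
Consecutive windows whose slopes share a sign and exceed a "zero" threshold
form candidate runs; a run is accepted as active when the mean of its window
slopes approximately equals the slope fitted over the whole run (within 50%
relative) and that run slope is not approximately zero. Rising runs are
activations, falling runs deactivations; accepting a run additionally
requires at least `min_run_windows = 3` consecutive windows (1 s), because
hemodynamic transitions take seconds and shorter slope excursions are noise.

The zero threshold is calibrated per series as
$\max(3 \times \mathrm{median}\,|\mathrm{window\ slopes\ in\ the\ first\
second}|,\ 0.05 \times \max|\mathrm{window\ slope}|)$: the first term adapts
to the trial's rest-period noise, the second keeps noise-free plateaus from
registering as activity. The run-level slope (rather than a whole-trial
slope) is used as the reference because a trial containing both a rise and a
fall has a near-zero whole-trial slope, which would make the acceptance
criterion unsatisfiable. All tolerances are configurable
(`segment_config()`); the 50% / 3× / 5% defaults are assumptions, not
measured constants.

```{r segments}
tr <- generate_trial(sim_config(noise_sd = 0, drift_amplitude = 0,
                                cardiac_amplitude = 0, missing_rate = 0),
                     "LF", seed = 7)
sig <- improve_recording(preprocess_recording(tr$recording), "DBSI")
subset(segment_recording(sig), channel == "ROEA" & series == "CMS")
```

## Features and windowing

Each window contributes its mean (MEA) and population standard deviation
(STD) per channel per component: 6 channels × 2 components × 2 features = 24
columns (12 for single-component signal types). `extract_features()` windows
densely by default; the pipeline drivers restrict windows to detected active
segments (`restrict_to_active = TRUE`, union over channels), which follows
the study design of extracting features from activation segments. The
restriction matters: windows before onset and after offset are
class-indistinguishable by construction (every class rests identically), so
dense windowing injects an irreducible error floor at the window level.
Partial windows at trial edges are dropped rather than padded. The
windowing mode is carried in the evaluation report's configuration echo.

## Classification and evaluation

A soft-margin SVM with Gaussian RBF kernel and penalty $C = 0.3$, one-vs-one
multiclass voting (libsvm), evaluated by stratified 10-fold cross-validation.
Per fold, z-score normalization parameters are fitted on the nine training
parts only and applied to the held-out part — scaling is the classic leakage
channel, and the test suite asserts that test-side outliers cannot move the
training-side parameters. The RBF width defaults to
$\gamma = 1/(p \cdot \overline{\mathrm{var}})$ over the $p$ features — a
scale-free choice, since no single fixed $\gamma$ suits all signal types. Class order is fixed at
NC < LF < TR < SE so pairwise-voting ties resolve deterministically.

The default split unit is the window, mirroring a random sample-level split;
note that window-level splitting places temporally adjacent (hence
correlated) windows of the same trial in train and test folds, which inflates
accuracy relative to trial- or subject-level splits. Both alternatives are
provided (`classifier_config(split_unit = ...)`). Reports carry both the
mean of fold accuracies and the pooled-prediction accuracy, since either
convention is found in practice; on balanced folds they differ negligibly.

## Problem sizes used in the shipped analyses

The numbered drivers under `analysis/` run demonstration-scale cohorts
(4 healthy / 3 stroke subjects at the study's 20/20/20/10 trials per class);
`scripts/acceptance.R` runs the full cohort sizes (10 healthy / 6 stroke).
The verification suite uses 6 subjects × 20 trials per class for the
end-to-end accuracy property, 100 clean trials for segment recovery, and
1,000–10,000 random draws for the transform and slope oracles. The
permutation-null check (chance-level accuracy on shuffled labels) runs on a
3,000-window subsample: SVM training on non-separable labels scales
quadratically, and chance level does not depend on the sample size.

## Known limitations

* Per-trial EMD detrending on single-activation records reduces, by design,
  to "EMD residual trend" removal; the classical residual rules only become
  meaningful on longer multi-activation records.
* The activation map's amplitudes are free parameters of the generator: the
  class patterns (which muscles dominate which compensation) are grounded in
  the rehabilitation literature, the magnitudes are not.
* Window-level cross-validation optimistically estimates generalization to
  new subjects; use `split_unit = "subject"` for a deployment-facing
  estimate.
* The segment detector reports ramps (concentration *change*), not the full
  activated span; activation-level summaries in `analysis/03_segment.R`
  bridge the two by averaging CMS between the first and last active segment
  of a channel.
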