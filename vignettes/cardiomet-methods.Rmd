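---
title: "Methods: signal analysis, morphometry and statistics in cardiomet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signal analysis, morphometry and statistics in cardiomet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiomet)
```

cardiomet implements the quantitative workflow of rodent
metabolic-syndrome exercise studies: continuous arterial-pressure
analysis, autoregressive spectral quantification of systolic-pressure
variability, baroreflex gains, the insulin-tolerance-test constant
Kitt, stereological morphometry of heart and aorta, and the group
statistics that compare control (C), sedentary fructose (F) and
trained fructose (FT) cohorts.  This vignette documents the models,
the tunable parameters, the numerical choices, and what the synthetic
generators do and do not emulate.

## Beat-to-beat hemodynamics

A rat arterial-pressure recording is pulsatile at 4–8 beats/s.
`detect_beats()` marks systolic peaks as strict local maxima rising
above a rolling one-second median by a prominence threshold (default
0.3 × the signal interquartile range), with a refractory period of
`60/max_hr` seconds; the physiologic band defaults to 200–500 bpm,
spanning resting bradycardia to stress tachycardia in the rat.  No
published criterion exists for the detector itself, so it was designed
for the one property that matters downstream: one detection per
simulated systole across that band.

`beat_series()` defines each beat from its systolic peak to the
diastolic trough preceding the next upstroke.  SAP is the window
maximum, DAP the trough, and MAP the time-average of the waveform over
the window — not the DAP + PP/3 estimator, because the signal itself
is available.  This windowing matters: a peak-to-peak window would
include the next beat's upstroke, so a beat followed by a taller beat
would inherit the taller systole and the systogram variance would be
biased low.  With the peak-to-trough window the per-beat ordering
DAP ≤ MAP ≤ SAP holds by construction, and partial edge beats are
discarded.  Whether DAP should be read before or after the systolic
peak is not standardised; the between-peaks minimum is used here.

## Systolic pressure variability

The systogram is treated as an evenly sampled series at the mean beat
rate (beats/s), the beat-domain convention of rodent blood-pressure
variability work; no resampling to uniform time is attempted.  The
series is divided into 300-beat segments with 50 % overlap (a
remainder shorter than one hop is dropped; a series shorter than one
segment is analysed whole, with a warning).  Each segment is
mean-detrended and its autocovariance estimated with the biased
(divide-by-N) estimator, which guarantees a positive-semidefinite
sequence for the recursion.

AR coefficients are obtained by the Levinson–Durbin recursion in
predictor form; the innovation variance path over orders 0–24 comes
out of the same pass, and the order is chosen by Akaike's criterion in
the form `AIC(p) = N log(sigma2_p) + 2(p + 1)` over 4–24, ties going
to the smaller order.  A constant segment short-circuits to the
minimum order with a zero-variance flag.  The one-sided spectrum
`PSD(f) = 2 sigma2 / (fs |1 − Σ a_k e^{−i2πfk/fs}|²)` integrates to
the process variance (checked against the theoretical Yule–Walker
variance to 1 % in the tests); band powers are trapezoidal integrals
over LF 0.2–0.6 Hz and HF 0.6–3.0 Hz with interpolated edges.  At rat
beat rates the HF edge can exceed the systogram Nyquist (e.g. 2.7 Hz
at 325 bpm); the band is then read up to Nyquist.  Segment spectra are
averaged before band integration, and the headline "variance" is the
time-domain sample variance of the full systogram — the spectral
integral is also reported, since the two need not coincide exactly.

The spectral grid defaults to 4096 points in `sap_variability()`
(1024 in a bare `ar_spectrum()` call).  The denser default is sized to
the narrowest peak the pipeline is expected to integrate: a nearly
sinusoidal Mayer-wave component drives the fitted pole radius toward
unity, and the trapezoid needs several grid points across the
resulting peak.  Band quantification is by direct PSD integration;
pole/residue component decomposition is deliberately out of scope.

## Baroreflex gains

Trials are tables of per-bolus MAP and HR changes.  Only boluses with
|ΔMAP| in the closed window 5–40 mmHg enter the estimate; the gain is
the mean of per-bolus ratios ΔHR/ΔMAP, which follows the "response per
millimetre of mercury" reading; a least-squares slope variant is
available (`method = "slope"`) for sensitivity analysis, since
averaging ratios versus regressing is not standardised.  BR (pressor
trials) is reported signed, typically negative; TR (depressor trials)
as a positive magnitude, matching the usual tabulation convention.
The response epoch is assumed pre-extracted; segmenting bolus
responses out of the raw waveform is out of scope.

## Insulin sensitivity (Kitt)

Glucose disappearance after an insulin bolus is exponential during the
linear phase of decline, so `kitt()` fits the least-squares slope of
ln(glucose) against time over a window (default 4–16 min, excluding
the pre-injection baseline), converts to t½ = ln 2 / k, and reports
Kitt = 100 × 0.693/t½ in %/min — the 0.693 constant is kept literal so
printed half-life tables reproduce exactly.  A raw-scale linear fit is
available behind `scale = "linear"`.  Non-decaying series return
Kitt = 0 with a flag rather than a negative value.  For recovery
studies on the synthetic generator the fit window 0–16 min is
appropriate, because the generator has no injection-lag phase: its
whole series is the linear phase, and excluding t = 0 only discards
precision.

Caloric bookkeeping uses 2.89 kcal per chow gram and 4.0 kcal per
fructose gram at 100 g/L.  A known quirk of the source tables in this
literature is that printed total caloric intakes are not exactly
reproducible from printed mean consumptions and these factors; the
package applies the stated factors and leaves the discrepancy to the
reader.

## Morphometry and stereology

Point counting uses systematic uniform random sampling: a near-square
lattice of exactly `n_points` positions with one uniform random
offset, which is unbiased for volume fraction with lattice efficiency.
The classic test systems are 82 points (atrial electron micrographs),
140 (left-ventricle EM) and 200 (aorta histology).  Vv = 100 PP/PT;
its sampling error on fine-grained structure approaches the binomial
√(f(1−f)/PT), which the tests verify on synthetic fields.

Granule morphometry labels connected components, takes per-profile
areas, and converts to equivalent-circle diameters 2√(area/π) —
adequate for near-circular secretory-granule profiles.  Vessel
geometry follows the standard chain: lumen diameter d = 2√(a/π) from
the traced lumen area; IMT as the mean of four radial measures at
0/90/180/270°; IMA as the annulus π[(d/2 + IMT)² − (d/2)²] corrected
for fixation shrinkage by ×1.28; elastic lamellae counted as rising
band crossings along 36 radial profiles, median across rays after a
3-point median smoothing of each profile (robust to isolated staining
noise); and circumferential wall tension by Laplace's law,
CWT = MSAP × d/2.  CWT is reported primarily in mmHg·mm — the scale on
which published rat aorta values are mutually consistent — with the
dyne/cm conversion (×133.322) alongside.

Percent-change summaries of trained-versus-sedentary contrasts are
computed under both denominators; the `auto` convention (decreases
expressed on the sedentary-fructose reference, increases on the
trained value) is the only single convention consistent with the usual
abstract-style reporting of such studies, and both are always
labelled.

## Group statistics

Endpoints are screened with the Lilliefors-corrected KS test
(`nortest::lillie.test`), compared by classical one-way ANOVA (sums of
squares computed in-package, verified against `lm`/`anova` oracles),
followed by the Student–Newman–Keuls step-down studentized-range
procedure with `qtukey` quantiles (verified against direct numerical
integration of the studentized-range distribution) and harmonic-mean
group sizes under imbalance, with non-significant spans protecting
nested pairs.  Whether SNK should be gated on the omnibus test is not
standardised; it runs unconditionally and the omnibus result is
attached as a flag.  Repeated measures use `aov` with an
`Error(subject)` stratum; with two time points sphericity holds
trivially and no correction is applied, and the one-group two-time
case reduces to the paired t (F = t²).  α defaults to 0.05.

## The synthetic generators

The generators define the study conditions; their defaults are the
published group scales of the fructose model (Tables of group means ±
SEM at n = 8, with per-animal SDs reconstructed as SEM × √8).

- **Waveform**: each beat is a quarter-sine upstroke and exponential
  diastolic decay; only beat-level features matter downstream, so the
  intra-beat morphology is a free choice.  LF (0.4 Hz) and HF
  (1.5 Hz) oscillations amplitude-modulate the per-beat systolic
  values — not the carrier — because the spectral analysis operates on
  the systogram; a sinusoid of SD s injects variance s² into its band.
  Noise is Gaussian throughout, the simplest null consistent with
  mean ± SEM reporting.  Within-animal variance is anchored to the
  published SAP Var scale (23.5–41.9 mmHg²): the LF share is set to
  the published LF row and the remainder split 25 % respiratory
  (1.5 Hz) and 75 % white, a choice made once for all analyses.
- **ITT**: g0·2^(−t/t½) plus Gaussian noise, clipped at 1 mg/dL, at
  the protocol times 0/4/8/12/16 min.  No injection-lag phase is
  simulated.
- **Baroreflex trials**: ΔHR = gain × ΔMAP + noise over a four-bolus
  ladder; no dose–response saturation, so the linear gain is exactly
  recoverable.
- **Tissue fields**: non-overlapping random disks laid down until the
  requested area fraction is met (achieved fraction recorded; within
  one disk of the request), plus discrete objects placed with a
  clearance margin so connected-component counts are exact.
  Impossible packings (beyond ~70 % occupancy) are rejected.
- **Aortic rings**: concentric annulus with evenly spaced lamellar
  bands, optional collagen speckle and salt-and-pepper label noise.
  Band thickness adapts to wall thickness; configurations whose bands
  would merge are rejected.
- **Cohorts**: per-animal endpoint truths are drawn around the group
  means; white-adipose weight and LV collagen share a latent factor
  (ρ = 0.9) so the adiposity–fibrosis correlation seen in animal data
  emerges in pooled cohorts.  Physiologic orderings (SAP > DAP,
  positive densities) are enforced after drawing.

What the generators do not emulate — ectopic beats and movement
artefacts, respiratory modulation of the carrier pressure, insulin
pharmacokinetics, anisotropic or clustered tissue texture beyond
random disks, and staining variation beyond uniform label noise.
Passing tests therefore demonstrate estimator correctness under clean,
calibrated conditions, not robustness to every artefact of real
recordings.

## Problem sizes and determinism

Every generator takes an integer seed and restores the caller's RNG
state; identical seeds give bit-identical outputs, and the pipeline is
deterministic end to end under the cohort seed.  The test suite runs
at deliberately modest sizes chosen to make each check sharp but
cheap: 60–180 s waveforms at 500 Hz (the 2 kHz of acquisition hardware
adds nothing for beat-level analysis), 900-beat systograms for band
recovery, 200-seed Monte-Carlo loops for reflex gains, 500 noisy ITTs,
50 seeded 140-point grids on 1000² fields, and three-animal groups for
the end-to-end pipeline checks.

## Known limitations

- Granule profile areas are pixel-quantised (disk radii of a few
  pixels at 10 nm/px), so small between-group area differences are
  coarsened even though counts and volume densities are faithful.
- The per-field to per-mm³ conversion for numerical densities is
  section-thickness dependent and is not attempted; densities are
  reported per reference area with explicit units.
- The ANOVA/SNK chain assumes normality and homoscedasticity as the
  original designs do; no non-parametric fallback is provided, and no
  multiplicity control is applied across endpoints.
- Spontaneous (sequence-method) baroreflex estimation, heart-rate
  variability spectra, cross-spectral indices and sigmoid baroreflex
  curve fitting are out of scope.
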