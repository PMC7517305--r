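---
title: "Predicting rearrest from post-ROSC ECG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting rearrest from post-ROSC ECG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The clinical problem

Patients who recover spontaneous circulation (ROSC) after an
out-of-hospital cardiac arrest frequently suffer a secondary arrest
("rearrest", RA) before reaching hospital. Rearrest worsens outcomes, and
clinicians currently have no automated tool to anticipate it. The only
signal universally available on scene is the single-channel ECG recorded
through the defibrillation pads. `postrosc` implements a complete
prediction pipeline for this setting: from a short ECG window cut right
after the ROSC annotation (`tw` = 1 or 2 minutes, 250 Hz, amplitudes in
microvolts), it computes 21 features — 17 heart rate variability (HRV)
metrics and 4 waveform metrics — and classifies RA vs. sustained ROSC
(NoRA) with a class-balanced random forest, evaluated by repeated
stratified patient-wise cross-validation.

Because no public recording collection exists for this population, the
package ships a synthetic cohort simulator that plays the role of the
clinical data for development, testing, and validation. Every synthetic
record carries its ground-truth R-peak positions, which is what makes the
detector and feature stages testable at all.

## Signal conditioning

The analysis segment is the half-open window `[tROSC, tROSC + 60*tw)`;
records with less post-ROSC signal are skipped with a warning (mirroring
the minimum-duration requirement any clinical protocol imposes). The
segment is band-pass filtered between 0.5 and 40 Hz with an order-4
Butterworth filter applied forward and backward, giving zero net phase
(effective order 8 in magnitude). Zero phase matters: R-peak *positions*
feed every HRV feature, so the filter must not displace them — a property
tested against ground truth (shift of at most one sample). Segments are
reflect-padded by roughly three periods of the low band edge before
filtering; the alternative (no padding) leaves visible end transients in
1-minute windows.

## QRS detection and signal quality

The primary detector is a Hamilton–Tompkins pipeline: 8–16 Hz band-pass
emphasis, differentiation, rectification, 80 ms moving-window
integration, then adaptive peak/noise thresholds with a 200 ms refractory
period and a searchback pass that re-examines gaps longer than 1.5 times
the running mean RR. Detections are refined to the local ECG extremum
within ±40 ms. Detector constants are the published defaults of the
algorithm family; none were re-tuned here.

Large transient artifacts (electrode motion, interventions) inflate the
adaptive thresholds and can suppress genuine beats that follow. The
variance-based correction computes a sliding 1 s variance, amplitude-clips
samples inside windows whose variance exceeds 5 times the median window
variance to the 99th percentile of the remaining signal, re-runs the
detector on the clipped signal, and merges the two annotation sets (union
with 200 ms de-duplication, original indices kept on collision). The
concrete clip-and-re-detect scheme is this package's design — its stated
purpose (rescuing spike-suppressed beats) fixes the behaviour, not the
mechanism — and two properties anchor it: it is the identity on clean
records, and it never removes a beat present before correction.

A secondary, curve-length-transform detector (130 ms window, computed on
a 16 Hz low-passed copy of the signal, same adaptive thresholding) serves
one purpose: beat-agreement quality. The bSQI is the fraction of matched
beats (greedy nearest-neighbour one-to-one matching within 150 ms, the
standard tolerance of the beat-agreement literature) over the union of
both detectors' beats. bSQI is reported per record and never used to
exclude records. Both detectors drop detections within 100 ms of the
segment edges: a complex cut by the boundary cannot be located reliably,
and the two detectors would otherwise disagree arbitrarily there.

The RR series is built from the corrected annotations; intervals outside
0.2–3.0 s are dropped as artifacts (the wide upper bound deliberately
covers post-ROSC bradycardia). Whether to apply such a range rule at all
is a genuinely open choice; applying it only removes physically
impossible intervals and is the conservative reading.

## The 21 features

Time domain (v1–v6): mean RR, SDNN (sample SD), RMSSD, coefficient of
variation v2/v1, NN50 (successive differences over 50 ms), interquartile
range. Frequency domain (v7–v13): the RR series is mean-subtracted and
its Lomb–Scargle periodogram evaluated on a fixed 0.005–0.5 Hz grid with
0.0025 Hz steps — fine enough to resolve the LF band lower edge at
`tw = 1` min while keeping peak-frequency quantization below the grid
step. Absolute and relative LF (0.04–0.15 Hz) and HF (0.15–0.4 Hz)
powers are trapezoid-integrated; relative powers are normalized by LF+HF
(not total power), which makes v8+v10 = 1 and keeps v11 = v7/v9 consistent
with them — the normalization denominator is not standardized in the HRV
literature, and this is the self-consistent choice. Peak frequencies v12,
v13 are band-restricted argmaxima. The Lomb normalization is scaled so
grid-integrated power approximates the series variance.

Nonlinear (v14–v17): Poincaré SD1² and SD2² are the sample variances of
`(RR[k+1] − RR[k])/sqrt(2)` and `(RR[k+1] + RR[k])/sqrt(2)`; the sample
(n−1) convention is used everywhere, and the closed form
SD1² = ½·var(ΔRR) is asserted exactly in the tests. Sample entropy uses
the universal convention for short RR series: cubic interpolation to a
uniform 10 Hz series, m = 1, r = 0.2 times the SD of the *interpolated*
series, Chebyshev distance, self-matches excluded. Since r scales with
the SD, v17 is amplitude-scale invariant — a tested property.

Waveform (v18–v21): Welch PSD (12 s Hann windows, 50% overlap, 4096-point
FFT, so 9 windows per minute and a 0.061 Hz grid at 250 Hz) feeds the
spectral centroid v18 and the relative QRS-band power v20 (5–14 Hz over
the full grid; the filtered signal has negligible power outside 0.5–40 Hz,
so full-grid and band-limited denominators agree). v19 is the mean
absolute amplitude of the filtered segment (the pipeline order makes
"filtered" the natural reading). v21 is the SD of QRS durations
delineated on the quadratic-spline dyadic wavelet detail at scale 2²:
the modulus-maxima pair bracketing each R peak is found within ±120 ms
and onset/offset placed at the 0.1-fraction threshold crossings of the
local modulus maximum. The threshold fraction and window are fixed here
(the delineation literature varies on them); what is validated is
ground-truth width recovery on synthetic beats — mean width within 20%
and width-SD recovery at planted jitter.

## The classifier

The random forest is grown by the package itself because its bootstrap
scheme is non-standard: each of B = 300 trees draws only 5% of the
training instances with replacement, then oversamples the minority class
*within that bootstrap* to an exact 50/50 balance (bootstrap first, then
balance — this preserves "5% of the data per tree" while achieving the
balance). Trees are unpruned CART with Gini impurity, choosing from
`ceiling(sqrt(p))` randomly selected features per split. Split thresholds
sit on the left order statistic (rule `x <= thr`) rather than midpoints,
so a tree's decision function depends on feature *order* only and
predictions are exactly invariant under strictly monotone feature
transforms — a tested identity. The positive-vote fraction is the
rearrest likelihood (a multiple of 1/B); the 0.5 tie resolves to the
majority (negative) class.

Out-of-bag (OOB) permutation importance permutes each feature within a
tree's OOB rows and averages the error increase over trees, normalized by
its SD over trees (the classical z-score; the raw mean is also kept).
Features unused by a tree contribute exactly zero and are skipped. The
two-stage procedure trains on all features, ranks by importance (ties to
the lower index), and retrains on the top `Nf`; the default `Nf` keeps all
21 features, since adding features improves both areas in this design.
Missing feature values are imputed by the training-fold median — computed
per fold, never on test patients, so no information leaks.

A univariate cost-sensitive logistic baseline (class weights inversely
proportional to class frequencies) is provided for single-feature
screening.

## Evaluation protocol

Patient-wise stratified 5-fold cross-validation: patients are shuffled
within class and dealt round-robin, so per-fold positive counts differ by
at most one and no patient ever appears in both train and test of a fold
(asserted on every run). The whole partition is repeated (100 times by
default; the tests and the acceptance script use 20 for problem sizes
that keep a full run in minutes), and metrics are aggregated as
median (IQR) over repetitions. Test scores are pooled across the 5 folds
of a repetition before curves are computed; the F1-maximizing threshold
is chosen per repetition on those pooled test scores (the framing under
which a single operating point per repetition is well defined; a
training-side threshold mode would be the conservative alternative and
the threshold is reported so either can be audited). Feature sets
(HRV-only vs. all) are compared with a two-sided Mann–Whitney test on the
per-repetition metric distributions.

The PR area uses a rectangular, right-continuous step rule: each
precision value is carried forward to the next recall level. Three
properties drove this choice over the common average-precision (upper
step) estimator: a constant-score classifier scores exactly the
prevalence; the mean over uniform random score draws sits at the
theoretical chance level (the upper-step rule is optimistic by about two
points at n = 162); and a perfect ranking still scores 100. The
upper-step (`"ap"`) and trapezoid rules remain available as options on
`compute_roc_pr()`.

## The synthetic cohort: what it emulates, and what it does not

RR dynamics are built cumulatively (integral-pulse style): the interval
beginning at beat time t is `mean_rr` plus LF (default 0.10 Hz) and HF
(default 0.30 Hz) sinusoidal modulations, white jitter, and occasional
ectopic perturbations (30% shortening with compensatory lengthening,
which produces the NN50/Poincaré dispersion patterns seen in unstable
rhythms). Sampling the modulation at beat times rather than on a uniform
grid matches how HRV modulations express in real RR series. Defaults
(mean RR 0.6 s; LF/HF amplitudes 0.04 s; jitter 0.06 s; SDNN about
0.07 s) sit at the NoRA medians of the post-ROSC population the pipeline
targets, where patients are typically tachycardic and moderately
variable.

The beat template is a narrow positive Gaussian QRS bump plus a broad low
T bump 250 ms later — analytically integrable, and the QRS width
parameter directly controls v21's ground truth (the template is scaled so
a derivative-threshold delineator recovers approximately the nominal
width). Noise comprises a baseline-wander sinusoid, white noise, and
transient Gaussian spikes; defaults are modest, matching the
high-beat-agreement recordings the method targets.

Rearrest records receive class-effect multipliers. The default — LF/HF
amplitudes ×2.5, jitter ×1.5, QRS-width jitter ×2 — approximately doubles
SDNN while shifting RR variability toward the periodic components, so RA
records show larger v2/v15 *and lower sample entropy*. A uniform
multiplier on all variability components would leave SampEn unchanged
(it is scale-invariant when r tracks the SD), which would contradict the
intended class ordering; the asymmetric default is therefore deliberate.
Per-patient heterogeneity is log-normal around the baseline parameters,
and one master seed spawns per-patient substreams, so cohorts are
reproducible independent of patient order.

What the simulator does not model: 12-lead geometry, dynamical-system
beat morphology, chest-compression artifacts, respiration-coupled
amplitude modulation, or the true (unknown) generative difference between
RA and NoRA hearts. Passing the pipeline's planted-effect tests therefore
shows that the machinery recovers class differences *of the kind
planted*, at realistic sizes and noise levels — it says nothing about
clinical effect sizes, and the simulator's class separation is easier
than the clinical one (cross-validated AUROC near 100 on the default
synthetic effect vs. about 69 reported on real cohorts of this kind).

## Numerical choices and degenerate inputs

Quantiles use linear interpolation between order statistics. Features
that cannot be computed (fewer than 2–3 intervals, zero band power, zero
SD2², no entropy template matches, under 50% of beats delineated) are
returned as `NA` and carried in a per-record missing mask; imputation
happens only inside training folds. Flatline segments yield zero beats
and an empty RR series rather than errors. RR generation redraws jitter
whenever an interval would fall at or below 0.2 s. The Lomb grid starts
at 0.005 Hz, below the LF band, so band integrals never truncate. In the
forest, a single-class bootstrap (possible at 5% sampling) grows a
single-leaf tree rather than being redrawn — such trees vote constantly
and dilute rather than bias the ensemble.

## Problem sizes used in validation

The test suite and `scripts/acceptance.R` validate at the cohort scale
the method targets: 162 patients at prevalence 0.34 (55 positives —
folds then hold exactly 11 positives each), `tw = 1` min for cohort-level
runs, 20 cross-validation repetitions, and 1000 random-score draws for
the chance-level baselines. The planted-effect cohort must reach median
AUROC of at least 80 and the null cohort must stay within 45–55; with 20
repetitions on one 162-patient cohort draw the null median fluctuates by
a few points around 50 across cohort seeds, which is the expected
finite-sample behaviour, not drift.

## Known limitations

The variance-correction scheme, delineation thresholds, and the
secondary detector's low-pass edge are fixed design choices validated on
synthetic ground truth, not re-derived from clinical recordings. The
Lomb normalization targets variance conservation only approximately
(within 20% for well-sampled tones). No powerline notch is provided (the
0.5–40 Hz band excludes mains frequencies), resampling is out of scope
(250 Hz assumed), and probabilities are raw vote fractions, not
calibrated.
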