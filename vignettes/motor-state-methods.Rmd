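---
title: "Methods: spectral motor-sign detection and motor-state classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectral motor-sign detection and motor-state classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wristpd)
```

## The measurement problem

Clinic visits sample a fluctuating disease at a single time point, and
patient motor diaries are burdensome and unreliable over long spans.
`wristpd` implements a continuous, objective alternative: a wrist-worn
tri-axial accelerometer sampled at 50 Hz per channel, analysed entirely in
the frequency domain, with 30-minute motor-state labels (ON, OFF, ON with
non-troublesome or troublesome dyskinesia, daytime/nighttime inactivity,
not worn, not detectable) and 0--4 intensity traces for tremor,
bradykinesia and dyskinesia.

The core idea is that the cardinal motor signs of Parkinson's disease
occupy characteristic frequency bands *and* characteristic movement
patterns. Band power alone cannot separate pathology from daily life --
ordinary activity covers the same 0--20 Hz range -- so each detector
combines a band rule with a pattern gate.

## Pipeline

1. **Epochs.** The recording is cut into contiguous 5 s epochs
   (`segment_epochs()`). The epoch length is a package choice: 5 s holds
   at least 15 tremor cycles at 3 Hz, gives a 0.4 Hz native grid with the
   Welch settings below, and 360 epochs per 30-minute window.
2. **Gravity removal.** A 4th-order Butterworth high-pass at 0.25 Hz is
   applied forward and backward (zero phase, odd-reflection padding).
   The cutoff sits deliberately below the 0.5 Hz lower edge of the
   bradykinesia band.
3. **Spectra.** Per axis, a Welch averaged periodogram: Hann window,
   2.5 s segments, 50% overlap, one-sided density normalisation so the
   integral over (0, 25] Hz approximates the signal variance
   (`compute_epoch_spectrum()`). Band powers are trapezoidal integrals of
   the piecewise-linear PSD, exactly additive across shared band edges.
4. **Combined channel.** The default combined spectrum is the *sum* of
   the three per-axis PSDs -- the spectrum of total gravity-free
   acceleration power. We considered the alternative of taking the PSD of
   the vector-magnitude time series and rejected it as the default: a
   supination--pronation tremor places near-quadrature oscillation on the
   two transverse axes, whose vector magnitude is nearly constant, and
   any single-axis oscillation appears in the magnitude at twice its
   frequency. The summed spectrum peaks at the true frequency, satisfies
   Parseval against the summed axis variances, and is what every detector
   integrates. The magnitude reading remains available as
   `pd_config(spectral = list(combine = "magnitude"))`.

## Detectors

**Tremor** (per epoch): detected when (a) the combined spectrum, searched
over 0.5--12 Hz, peaks inside 3--7 Hz; (b) the supination--pronation gate
passes -- the transverse axes y/z jointly carry at least `rho_axis = 0.6`
of the summed in-band power across axes and their own in-band peaks agree
with the combined peak within `delta_f = 0.5` Hz; and (c) the 3--7 Hz
combined power reaches `theta0`. The gate is a concrete formalisation of
"inter-axis comparison of frequency content": forearm rotation loads the
transverse axes coherently at the tremor frequency, whereas gait
harmonics and single-axis oscillation do not.

**Dyskinesia** (per 30-minute window): an epoch is flagged when *both*
the 1--3 Hz and the 3--8 Hz combined powers exceed their thresholds;
the window is dyskinetic when flagged epochs exceed the majority
`q = 0.5` (overwhelming majority `q_over = 0.75` for the troublesome
state). The dual-band requirement reflects that choreiform movement is
broadband while tremor is narrowband (little 1--3 Hz power) and gait is
low-band (little 3--8 Hz power); the majority requirement makes isolated
tremor or movement bursts irrelevant, in either direction.

**Bradykinesia** (per epoch): only while "upright-active" -- the epoch
mean gravity vector within `alpha_max = 40` degrees of the upright
reference (device x along the forearm, arm hanging) *and* high-passed
vector RMS above a rest floor -- and when the 0.5--3 Hz combined power
lies strictly between `theta_low` (excludes motionless arms) and
`theta_high` (excludes brisk movement). A wrist device cannot observe
trunk posture; the orientation rule is an explicit approximation of
"standing / non-sedentary".

**Wear**: worn when the near-body temperature reaches `t_wear = 30` deg C
or the high-passed RMS reaches a movement floor; without a temperature
channel the movement rule decides alone.

**Intensity maps.** Band power is mapped to the clinical 0--4 scale
piecewise-linearly in `log10(power)` through two anchors (low anchor at
score 0.5, high anchor at 4.0; reversed for bradykinesia, where *less*
residual movement is worse), clipped to [0, 4]. Log-power anchoring was
chosen because acceleration band powers span orders of magnitude and the
map stays monotone and interpretable with two parameters. The dyskinesia
intensity trace is gated by the epoch flag, so ordinary activity reads 0
rather than inheriting a spurious score from its 1--8 Hz power.

## The 30-minute classifier

Deterministic precedence (`classify_window()`): not-worn majority;
troublesome dyskinesia (`fraction >= q_over` and max intensity > 2.5);
non-troublesome dyskinesia (majority, max intensity in (0.5, 2.5] --
exactly 2.5 is non-troublesome); day/night inactivity when fewer than
`a_min = 0.2` of epochs are active, split at a [06:00, 22:00) local-clock
day window; OFF when tremor-plus-bradykinesia epochs predominate
(`> p_off = 0.5`) among active epochs and exceed the dyskinetic fraction;
ON when activity is present with no such predominance and dyskinesia not
impactful (max intensity at most 0.5); otherwise not detectable. The
qualitative words behind `p_off`, `q`, `q_over` and `a_min` have no
published numeric values; the defaults fix them once as configuration.
The interval grid is anchored at the first sample by default;
`snap_to_clock = TRUE` aligns it to :00/:30 for diary comparison.

## Diary comparison and agreement statistics

Diaries use four states on the same grid (Asleep / OFF / ON or ON with
non-troublesome dyskinesia / ON with troublesome dyskinesia). Device
states map onto these (both inactivity states are asleep-equivalent);
intervals where the diary is missing or the device reports not-worn or
not-detectable are excluded. Confusion counts are computed for an OFF
dichotomy and an ON dichotomy (asleep is negative in both) and pooled by
elementwise summation, so each compared interval contributes exactly two
counts. The pooled convention is an inference from the structure of the
published validation table, where row totals equal twice the
diary-covered intervals; the two dichotomies remain separately available
(`mode = "off_dichotomy"` / `"on_dichotomy"`).

Sensitivity, specificity, accuracy and Cohen's kappa follow the standard
2x2 definitions; kappa is evaluated as
`2(TP*TN - FN*FP) / ((TP+FP)(FP+TN) + (TP+FN)(FN+TN))`, algebraically the
classical chance-corrected form. Rates are kept at full precision and
rounded half-up to two decimals only for display; the kappa spread uses
the sample (n-1) standard deviation. Undefined rates (zero denominators)
are errors, never silent zeros.

## The synthetic generator

`simulate_recording()` turns a segment script into a deterministic (per
seed; each segment has its own counter-derived substream) 50 Hz recording
with a 1 Hz temperature channel, a ground-truth timeline (majority
segment kind per interval) and a diary derived from the truth with an
optional error rate. Signal models: tremor is an amplitude-modulated
sinusoid at the scripted frequency placed mainly, and near quadrature, on
the transverse axes over a noise background; dyskinesia is 1--8 Hz
band-limited noise on all axes with mild and severe amplitude tiers
calibrated to land on either side of the 2.5 intensity cutoff;
bradykinesia is low-amplitude 0.5--3 Hz movement in an upright
orientation; normal activity carries a 1.7--2.0 Hz gait fundamental plus
a small harmonic and broadband noise; sleep/rest are near-floor noise
with sparse movement bursts; not-worn is the sensor noise floor with the
temperature relaxing exponentially (tau = 2 min) to a 24 deg C ambient.

All unpublished detector thresholds and anchors were calibrated **once**
against these signal models (`scripts/calibrate.R` prints the band powers
and detection rates per kind) and then frozen in `pd_config()`.

What the generator does *not* emulate -- and therefore what passing tests
do not establish about clinical data: real tremor is non-sinusoidal and
waxes with stress and posture; real dyskinesia is not stationary Gaussian
band noise; gait spectra vary far more than a two-harmonic model;
transitions between states are gradual, not segment-aligned; diaries err
systematically (recall bias), not independently per interval. Synthetic
recovery rates are a correctness check of the pipeline, not a clinical
performance claim.

## Numerical choices and degenerate inputs

Welch segments are demeaned before windowing; the 125-sample segment
grid ends at 24.8 Hz and the half-open top bin extends flat to the 25 Hz
Nyquist so band integrals over (0, 25] are well defined. Peak ties break
toward the lower frequency. Non-finite samples are rejected at the
boundary, or linearly interpolated for gaps up to 0.2 s when requested.
A recording shorter than one epoch yields an empty epoch set; shorter
than one interval, a classification error. Zero-width bands, misordered
thresholds and unknown diary tokens are errors.

Problem sizes used by the shipped tests: single 5 s epochs for detector
properties (100 seeded tremor epochs, 75 negative epochs), 30-minute to
2-hour scripts for window-level behaviour, and ten seeded 24-hour days
for the end-to-end recovery and diary-agreement checks.

## Known limitations

Wrist placement cannot see axial bradykinesia or lower-limb signs; the
posture gate is an orientation proxy; dyskinesia and vigorous exercise
can overlap spectrally, which the majority rule mitigates but cannot
eliminate; intensity anchors are calibrated on synthetic tiers, so on
real devices they require re-calibration against clinical ratings; the
eight-state classifier assumes a fluctuating patient, and for
non-fluctuating patients only the tremor/bradykinesia traces are
meaningful. One acquisition in the shipped validation table is internally
inconsistent as published (its printed rates do not follow from its
printed counts); the counts are kept as published and the discrepancy is
visible in the acceptance checks.
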