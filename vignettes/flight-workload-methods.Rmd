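---
title: "Methods: simulating and analyzing multitasking mental workload"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analyzing multitasking mental workload}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flightload)
```

`flightload` builds, end to end and on fully synthetic data, a
simulated-flight multitasking workload experiment: three 180-s multitasking
runs of increasing load (low = compensatory tracking + a residual-capacity
numeral task; medium adds four meter dashboards; high adds an emergency
red-dot counting task), with weighted NASA-TLX ratings, chest-band RR
intervals, and eight-channel prefrontal fNIRS recorded per run, analyzed by
HRV features, a Beer–Lambert + wavelet + GLM activation chain, and one-way
repeated-measures ANOVA with Bonferroni post-hocs. Because no human data are
distributed, every input is generated by the package itself with known
ground truth; a green test therefore establishes that the *analysis chain
recovers what the generator put in* under the stated world, not that any
human result replicates.

## The operator model and the task engine

The synthetic operator is a single limited resource pool (capacity 1.0)
allocated greedily in a fixed priority order (meters > emergencies >
tracking > residual numerals; primary tasks always outrank the residual
task). Event-driven subtasks request a small idle share for scanning (0.05)
and a large share while a demand is pending (meters 0.8 during a warning,
emergencies 0.6 while dots are shown); tracking requests 0.55 and the
residual task 0.45. Under contention the lower-priority continuous tasks are
part-served, which is the entire mechanism by which load degrades
performance:

* **Tracking** is an Ornstein–Uhlenbeck error process, mean-reverting to
  zero at rate `tracking_gain × share` (default gain 0.45 s⁻¹) with
  diffusion `tracking_noise_sd` (default 19 mm·s⁻½), integrated by
  Euler–Maruyama at 20 Hz; the reported distance is the absolute error.
  With these defaults the stationary mean distance is ≈21.5 mm at low load,
  rising through ≈24 and ≈28 mm as the granted share falls — the magnitude
  range of published tracking tables.
* **Meters** follow deterministic pointer kinematics (speeds 9/12/15/18 °/s,
  30° warning arcs starting at 120/150/180/210°); a correct key press drops
  the pointer immediately, otherwise it falls after traversing the arc.
* **Emergencies** show 10–20 dots for at most 30 s, with a 30-s gap after
  removal.
* **Numerals** complete at hazard `share_residual / numeral_latency_s`
  (latency 0.75 s at full share), so the correct-response count is
  essentially proportional to the time-integral of the residual share —
  the residual-capacity logic made literal.

Response latencies are shifted exponentials truncated at each event window,
correctness is Bernoulli per subtask (meter 0.9, emergency 0.9, numeral
0.95). All subtask streams draw from separate seeds derived from the run
seed, so activating a subtask never perturbs another stream's draws.

**Alarm rule.** Tracking tasks of this kind log an alarm when the distance
exceeds 30 mm, but published protocols rarely state whether counting is
per-sample or per-excursion. Both are implemented on a configurable check grid (default 1 Hz).
The package defaults to **per-check** counting: onset (per-excursion)
counting at 1 Hz caps at 90 alarms per 180 s — below the 72–116 range of
published counts — and, because the error's level and its autocorrelation
move together (crossing rate ∝ √θ·e^(−c²θ/σ²) for an OU process), onset
counts are non-monotone in load exactly in the realistic regime where the
threshold sits 1.1–1.4 stationary SDs out. Per-check counting is monotone in
tracking noise by construction and reproduces the published magnitudes.

## Physiological synthesis

**RR intervals.** The tachogram is sinusoids-plus-noise:
`RR(t) = RR̄(load) + A_LF sin(2π·0.10·t) + A_HF sin(2π·0.25·t + φ) + ε`,
with `RR̄(load) = 60000 / (60000/RR̄₀ + load · slope)` so mean heart rate
rises linearly with load (default slope 1.2 bpm/step on a 67.2-bpm
baseline, matching the ~1–2.5 bpm shifts reported for this kind of
paradigm). Defaults A_LF = A_HF = 25 ms, white SD 25 ms. The spectral
amplitudes carry **no load effect** — deliberately mirroring the common
finding that SDNN/RMSSD/LF-HF are insensitive to load in short
high-workload runs, and giving the null-calibration tests a true null. An
integral-pulse-frequency-modulation generator would be more physiological;
the sinusoidal tachogram was chosen because it gives every HRV feature a
closed-form target.

**fNIRS.** Ground-truth HbO amplitudes per channel are
`β = β₀(subject) + 0.25·load + channel and run scatter` (β₀ ~ N(0.1, 0.1²)
μM); HbR is −1/3 of HbO, the typical anticorrelation. The noise-free series
is `β × (boxcar ⊗ HRF)`; structured noise adds a linear drift
(0.003 μM/s), a 0.1-Hz Mayer wave (0.05 μM), a cardiac sinusoid (0.1 μM at
1.1 Hz, generated explicitly at its 0.9-Hz alias for the 2-Hz sampling
rate), and white noise (0.1 μM), with independently seeded streams and
random phases per channel. Optical densities follow the forward modified
Beer–Lambert law with the shipped Gratzer/Prahl extinction table, 3.5-cm
source–detector distance and DPF 6.0 per wavelength (published analyses
rarely report either; both are configurable), with units arranged so
concentrations are in μM.

## The activation analysis chain

1. **MBLL inversion** solves the per-sample 2×2 system; the configuration
   reports the system's condition number and refuses to invert past 10⁶.
2. **Wavelet denoising** is a periodized sym8 DWT (filter derived by
   spectral factorization and re-verified by tests: orthonormality, perfect
   reconstruction, eight vanishing moments), soft-thresholded at the
   universal threshold σ̂√(2 ln n) with σ̂ the MAD of the finest details,
   default depth ⌊log₂ n⌋ − 4. This replaces the wavelet-MDL detrending of
   NIRS-SPM-style pipelines with a fully specified procedure serving the
   same stated purpose (attenuating high-frequency noise). Soft thresholding slightly shrinks real signal — about
   2–4% attenuation of recovered amplitudes at the default noise level —
   which is why the estimator-recovery tests characterize the GLM with and
   without the denoiser separately.
3. **GLM with HRF precoloring.** The task regressor is the boxcar convolved
   with the canonical double-gamma HRF (peak 6 s, undershoot 16 s, ratio 6).
   The regressor is *peak-normalized* (maximum exactly 1); a unit-area
   kernel would instead put the sustained plateau at 1 with a ~14% transient
   overshoot — the two conventions cannot both hold, and peak normalization
   was chosen so that β is bounded by the peak response. With precoloring
   (default, treating the HRF as a low-pass filter), data and design are
   convolved with the unit-area HRF kernel; residual variance uses the
   Worsley–Friston effective degrees of freedom tr(RV)²/tr(RVRV) and
   coefficient covariance (X'X)⁻¹X'VX(X'X)⁻¹ with V = SS'. These are exact
   under smoothed-white noise; the structured noise terms make them
   approximate, which the coverage tests quantify (≥90% required, ~93–97%
   observed). Each condition is fit as its own run (60-s rests bracketing
   the 180-s block, boxcar over the task period); only HbO enters
   condition-level inference, HbR betas are returned for QC.

## NASA-TLX

Ratings are continuous 0–100 (mapping the instrument's line marks);
own-performance is used as marked with no reverse-coding (protocols often
leave the anchoring direction unstated; a config flag could add it but
defaults to off). Weights are pair-win tallies over the 15 unordered pairs and always
sum to 15; the weighted score is Σ(rating×weight)/15, reported to 2
decimals. Synthetic ratings are affine in load with subject intercepts
(SD 8) and rating noise (SD 6); mental and temporal demand carry the
largest slopes (12 and 14 points/step), so those dimensions drive the
condition differences — the usual signature of time-pressure-driven
multitasking load.

## HRV features

Mean HR is defined as 60000/mean(RR) (not the mean of instantaneous rates);
SDNN uses the sample (n−1) denominator; both choices are documented because
device software rarely states them. Artifact cleaning replaces intervals
jumping >20% from the last *accepted* interval by neighbor interpolation —
comparing to the cleaned value instead would let a sustained artifact
re-baseline the filter within two beats — and errors when >20% of beats
(and at least 3) are flagged. Frequency-domain features use a Lomb–Scargle
periodogram on the beat times (no resampling, hence no interpolation bias),
scaled so the PSD integrates to the series variance over (0, f_Nyquist];
band powers are trapezoidal integrals over half-open bands [0.04, 0.15) and
[0.15, 0.40) Hz so 0.15 Hz is never double-counted. A sinusoid of amplitude
A integrates to ≈A²/2, which the tests use as a closed-form oracle.

## Statistics

The repeated-measures ANOVA is the two-way additive decomposition with
subject as blocking factor, F = MS_condition/MS_(condition×subject) on
(k−1, (k−1)(n−1)) df, unadjusted for sphericity by default. Published
reports of this paradigm sometimes quote F(2, 26) for n = 26, k = 3, where
the standard denominator is (k−1)(n−1) = 50; the package reports the
standard df. The Bonferroni
post-hoc threshold is stored exactly (α/m) and *displayed* truncated to
three decimals (0.05/3 → .016), the truncation convention common in this
literature's tables. Correlations are computed within each condition only between
measure families (subjective, performance, ECG, fNIRS); ECG-internal and
performance-internal pairs are excluded, and no multiplicity correction is
applied to the correlation family, matching common reporting practice for
exploratory cross-measure correlations in this literature.

## The study runner and its stated world

`run_study()` composes all stages for 26 subjects × 3 conditions with
Latin-square counterbalancing, deriving every random stream from the root
seed by string-keyed hashing (`child_seed`), so (a) results are bit-identical
across runs, and (b) perturbing one stage's stream (e.g. the fNIRS noise
salt) leaves all other stages untouched. The null world (`null_effects()`)
zeroes the TLX, HR and β slopes and simulates every run with the low-load
task set under its nominal condition seed, making every measure's ANOVA a
true null for type-I calibration.

What the generator does **not** emulate: learning or fatigue across runs,
order effects (so counterbalancing is verified structurally, not
inferentially), motion artifacts or optode-coupling losses in fNIRS,
ectopic beats (the RR artifact model is a jump model), and any correlation
between a subject's subjective ratings and their physiology beyond shared
load — so observed cross-family correlations under the default world are
genuine small-sample noise, not planted effects.

## Numerical choices and degenerate inputs

* MBLL refuses condition numbers >10⁶ (inversion) or >10¹² (configuration).
* Lomb–Scargle needs ≥60 s of data; time-domain features ≥3 intervals.
* A zero-duration event list yields a nuisance-only design, flagged rather
  than silently fit; rank deficiency names the dependent columns.
* Zero error variance in the ANOVA reports the boundary (F = 0/p = 1 or
  F = ∞/p = 0) with a warning; exact-tie post-hoc pairs report t = 0, p = 1.
* An HF band power of exactly zero reports LF/HF as `NA`, never infinity.
* All scores are computed in double precision; the TLX score is rounded
  only at the final reporting step.

## Known limitations

The operator model is a single-pool abstraction of multiple-resource
theory; it reproduces the qualitative load pattern but its parameters
(demands, latencies) are design choices, not fitted quantities. The
denoiser's amplitude shrinkage biases recovered β by a few percent at
default noise — acceptable for condition contrasts (which it affects
symmetrically) but worth remembering for absolute amplitude claims. The
precoloring variance formula ignores residual structured noise; coverage
stays above 90% at default noise levels but would degrade for much larger
Mayer-wave amplitudes.
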