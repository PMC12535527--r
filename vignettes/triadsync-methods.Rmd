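---
title: "Measuring HRV synchrony in a therapy triad: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring HRV synchrony in a therapy triad}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triadsync)
```

## The problem

During horse-assisted therapy a participant, a riding therapist and a
therapy horse interact for about an hour. Each has a beating heart whose
beat-to-beat variability (HRV) is shaped by the autonomic nervous system:
the high-frequency (HF, >= 0.15 Hz) component of HRV is driven by
respiration through the vagus nerve and indexes parasympathetic activity.
When two individuals relax together, their HF rhythms can align —
physiological synchrony. `triadsync` measures that alignment from raw
RR-interval logs and tests what predicts it with hierarchical mixed
models: does horse–therapist synchrony transfer to the participant's
dyads, does a therapist's favorite horse matter, and does early-life
adversity (ELA, measured by the Childhood Trauma Questionnaire, CTQ)
attenuate human–human but not human–horse coupling?

The pipeline has four stages — synthetic data generation, RR cleaning,
cross-wavelet spectral analysis, and mixed-model inference — each usable
on its own. Because raw recordings of this kind are not shipped with the
package, a generator with known ground truth stands in for them, so every
stage can be validated against what was actually simulated.

## Cleaning raw RR series

Chest-belt RR logs contain double entries, spikes (missed or doubly
detected beats) and dropouts. Cleaning proceeds in the order the
artifacts demand:

1. **Duplicates** — rows with identical timestamps are collapsed
   (`remove_duplicates()`).
2. **Outliers** — a beat is flagged when its RR deviates from the running
   median of an 11-beat neighbourhood by strictly more than a relative
   threshold, constrained to the range 20–50% (default 0.30, the
   middle of the physiologically defensible range), or when it leaves
   absolute species bounds (300–2000 ms for humans, 500–4000 ms for
   horses). The threshold comparison is strict: a deviation exactly at
   the threshold is kept.
3. **Gaps** — deleted or missing beats leave holes. Holes up to 2 s are
   bridged by beats whose RR interpolates linearly between the flanking
   RR values (midpoint convention: a 1.6 s hole between an 800 and an
   820 ms beat receives two beats of about 805 and 815 ms). Longer holes
   follow a linear trend fitted to 10 s of real data on each side,
   rescaled so inserted time equals the hole exactly. Inserted beats are
   flagged `interpolated` and enter downstream analyses like any other —
   they restore the time base rather than invent variability.

Horse recordings are much more artifact-laden (belt shift, thick skin,
pad interference), so `clean_equine()` iterates
detect–delete–interpolate until a pass flags nothing, keeping a per-pass
audit log. The iteration replaces manual inspection with a reproducible
loop; if any pass flags more than half of the beats the recording is
declared unusable rather than silently repaired. `rmssd()` supplies the
baseline vagal-tone covariate (root mean square of successive
differences) over the same four-minute window used for the synchrony
measurements.

## Cross-wavelet synchrony

The cleaned series are resampled to uniform 4 Hz tachograms by cubic
spline (Nyquist 2 Hz comfortably covers all HRV bands), mean-removed and
variance-normalised, and transformed with the analytic Morlet wavelet
(`omega0 = 6`, 12 scale steps per octave, smallest scale twice the
sampling step, periods up to a quarter of the window). The
cross-wavelet transform of two series is `W_xy = W_x * Conj(W_y)`; its
modulus is cross-wavelet power (co-occurring oscillation strength at a
given time and period) and its argument is the relative phase
(rightward arrows on the standard plot = in-phase). The Fourier period
of scale `s` is `4*pi*s/(omega0 + sqrt(2 + omega0^2))` and the
e-folding time `sqrt(2)*s` defines the cone of influence within which
edge effects matter.

Pointwise significance compares each cell's power against the product
of the two series' theoretical AR(1) spectra (lag-1 autocorrelations
estimated from the data). For the modulus of the cross spectrum of two
independent chi-squared (2 df) powers, the background quantile solves
`z * K1(z) = alpha` with the modified Bessel function `K1` — at
`alpha = 0.05` this gives `z = 3.9995`, and the cell threshold is
`(z/2) * sqrt(P_x(f) P_y(f))`. A Monte-Carlo alternative with matched
AR(1) surrogates is provided for checking the analytic background. The
calibration of this test under the null is itself a tested property of
the package (the empirical flag fraction must sit near the nominal
level).

HRV is partitioned by frequency `f = 1/period` into four bands — LLF
`[0.04, 0.0775)`, ULF `[0.0775, 0.15)`, LHF `[0.15, 0.245)`, UHF
`[0.245, 0.40)` Hz, half-open like every interval in the package. Only
the HF edge (0.15 Hz, period 6.67 s) is anchored in the HRV standards;
the sub-band splits are geometric midpoints of the conventional HF and
LF bands, exposed as configuration. The analysis uses one common band
grid for both species: equine HF band limits are not standardised, and
a common grid is the only way cross-species HF power is comparable.

Synchrony measurements are taken over the first 240 s of the *lying*
segment (the participant prone on the horse's back — the stationary,
parasympathetically dominated part of the session): 4 minutes x 6
ten-second intervals x 2 HF bands, the mean power over in-cone cells of
each chunk. Cells outside the cone are dropped, not zero-filled,
otherwise the first and last intervals would be biased; intervals losing
more than half their cells are flagged. The significance mask is
reported but never gates extraction. Because wavelet power is strongly
right-skewed, measurements are log-transformed and z-scored with the
sample standard deviation within each dyad type. Z-scoring within
dyad x session was considered and rejected: it removes all
between-participant variance and would make any between-participant
predictor (CTQ, group) structurally untestable, so the default stratum
pools across sessions; the session stratum remains available as a
configuration switch.

## The synthetic triad generator

The generator produces RR series with known coupling so the whole chain
can be validated. Each subject's pacemaker is an integral pulse
frequency modulation (IPFM) model: a beat fires whenever the integral of
`(mean_hr/60) * m(t)` crosses the next integer. The modulator is

```
m_i(t) = 1 + hf_amp * HF_i(t) + lf_amp * LF_i(t) + noise
```

with unit-variance narrowband Gaussian oscillations as components.
Coupling is a shared-variance construction: dyad `d`'s members receive
`sqrt(kappa_d) * S_d(t)` of a common HF oscillator plus
`sqrt(1 - kappa_d)` of their own, so the HF correlation of a dyad equals
its `kappa` exactly, and `kappa` is the ground-truth coupling knob that
downstream estimates are judged against. In the triad, each subject
carries the weights of both dyads it belongs to (rescaled if their sum
would exceed 1).

Defaults encode resting physiology: humans 70 bpm with individual
respiratory frequencies drawn from 0.18–0.33 Hz, horses 38 bpm with
0.08–0.12 Hz; HF modulation depth 0.08, LF 0.04 (RR fluctuations of a
few percent, as in calm adults). Two choices deserve explanation
because they are what makes modulus cross power respond to coupling at
all:

* **Dyad-specific coupling frequencies** (0.30, 0.20, 0.37 Hz for
  horse–participant, therapist–participant, horse–therapist). Modulus
  cross power is an amplitude-overlap measure, not a coherence: two
  same-species subjects have unit HF variance wherever their rhythms
  sit, so if every coupling shared one frequency, a subject's coupling
  to the horse would be spectrally indistinguishable from coupling to
  the therapist. Giving each dyad its own rhythm inside the HF band
  keeps the three couplings separable — physiologically, each pair
  entrains on its own common rhythm.
* **Individual uncoupled rhythms.** Each subject's own respiratory
  frequency is drawn per session from the species range, so an
  uncoupled pair rarely oscillates at the same frequency; coupling
  moves spectral mass onto the dyad's common rhythm, which is exactly
  what the band-wise cross power detects.

During lying, the horse–participant kappa receives a +0.2 proximity
boost (lying on the horse intensifies contact). Artifact injection
(multiplicative spikes, duplicate rows, dropout windows) is configured
per role, horses worst, and returns ground-truth masks so the cleaning
stage can be scored. Cohort generation mirrors the emulated study
design: 56 controls with one session, 36 patients with four, three
therapists (each with a favorite among four horses), CTQ subscales 5–25
summing to totals in 25–125, patients spanning the full severity range.
Coupling depends on adversity linearly:
`kappa = base + effect * (CTQ_total - 25)/100`, clipped to `[0, 1]`,
with no extra noise by default so ground truth is an exact function of
CTQ. All randomness descends from one master seed through a documented
hierarchical derivation (`derive_seed()`), making cohorts bit-identical
under the same seed.

What the generator does **not** emulate: riding-motion artifacts,
respiration traces, electrode physics, circadian or menstrual-cycle
effects, and any nonstationarity of coupling beyond the lying boost.
Passing tests therefore show that the *pipeline* recovers the structure
this model encodes — not that real horse–human dyads behave like the
model.

## The model ladder

The band-power table has a strict hierarchy: 10-s intervals in minutes
in sessions in participants (or therapists). `fit_mlm()` fits Gaussian
mixed models by maximum likelihood through `lme4` (ML, not REML,
because the ladder compares models differing in fixed effects), with
Wald normal-approximation confidence intervals — within-group sample
sizes here are in the thousands, so a finite-df correction would change
nothing material. Ladders start from a random-intercept null model and
add design terms (minute, interval, band, session where more than one
exists, interactions), covariates, and the substantive predictors
(other-dyad synchrony aligned row-wise by the hierarchical key,
favorite-horse flag, CTQ scores); each rung is kept only if the
likelihood-ratio test against the current best model is significant at
the predetermined 5% level. Random-slope structures fall back to random
intercepts when the fit is singular, and the fallback is recorded on
the fit object rather than silently accepted. Variance-partition R²
follows the standard mixed-model decomposition: the marginal value is
`var_fixed / (var_fixed + var_random + var_residual)` with `var_fixed`
the variance of the fixed-effect predictor and `var_random` the mean
per-observation random-effect variance; the conditional value adds the
random variance to the numerator.

`assumption_checks()` turns the usual visual diagnostics into numbers:
residual skewness/kurtosis and a Shapiro–Wilk statistic on a capped
subsample, a Brown–Forsythe statistic across fitted-value bins,
variance-inflation factors with aliasing detection, and an extreme
standardized-residual count. The report is advisory — these models are
robust to mild violations and no analysis is blocked on it. No
multiple-testing correction is applied across CTQ subscales; each
subscale is tested in its own model, and the report says so.

## Numerical conventions and degenerate inputs

* All intervals are half-open: time `[start, end)`, frequency bands
  `[low, high)`.
* The outlier threshold uses strict inequality.
* A z-scoring stratum with zero spread maps to all-zero scores rather
  than dividing by zero.
* Cross-wavelet grids must match exactly; mismatched transforms are an
  error, not a resample.
* A gap at the recording edge with no flanking data is left unfilled
  and reported, never extrapolated from one side.
* Likelihood-ratio chi-squares are floored at zero (boundary fits can
  produce tiny negative differences); comparing a model with itself
  gives chi2 = 0, p = 1.
* Non-convergent fits halt a ladder with partial results; singular
  (boundary) fits are converged-but-degenerate and are kept, with the
  slope-to-intercept fallback logged.

## Problem sizes used in the validation suite

The package's validation experiments are sized for a desk machine: the
significance calibration uses 200 surrogate pairs of 240 s at 4 Hz;
coupling monotonicity averages 20 seeds per kappa on single-triad
sessions with a compressed timeline (full 5-minute lying segment, short
surrounding segments); fixed-effect recovery uses 100 replicates of 40
groups x 48 observations; type-I control of the ladder step uses 500
one-df replicates at 24 groups x 12 observations; and the end-to-end
adversity experiment uses 25 replicate cohorts of 36 patients x 4
sessions with a -0.3 CTQ-to-kappa slope on the therapist dyad and none
on the horse dyad. The emulated study's full design (56 controls, 36
patients, hour-long timelines) remains the generator default for
interactive use.

## Known limitations

* Modulus cross-wavelet power conflates amplitude co-variation with
  synchrony; it cannot separate phase-locking from simultaneous
  loudness. Wavelet coherence would, but the measure implemented here
  is deliberately the plain cross power, with phase statistics reported
  alongside.
* The analytic significance background assumes AR(1) spectra and
  chi-squared distributed wavelet power; both are approximations at
  coarse scales, where few independent samples exist in a 240 s window.
* The equine cleaning loop is automatic; genuinely pathological
  recordings that a human would reject on sight are caught only by the
  50% rule.
* Tables produced from one-session cohorts omit session terms
  automatically; comparisons across cohorts of different designs should
  use identical ladders.
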