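# triadsync

Heart-rate-variability (HRV) synchrony analysis for human–horse therapy
triads.

During horse-assisted therapy, the beat-to-beat heart rhythms of the
participant, the riding therapist and the therapy horse can align —
physiological synchrony, carried mostly by the high-frequency
(respiratory, parasympathetic) component of HRV. `triadsync` implements
the full measurement chain from raw RR-interval logs to inferential
statistics:

* **RR cleaning** — duplicate collapse, running-median outlier
  detection with a 20–50% relative threshold, short-gap bridging and
  long-gap trend interpolation, and an iterative artifact pass for the
  much noisier equine recordings (`clean_rr()`, `clean_equine()`,
  `rmssd()`).
* **Cross-wavelet spectra** — cubic-spline tachogram resampling at
  4 Hz, analytic Morlet continuous wavelet transform, cross-wavelet
  power `|W_x conj(W_y)|` with phase, cone of influence, and pointwise
  red-noise significance: cell power is tested against
  `(z/2) sqrt(P_x(f) P_y(f))` where `z` solves `z K1(z) = alpha` and
  `P` are the AR(1) spectra of the two series (`cwt_morlet()`,
  `cross_wavelet()`, `xwt_significance()`, `plot()`).
* **Synchrony extraction** — mean cross power per 10-second interval
  over the first four minutes of the *lying* segment, split into lower
  and upper HF bands (LHF 0.15–0.245 Hz, UHF 0.245–0.40 Hz; the HF
  edge at 0.15 Hz is the 6.67 s wavelet period), log-transformed and
  z-scored within dyad (`extract_interval_power()`,
  `ztransform_power()`).
* **Hierarchical models** — maximum-likelihood mixed models on the
  interval table (10-s intervals in minutes in sessions in subjects)
  compared by likelihood-ratio ladders at alpha 0.05, with Nakagawa
  marginal/conditional R², Wald CIs and numeric assumption checks
  (`fit_mlm()`, `model_ladder()`, `r2_nakagawa()`,
  `assumption_checks()`).
* **Synthetic triads** — an integral-pulse-frequency-modulation cardiac
  generator with shared-variance HF coupling (`kappa` per dyad is the
  ground-truth coupling), species-specific physiology, CTQ-linked
  coupling effects and artifact injection, so every stage above is
  testable against known truth (`generate_cohort()`,
  `generate_triad_session()`, `ipfm_beats()`, `inject_artifacts()`).

## Worked example

```r
library(triadsync)

# a cohort of 2 controls (1 session) and 2 patients (2 sessions each),
# with adversity attenuating therapist-participant coupling
cc <- cohort_config(n_control = 2, n_patient = 2, sessions_per_patient = 2,
                    ctq_effect_therapist = -0.3, seed = 42)
cohort <- generate_cohort(cc, timeline = demo_timeline())
table <- process_cohort(cohort)          # clean -> resample -> XWT -> extract
print(dim(table))
#> [1] 864  27

# one session in detail, with significance contours and phase arrows
bp <- process_session(cohort$sessions[[1]], significance = "analytic",
                      keep_xwt = TRUE)
plot(attr(bp, "xwt")[["horse-participant"]])

# the standard model ladder for each dyadic response
ladders <- standard_ladders(table)
ladders[["therapist-participant"]]
#> <hrv_ladder> 3 models, best = 'transfer' (alpha = 0.05)
#>     model npar loglik   aic   chi2 df         p kept
#>      null    3 -408.2 822.3     NA NA        NA TRUE
#>    design   28 -365.3 786.6  85.73 25 1.404e-08 TRUE
#>  transfer   29 -290.5 639.1 149.49  1 2.236e-34 TRUE
```

The ladder output reads like the analysis it encodes: adding the
design factors improves on the null model, and adding horse–therapist
synchrony as a row-wise predictor of therapist–participant synchrony
improves the fit again (the synchrony-transfer effect), with estimates,
CIs and marginal/conditional R² available via
`ladders[["therapist-participant"]]$best_fit`.

A thin command-line wrapper drives the same pipeline:

```sh
Rscript inst/cli/triadsync.R all --seed 7 --outdir out/
```

writes RR logs, the cohort metadata, the band-power table, ladder and
estimate CSVs, and a plain-text report, and is byte-reproducible for a
fixed seed and config.

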