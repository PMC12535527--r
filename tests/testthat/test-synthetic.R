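# synthetic triad generator: modulators, IPFM beats, artifacts, cohort

test_that("shared-variance coupling gives the expected HF correlation", {
  # full sharing: the two HF components are the same series
  md <- generate_modulators(coupling_config(kappa = 1, noise_sd = 0, seed = 4))
  expect_equal(md$hf[, 1], md$hf[, 2])

  # no sharing: sample correlation near zero for a long record
  md0 <- generate_modulators(coupling_config(duration_s = 1200, kappa = 0,
                                             seed = 5))
  expect_lt(abs(cor(md0$hf[, 1], md0$hf[, 2])), 0.25)

  # kappa = 0.5: Monte-Carlo oracle; expected correlation is kappa
  # because each member is sqrt(k)*S + sqrt(1-k)*O with unit variances
  cors <- vapply(1:50, function(s) {
    m <- generate_modulators(coupling_config(duration_s = 600, kappa = 0.5,
                                             seed = s))
    cor(m$hf[, 1], m$hf[, 2])
  }, numeric(1))
  expect_lt(abs(mean(cors) - 0.5), 0.1)
})

test_that("modulator invariants and input validation hold", {
  expect_error(coupling_config(kappa = 1.2), "kappa")
  expect_error(coupling_config(mean_hr = -1), "mean_hr")
  expect_error(coupling_config(hf_freq = 0.05, lf_freq = 0.08), "hf_freq")
  expect_error(generate_modulators(coupling_config(), sample_rate = 2),
               "sample_rate")
  md <- generate_modulators(coupling_config(seed = 7))
  expect_true(all(md$m > 0))
  # determinism under a fixed seed
  md2 <- generate_modulators(coupling_config(seed = 7))
  expect_identical(md$m, md2$m)
})

test_that("IPFM emits metronome beats for a constant modulator", {
  t <- seq(0, 300, by = 0.125)
  s60 <- ipfm_beats(t, rep(1, length(t)), 60)
  expect_equal(unique(round(s60$rr, 9)), 1000)
  expect_equal(s60$beat_time, seq_len(nrow(s60)))
  s40 <- ipfm_beats(t, rep(1, length(t)), 40, role = "horse")
  expect_equal(unique(round(s40$rr, 9)), 1500)
  expect_error(ipfm_beats(t, rep(1, length(t)), -5), "mean_hr")
  expect_error(ipfm_beats(t, rep(0, length(t)), 60), "positive")
})

test_that("IPFM beat count matches a numerical-integration oracle", {
  # oracle: count integer crossings of the integrated rate on a fine grid
  t <- seq(0, 300, by = 1 / 256)
  m <- 1 + 0.1 * sin(2 * pi * 0.25 * t)
  rate <- m / 1  # mean_hr 60 -> one beat per second at m = 1
  cum <- cumsum(c(0, diff(t) * (rate[-length(rate)] + rate[-1]) / 2))
  oracle_beats <- floor(cum[length(cum)])

  tg <- seq(0, 300, by = 0.125)
  s <- ipfm_beats(tg, 1 + 0.1 * sin(2 * pi * 0.25 * tg), 60)
  expect_lte(abs(nrow(s) - oracle_beats), 1)
  # mean RR close to 60000/mean_hr
  expect_lt(abs(mean(s$rr) - 1000) / 1000, 0.02)
})

test_that("generated RR series has mean RR near 60000/mean_hr", {
  for (hr in c(38, 70)) {
    cfg <- coupling_config(duration_s = 300, mean_hr = hr,
                           hf_freq = if (hr < 50) 0.1 else 0.25,
                           lf_freq = 0.04, seed = 11)
    md <- generate_modulators(cfg)
    s <- ipfm_beats(md$t, md$m[, 1], hr)
    expect_lt(abs(mean(s$rr) - 60000 / hr) / (60000 / hr), 0.02)
  }
})

test_that("tachogram spectral peak sits at the HF modulator frequency", {
  cfg <- coupling_config(duration_s = 600, mean_hr = 70, hf_freq = 0.25,
                         lf_freq = 0.08, hf_amp = 0.1, lf_amp = 0,
                         noise_sd = 0, seed = 3)
  md <- generate_modulators(cfg)
  s <- ipfm_beats(md$t, md$m[, 1], 70)
  tach <- resample_ibi(s, fs = 4, window = c(5, 581))
  sp <- stats::spec.pgram(stats::ts(tach$ibi, frequency = 4), plot = FALSE,
                          taper = 0, detrend = TRUE, spans = 3)
  peak_f <- sp$freq[which.max(sp$spec)]
  expect_lt(abs(peak_f - 0.25), 0.02)
})

test_that("artifact injection is faithful to its ground-truth mask", {
  s <- constant_series(800, 400)
  # identity when nothing is injected
  out0 <- inject_artifacts(s, 0, 0, list(), seed = 1)
  expect_equal(rr_df(out0$series), rr_df(s))

  # gap construction: no beats inside the window
  outg <- inject_artifacts(s, 0, 0, list(c(100, 1.5)), seed = 1)
  expect_false(any(outg$series$beat_time > 100 &
                     outg$series$beat_time < 101.5))
  expect_equal(outg$n_removed,
               sum(s$beat_time > 100 & s$beat_time < 101.5))

  # spike count equals an independent replay of the generator draw
  outs <- inject_artifacts(s, spike_rate = 2, duplicate_rate = 0,
                           gap_spec = list(), seed = 42)
  dur_min <- (max(s$beat_time) - min(s$beat_time)) / 60
  replay <- withr_seed(42, stats::rpois(1, 2 * dur_min))
  expect_equal(length(outs$spiked_time), min(replay, nrow(s)))

  expect_error(inject_artifacts(s, gap_spec = list(c(1e6, 1))), "gap")
})

test_that("cohort kappas are an exact function of CTQ before clipping", {
  cc <- cohort_config(n_control = 0, n_patient = 40,
                      ctq_effect_therapist = -0.3, ctq_effect_horse = 0,
                      seed = 9)
  coh <- generate_cohort(cc, simulate = FALSE)
  p <- coh$participants[coh$participants$session_index == 1, ]
  resc <- (p$ctq_total - 25) / 100
  fit <- stats::lm(p$kappa_tp ~ resc)
  expect_equal(unname(coef(fit)[2]), -0.3, tolerance = 1e-10)
  # null effect: slope exactly 0
  coh0 <- generate_cohort(cohort_config(n_control = 0, n_patient = 40,
                                        seed = 9), simulate = FALSE)
  p0 <- coh0$participants[coh0$participants$session_index == 1, ]
  expect_equal(stats::sd(p0$kappa_tp), 0)
  # CTQ structure: subscales in range, total consistent
  expect_true(all(p[triadsync:::ctq_subscales] >= 5 &
                    p[triadsync:::ctq_subscales] <= 25))
  expect_equal(p$ctq_total,
               as.integer(rowSums(p[triadsync:::ctq_subscales])))
})

test_that("cohorts are bit-identical under identical seeds", {
  cc <- cohort_config(n_control = 1, n_patient = 1,
                      sessions_per_patient = 1, seed = 13)
  a <- generate_cohort(cc, timeline = demo_timeline(lying_s = 250))
  b <- generate_cohort(cc, timeline = demo_timeline(lying_s = 250))
  expect_identical(a$participants, b$participants)
  expect_identical(lapply(a$sessions, function(s) s$series),
                   lapply(b$sessions, function(s) s$series))
})

test_that("triad sessions honour the timeline and role configuration", {
  tl <- demo_timeline()
  ses <- generate_triad_session(kappa = list(hp = .3, tp = .3, ht = .3),
                                timeline = tl, seed = 2)
  for (role in c("participant", "therapist", "horse")) {
    s <- ses$series[[role]]
    expect_lt(max(s$beat_time), timeline_duration(tl) + 2)
    expect_equal(attr(s, "role"), role)
  }
  # horse beats much sparser than human beats
  expect_lt(nrow(ses$series$horse), 0.7 * nrow(ses$series$participant))
  expect_error(generate_triad_session(kappa = list(hp = .3, tp = .3),
                                      seed = 1), "ht")
  expect_error(generate_triad_session(kappa = list(hp = 2, tp = .3, ht = 0),
                                      seed = 1), "0, 1")
})
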