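# Morlet CWT, cross-wavelet, significance, bands, extraction, phase

test_that("Fourier period per scale matches the closed form", {
  # omega0 = 6: lambda/s = 4*pi/(6 + sqrt(38)) ~ 1.0330
  tach <- sinusoid_tachogram(8)
  cw <- cwt_morlet(tach)
  expect_equal(cw$period / cw$scale,
               rep(4 * pi / (6 + sqrt(2 + 36)), length(cw$scale)))
  expect_equal(round(cw$period[1] / cw$scale[1], 4), 1.0330)
})

test_that("zero signal yields zero coefficients", {
  cw <- cwt_morlet(make_tachogram(rep(0, 512)))
  expect_true(all(Mod(cw$W) == 0))
})

test_that("a sinusoid's power peaks at its period, within one dj step", {
  for (p0 in c(4, 8, 16)) {
    cw <- cwt_morlet(sinusoid_tachogram(p0, dur_s = 256))
    peak <- cw$period[which.max(rowMeans(Mod(cw$W)^2))]
    expect_lt(abs(log2(peak / p0)), 1 / 12 + 1e-9)
  }
})

test_that("CWT agrees with direct time-domain convolution", {
  # oracle: explicit convolution with the analytic Morlet wavelet at a
  # few scales, evaluated mid-series where edge effects vanish
  tach <- sinusoid_tachogram(8, dur_s = 128)
  cfg <- cwt_config()
  cw <- cwt_morlet(tach, cfg)
  dt <- 1 / tach$fs
  x <- tach$ibi - mean(tach$ibi)
  x <- x / stats::sd(x)
  n <- length(x)
  mid <- seq(n %/% 2 - 10, n %/% 2 + 10)
  for (j in round(seq(10, length(cw$scale) - 5, length.out = 5))) {
    s <- cw$scale[j]
    for (i in mid[c(1, 11, 21)]) {
      eta <- ((seq_len(n) - i) * dt) / s
      psi0 <- pi^(-1 / 4) * exp(1i * 6 * eta) * exp(-eta^2 / 2)
      w_direct <- sqrt(dt / s) * sum(x * Conj(psi0))
      expect_equal(w_direct, cw$W[j, i], tolerance = 0.02)
    }
  }
})

test_that("self-cross power is the wavelet power, phase identically zero", {
  cw <- cwt_morlet(sinusoid_tachogram(8))
  xw <- cross_wavelet(cw, cw)
  expect_equal(xw$power, Mod(cw$W)^2)
  expect_true(all(abs(xw$phase) < 1e-12))
})

test_that("swapping inputs preserves power and negates phase", {
  ta <- sinusoid_tachogram(8, phase = 0)
  tb <- sinusoid_tachogram(8, phase = pi / 3)
  ca <- cwt_morlet(ta); cb <- cwt_morlet(tb)
  ab <- cross_wavelet(ca, cb); ba <- cross_wavelet(cb, ca)
  expect_equal(ab$power, ba$power)
  expect_equal(ab$phase, -ba$phase, tolerance = 1e-12)
  # and the significance mask is unchanged under the swap
  expect_equal(xwt_significance(ab)$sig_mask, xwt_significance(ba)$sig_mask)
})

test_that("a quarter-period lag shows up as pi/2 mean phase", {
  # second series lags by 2 s at period 8 s
  ta <- sinusoid_tachogram(8, phase = 0)
  tb <- sinusoid_tachogram(8, phase = -2 / 8 * 2 * pi)
  xw <- cross_wavelet(cwt_morlet(ta), cwt_morlet(tb))
  j <- which.min(abs(xw$period - 8))
  keep <- xw$coi >= 8
  expect_equal(mean(xw$phase[j, keep]), pi / 2, tolerance = 0.05)

  ps <- phase_stats(xw, "UHF", bands = frequency_bands(hf_split = 0.1,
                                                       hf_low = 0.05,
                                                       lf_split = 0.04,
                                                       lf_low = 0.03,
                                                       hf_high = 0.2))
  expect_equal(ps$mean_phase, pi / 2, tolerance = 0.1)
  expect_gt(ps$concentration, 0.9)
})

test_that("anti-phase and in-phase signals give the expected phase stats", {
  ta <- sinusoid_tachogram(6, phase = 0, dur_s = 240)
  xw_self <- cross_wavelet(cwt_morlet(ta), cwt_morlet(ta))
  ps <- phase_stats(xw_self, "LHF")
  expect_equal(ps$mean_phase, 0)
  expect_equal(ps$concentration, 1)

  tb <- sinusoid_tachogram(6, phase = pi, dur_s = 240)
  xw <- cross_wavelet(cwt_morlet(ta), cwt_morlet(tb))
  j <- which.min(abs(xw$period - 6))
  keep <- xw$coi >= 6
  circ_mean <- Arg(mean(exp(1i * xw$phase[j, keep])))
  expect_equal(abs(circ_mean), pi, tolerance = 0.05)
})

test_that("analytic significance is trivial at alpha 1 and strict at 0", {
  withr_seed(21, {
    tx <- make_tachogram(ar1_sim(480, 0.7))
    ty <- make_tachogram(ar1_sim(480, 0.7))
  })
  xw <- cross_wavelet(cwt_morlet(tx), cwt_morlet(ty))
  expect_true(all(xwt_significance(xw, alpha = 1)$sig_mask))
  # montecarlo with alpha = 0 takes the surrogate maximum: nothing
  # should exceed it on null data (tiny surrogate count for speed)
  withr_seed(22, {
    xw0 <- xwt_significance(xw, alpha = 0, method = "montecarlo",
                            n_surrogates = 20)
  })
  inside <- outer(xw0$period, xw0$coi, `<=`)
  expect_lt(mean(xw0$sig_mask[inside]), 0.02)
  xw$ar1_x <- 1
  expect_error(xwt_significance(xw), "ar1")
})

test_that("band partition maps the HF edge and examples correctly", {
  # 0.15 Hz <-> 6.67 s is the HF lower edge
  expect_equal(band_partition(c(6.6, 6.8)), c("LHF", "ULF"))
  expect_equal(band_partition(3.0), "UHF")     # 0.333 Hz >= 0.245 split
  expect_equal(band_partition(30), "out")      # 0.033 Hz below lf_low
  expect_equal(band_partition(1 / 0.15), "LHF")  # boundary is half-open
  expect_equal(band_partition(c(10, 20)), c("ULF", "LLF"))
  expect_error(frequency_bands(hf_low = 0.5), "increasing")
})

test_that("interval extraction yields 24 rows per band with correct means", {
  tl <- demo_timeline()
  lying <- tl[tl$segment == "lying", ]
  ses <- generate_triad_session(kappa = list(hp = .4, tp = .4, ht = .4),
                                timeline = tl, seed = 31, artifacts = FALSE)
  bp <- process_session(ses)
  for (d in unique(bp$dyad)) {
    expect_equal(sum(bp$dyad == d & bp$band == "LHF"), 24)
    expect_equal(sum(bp$dyad == d & bp$band == "UHF"), 24)
  }

  # constant power field: every interval mean equals the constant
  cw <- cwt_morlet(make_tachogram(rep(0, 4 * 300), t0 = lying$start_s - 20))
  xw <- cross_wavelet(cw, cw)
  xw$power[] <- 3.14
  rows <- extract_interval_power(xw, tl)
  expect_true(all(abs(rows$power - 3.14) < 1e-12))
  expect_true(all(rows$minute %in% 1:4) && all(rows$interval %in% 1:6))
  # a short lying segment is rejected
  expect_error(demo_timeline(lying_s = 100), "240")
})

test_that("z-transform has the documented moments and conventions", {
  rows <- data.frame(dyad = rep(c("a", "b"), each = 6),
                     power = exp(c(1:6 / 2, rep(2, 6))))
  z <- ztransform_power(rows, stratum = "dyad")
  za <- z$cwp_z[z$dyad == "a"]
  expect_equal(mean(za), 0, tolerance = 1e-12)
  expect_equal(stats::sd(za), 1, tolerance = 1e-12)
  # zero-spread stratum maps to all zeros
  expect_true(all(z$cwp_z[z$dyad == "b"] == 0))
  # two-row stratum under the sample-sd convention
  two <- ztransform_power(data.frame(power = exp(c(1, 3))), stratum = NULL)
  expect_equal(two$cwp_z, c(-1, 1) / sqrt(2), tolerance = 1e-12)
  expect_equal(round(two$cwp_z, 4), c(-0.7071, 0.7071))
  expect_error(ztransform_power(data.frame(power = c(-1, 2))), "positive")
})

test_that("resampling matches the expected grid and spline oracle", {
  s <- constant_series(1000, 300)
  tach <- resample_ibi(s, fs = 4, window = c(10, 250))
  expect_equal(length(tach$ibi), 960)
  expect_true(all(abs(tach$ibi - 1000) < 1e-9))

  # alternating 990/1010 at 1 Hz beats oscillates at 0.5 Hz; compare
  # against a direct spline evaluation on the same knots
  rr <- rep(c(990, 1010), 150)
  bt <- cumsum(rr) / 1000
  s2 <- rr_series(bt, rr)
  tach2 <- resample_ibi(s2, fs = 4, window = c(20, 260))
  knots <- bt >= 15 & bt < 265   # the documented 5 s margin
  oracle <- stats::spline(bt[knots], rr[knots], xout = tach2$t,
                          method = "fmm")$y
  expect_equal(tach2$ibi, oracle, tolerance = 1e-9)
  sp <- stats::spec.pgram(stats::ts(tach2$ibi, frequency = 4), plot = FALSE,
                          taper = 0, detrend = TRUE)
  expect_lt(abs(sp$freq[which.max(sp$spec)] - 0.5), 0.02)

  # a hole bigger than the tolerated gap is refused
  keep <- bt < 100 | bt > 106
  s3 <- rr_series(bt[keep], rr[keep])
  expect_error(resample_ibi(s3, fs = 4, window = c(20, 260)), "gap")
})

test_that("plot method renders without error", {
  ta <- sinusoid_tachogram(8, dur_s = 128)
  tb <- sinusoid_tachogram(10, dur_s = 128)
  xw <- xwt_significance(cross_wavelet(cwt_morlet(ta), cwt_morlet(tb)))
  f <- tempfile(fileext = ".png")
  grDevices::png(f)
  expect_no_error(plot(xw))
  grDevices::dev.off()
  expect_true(file.exists(f))
  unlink(f)
})
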