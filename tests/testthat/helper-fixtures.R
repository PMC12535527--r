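# shared fixture builders; everything is generated in code

make_tachogram <- function(ibi, fs = 4, t0 = 0) {
  structure(list(t = t0 + (seq_along(ibi) - 1) / fs, ibi = ibi, fs = fs),
            class = "tachogram")
}

sinusoid_tachogram <- function(period_s, dur_s = 256, fs = 4, phase = 0,
                               mean_ibi = 0) {
  t <- (seq_len(dur_s * fs) - 1) / fs
  make_tachogram(mean_ibi + sin(2 * pi * t / period_s + phase), fs = fs)
}

constant_series <- function(rr_ms = 800, n = 100, role = "participant") {
  rr_series(seq_len(n) * rr_ms / 1000, rep(rr_ms, n), role = role,
            subject_id = "X", session_id = "S")
}

# hierarchical Gaussian data with known fixed slope and random intercepts
sim_hier_data <- function(beta = 0.5, n_groups = 40, n_per = 48,
                          sd_group = 0.5, sd_resid = 1, seed = 1) {
  withr_seed(seed, {
    g <- factor(rep(seq_len(n_groups), each = n_per))
    x <- stats::rnorm(n_groups * n_per)
    b <- stats::rnorm(n_groups, 0, sd_group)[as.integer(g)]
    data.frame(y = beta * x + b + stats::rnorm(length(x), 0, sd_resid),
               x = x, g = g)
  })
}

rr_df <- function(s) data.frame(beat_time = s$beat_time, rr = s$rr,
                                flag = s$flag)

withr_seed <- triadsync:::withr_seed
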