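#' Coupling configuration for a synthetic dyad
#'
#' Describes one simulated dyad: how fast each heart beats, which
#' high-frequency (respiratory/parasympathetic) and low-frequency
#' oscillations modulate it, and what share `kappa` of the HF modulator
#' the two members have in common. `kappa` is the coupling knob: the
#' HF component of member i is
#' `sqrt(kappa) * shared + sqrt(1 - kappa) * own_i`, so the expected
#' correlation of the two HF components equals `kappa`.
#'
#' @param duration_s recording length, seconds.
#' @param mean_hr mean heart rate in beats per minute; length 1 or 2
#'   (one per member; horses rest near 38 bpm, humans near 70).
#' @param hf_freq HF modulator centre frequency, Hz (human respiratory
#'   default 0.25).
#' @param lf_freq LF modulator centre frequency, Hz (default 0.08).
#' @param hf_amp,lf_amp dimensionless modulation depths.
#' @param kappa shared-variance coupling weight in `[0, 1]`.
#' @param noise_sd dimensionless white-noise level added to the
#'   modulator.
#' @param seed integer seed; all draws are deterministic given it.
#' @return a list of class `"coupling_config"`.
#' @export
coupling_config <- function(duration_s = 300, mean_hr = c(70, 70),
                            hf_freq = 0.25, lf_freq = 0.08,
                            hf_amp = 0.08, lf_amp = 0.04,
                            kappa = 0.5, noise_sd = 0.01, seed = 1L) {
  if (kappa < 0 || kappa > 1) stop("kappa must lie in [0, 1]")
  if (any(mean_hr <= 0)) stop("mean_hr must be positive")
  if (!(hf_freq > lf_freq && lf_freq > 0)) stop("need hf_freq > lf_freq > 0")
  if (duration_s <= 0) stop("duration_s must be positive")
  structure(list(duration_s = duration_s,
                 mean_hr = rep_len(mean_hr, 2),
                 hf_freq = hf_freq, lf_freq = lf_freq,
                 hf_amp = hf_amp, lf_amp = lf_amp,
                 kappa = kappa, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "coupling_config")
}

#' Generate coupled heart-rate modulator signals for a dyad
#'
#' Builds, on a uniform grid, the multiplicative rate modulators
#' `m_i(t) = 1 + hf_amp * (sqrt(kappa) * s_HF_shared + sqrt(1-kappa) * s_HF_own_i)
#'           + lf_amp * s_LF_own_i + noise` for both dyad members.
#' Shared and own components are independent unit-variance narrowband
#' oscillations at `hf_freq` / `lf_freq`.
#'
#' @param config a [coupling_config()].
#' @param sample_rate modulator sampling rate, Hz (>= 4).
#' @return list with `t` (seconds), `m` (n x 2 matrix of modulators),
#'   `hf` (n x 2 matrix of the HF components alone).
#' @export
generate_modulators <- function(config, sample_rate = 8) {
  stopifnot(inherits(config, "coupling_config"))
  if (sample_rate < 4) stop("sample_rate must be >= 4 Hz")
  dt <- 1 / sample_rate
  n <- ceiling(config$duration_s * sample_rate) + 1L
  withr_seed(config$seed, {
    shared <- narrowband_noise(n, dt, config$hf_freq)
    hf <- m <- matrix(0, n, 2)
    for (i in 1:2) {
      own_hf <- narrowband_noise(n, dt, config$hf_freq)
      own_lf <- narrowband_noise(n, dt, config$lf_freq)
      hf[, i] <- sqrt(config$kappa) * shared +
        sqrt(1 - config$kappa) * own_hf
      m[, i] <- 1 + config$hf_amp * hf[, i] + config$lf_amp * own_lf +
        stats::rnorm(n, 0, config$noise_sd)
    }
    m <- pmax(m, 0.05)  # modulators must stay positive for IPFM
    list(t = (seq_len(n) - 1) * dt, m = m, hf = hf)
  })
}

# evaluate expr under a temporary RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Emit beats from a modulated pacemaker (IPFM model)
#'
#' Integral pulse frequency modulation: a beat is emitted each time
#' `integral_0^t (mean_hr/60) m(tau) dtau` crosses the next integer.
#' With `m == 1` this is a metronome at `mean_hr` bpm; modulation of
#' `m` produces heart-rate variability with controlled spectral
#' content.
#'
#' @param t uniform time grid, seconds.
#' @param m modulator values on `t`, strictly positive.
#' @param mean_hr mean heart rate, beats per minute.
#' @param role,subject_id,session_id metadata for the returned series.
#' @return an [rr_series()].
#' @export
ipfm_beats <- function(t, m, mean_hr, role = "participant",
                       subject_id = NA_character_,
                       session_id = NA_character_) {
  if (mean_hr <= 0) stop("mean_hr must be positive")
  if (any(m <= 0)) stop("modulator must be strictly positive")
  rate <- (mean_hr / 60) * m
  dt <- diff(t)
  cum <- c(0, cumsum(dt * (rate[-length(rate)] + rate[-1]) / 2))
  n_beats <- floor(cum[length(cum)])
  if (n_beats < 2) stop("recording too short to emit beats")
  beat_t <- stats::approx(cum, t, xout = seq_len(n_beats))$y
  rr <- diff(c(t[1], beat_t)) * 1000
  rr_series(beat_t, rr, role = role,
            subject_id = subject_id, session_id = session_id)
}

#' Corrupt an RR series with realistic recording artifacts
#'
#' Adds the three artifact types the cleaning stage must handle:
#' multiplicative spikes (an RR scaled by roughly 0.5x or 2x, as from a
#' missed or doubly detected beat), exact duplicate rows, and dropout
#' gaps (all beats inside a window removed). A ground-truth corruption
#' mask is returned alongside so recovery can be scored.
#'
#' @param series an [rr_series()].
#' @param spike_rate,duplicate_rate expected events per minute.
#' @param gap_spec list of `c(start_s, length_s)` dropout windows.
#' @param seed integer seed.
#' @return list with `series` (corrupted copy), and ground truth:
#'   `spiked_time` (beat times whose rr was scaled), `duplicated_time`,
#'   `gaps` (matrix of start/length), `n_removed` (beats deleted by
#'   gaps).
#' @export
inject_artifacts <- function(series, spike_rate = 0, duplicate_rate = 0,
                             gap_spec = list(), seed = 1L) {
  stopifnot(inherits(series, "rr_series"))
  if (spike_rate < 0 || duplicate_rate < 0) stop("rates must be >= 0")
  t0 <- series$beat_time[1]
  t1 <- series$beat_time[nrow(series)]
  for (g in gap_spec) {
    if (g[1] < t0 || g[1] + g[2] > t1)
      stop("gap window outside the recording")
  }
  withr_seed(seed, {
    dur_min <- (t1 - t0) / 60
    df <- as.data.frame(series)

    n_spk <- stats::rpois(1, spike_rate * dur_min)
    n_spk <- min(n_spk, nrow(df))
    spk_idx <- sort(sample(nrow(df), n_spk))
    if (n_spk > 0) {
      fac <- sample(c(0.5, 2.0), n_spk, replace = TRUE) *
        exp(stats::rnorm(n_spk, 0, 0.05))
      df$rr[spk_idx] <- df$rr[spk_idx] * fac
    }
    spiked_time <- df$beat_time[spk_idx]

    # dropout gaps: remove all beats strictly inside each window
    n_removed <- 0L
    for (g in gap_spec) {
      inside <- df$beat_time > g[1] & df$beat_time < g[1] + g[2]
      n_removed <- n_removed + sum(inside)
      df <- df[!inside, , drop = FALSE]
    }

    n_dup <- stats::rpois(1, duplicate_rate * dur_min)
    n_dup <- min(n_dup, nrow(df))
    dup_idx <- sort(sample(nrow(df), n_dup))
    duplicated_time <- df$beat_time[dup_idx]
    if (n_dup > 0) {
      df <- df[sort(c(seq_len(nrow(df)), dup_idx)), , drop = FALSE]
    }

    out <- rr_like(series, df$beat_time, df$rr, df$flag)
    gaps <- if (length(gap_spec))
      do.call(rbind, gap_spec) else matrix(numeric(0), 0, 2)
    list(series = out, spiked_time = spiked_time,
         duplicated_time = duplicated_time,
         gaps = gaps, n_removed = n_removed)
  })
}
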