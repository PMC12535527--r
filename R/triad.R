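#' Simulation parameter defaults for triad sessions
#'
#' Physiological and artifact defaults used by
#' [generate_triad_session()]. Humans rest near 70 bpm, horses near
#' 38 bpm. Between-subject coupling is carried by one shared
#' narrowband oscillator per dyad, each at its own fixed frequency
#' inside the analysed HF band (`coupling_freq`, defaults 0.30 Hz for
#' horse-participant, 0.20 Hz for therapist-participant, 0.37 Hz for
#' horse-therapist) so the three dyadic rhythms stay spectrally
#' distinguishable; each subject's *uncoupled* HF variance sits at
#' an individual respiratory frequency drawn from the species range
#' (`hf_freq`, default 0.18-0.33 Hz for humans, 0.08-0.12 Hz for
#' horses). Coupling therefore does what it does physiologically: it
#' pulls spectral mass from the individual rhythm onto the common
#' one, which is what makes cross-wavelet power near the coupling
#' frequency respond to kappa even for two subjects of the same
#' species. Horse recordings receive markedly more artifacts than
#' human ones, mirroring chest-belt behaviour on equine skin.
#'
#' @param ... overrides for any default listed below.
#' @return a list of simulation parameters.
#' @export
sim_params <- function(...) {
  p <- list(
    sample_rate = 8,            # Hz, modulator grid
    coupling_freq = c(hp = 0.30, tp = 0.20, ht = 0.37),  # Hz, per dyad
    human = list(mean_hr = 70, hf_freq = c(0.18, 0.33), lf_freq = 0.08),
    horse = list(mean_hr = 38, hf_freq = c(0.08, 0.12), lf_freq = 0.04),
    hf_amp = 0.08, lf_amp = 0.04, noise_sd = 0.01,
    lying_boost = 0.2,          # extra horse-participant kappa while lying
    artifact = list(
      participant = list(spike_rate = 0.3, duplicate_rate = 0.05),
      therapist   = list(spike_rate = 0.3, duplicate_rate = 0.05),
      horse       = list(spike_rate = 1.2, duplicate_rate = 0.10)
    )
  )
  over <- list(...)
  p[names(over)] <- over
  p
}

#' Generate one synthetic triad therapy session
#'
#' Produces three coupled RR series (participant, therapist, horse)
#' spanning a segment timeline. Coupling is imposed through three
#' shared HF oscillators, one per dyad; subject i's HF component is
#' `sum_d sqrt(w_id) S_d + sqrt(1 - sum_d w_id) O_i` over the dyads d
#' it belongs to, so each dyad's HF correlation equals its kappa.
#' During the lying segment the horse-participant kappa is raised by
#' `params$lying_boost` (physical proximity intensifies coupling).
#'
#' @param kappa named numeric: `hp` (horse-participant), `tp`
#'   (therapist-participant), `ht` (horse-therapist), each in `[0, 1]`.
#' @param timeline a segment timeline, see [session_timeline()].
#' @param seed integer seed for this session.
#' @param params see [sim_params()].
#' @param mean_hr optional named numeric overriding per-subject mean
#'   heart rates (`participant`, `therapist`, `horse`).
#' @param subject_ids named character ids for the three roles.
#' @param session_id session identifier string.
#' @param artifacts logical; inject recording artifacts?
#' @return a list of class `"triad_session"` with elements `series`
#'   (named list of [rr_series()]), `timeline`, `truth` (realised
#'   kappas incl. the lying boost), `artifact_truth` (per-role
#'   corruption masks, when `artifacts = TRUE`).
#' @export
generate_triad_session <- function(kappa, timeline = demo_timeline(),
                                   seed = 1L, params = sim_params(),
                                   mean_hr = NULL,
                                   subject_ids = c(participant = "P01",
                                                   therapist = "T01",
                                                   horse = "H01"),
                                   session_id = "S1",
                                   artifacts = TRUE) {
  validate_timeline(timeline)
  for (d in c("hp", "tp", "ht")) {
    if (is.null(kappa[[d]])) stop("missing kappa for dyad '", d, "'")
    if (kappa[[d]] < 0 || kappa[[d]] > 1)
      stop("kappa['", d, "'] must lie in [0, 1]")
  }
  roles <- c("participant", "therapist", "horse")
  hr <- c(participant = params$human$mean_hr,
          therapist = params$human$mean_hr,
          horse = params$horse$mean_hr)
  if (!is.null(mean_hr)) hr[names(mean_hr)] <- mean_hr

  fs <- params$sample_rate
  dur <- timeline_duration(timeline)
  n <- ceiling(dur * fs) + 1L
  tgrid <- (seq_len(n) - 1) / fs
  lying <- timeline_segment(timeline, "lying")
  in_lying <- tgrid >= lying["start"] & tgrid < lying["end"]

  # dyad membership: which two shared oscillators feed each subject
  dyads_of <- list(participant = c("hp", "tp"),
                   therapist   = c("tp", "ht"),
                   horse       = c("hp", "ht"))

  series <- list()
  truth_boosted <- unlist(kappa[c("hp", "tp", "ht")])
  artifact_truth <- list()
  # one shared narrowband rhythm per dyad, each at its own frequency
  # inside the HF band so the dyads remain spectrally distinguishable
  shared <- list()
  withr_seed(derive_seed(seed, "shared"), {
    for (d in c("hp", "tp", "ht")) {
      f_d <- if (length(params$coupling_freq) > 1)
        params$coupling_freq[[d]] else params$coupling_freq
      shared[[d]] <- narrowband_noise(n, 1 / fs, f_d)
    }
  })
  truth_boosted["hp"] <- min(1, kappa[["hp"]] + params$lying_boost)

  for (role in roles) {
    sp <- if (role == "horse") params$horse else params$human
    withr_seed(derive_seed(seed, "subject", role), {
      f_own <- if (length(sp$hf_freq) > 1)
        stats::runif(1, sp$hf_freq[1], sp$hf_freq[2]) else sp$hf_freq
      own_hf <- narrowband_noise(n, 1 / fs, f_own)
      own_lf <- narrowband_noise(n, 1 / fs, sp$lf_freq)
      wnoise <- stats::rnorm(n, 0, params$noise_sd)
    })
    # time-varying dyad weights (lying proximity boost on hp)
    w <- sapply(dyads_of[[role]], function(d) {
      wd <- rep(kappa[[d]], n)
      if (d == "hp") wd[in_lying] <- pmin(1, wd[in_lying] + params$lying_boost)
      wd
    })
    tot <- rowSums(w)
    scl <- ifelse(tot > 1, 1 / tot, 1)
    w <- w * scl
    hf_i <- sqrt(pmax(0, 1 - rowSums(w))) * own_hf
    for (j in seq_along(dyads_of[[role]]))
      hf_i <- hf_i + sqrt(w[, j]) * shared[[dyads_of[[role]][j]]]
    m <- pmax(1 + params$hf_amp * hf_i + params$lf_amp * own_lf + wnoise, 0.05)
    s <- ipfm_beats(tgrid, m, hr[[role]], role = role,
                    subject_id = subject_ids[[role]],
                    session_id = session_id)
    if (artifacts) {
      ar <- params$artifact[[role]]
      corr <- inject_artifacts(s, spike_rate = ar$spike_rate,
                               duplicate_rate = ar$duplicate_rate,
                               seed = derive_seed(seed, "artifact", role))
      artifact_truth[[role]] <- corr[c("spiked_time", "duplicated_time")]
      s <- corr$series
    }
    series[[role]] <- s
  }

  structure(list(series = series, timeline = timeline,
                 truth = list(kappa = unlist(kappa[c("hp", "tp", "ht")]),
                              kappa_lying = truth_boosted),
                 artifact_truth = artifact_truth,
                 subject_ids = subject_ids, session_id = session_id,
                 seed = seed),
            class = "triad_session")
}

#' @export
print.triad_session <- function(x, ...) {
  cat(sprintf("<triad_session> %s: kappa hp=%.2f tp=%.2f ht=%.2f (lying hp=%.2f)\n",
              x$session_id, x$truth$kappa["hp"], x$truth$kappa["tp"],
              x$truth$kappa["ht"], x$truth$kappa_lying["hp"]))
  for (role in names(x$series))
    cat(sprintf("  %-11s %d beats\n", role, nrow(x$series[[role]])))
  invisible(x)
}
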