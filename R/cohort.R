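#' Cohort configuration
#'
#' Defines the simulated study population. Defaults mirror the study
#' design this generator emulates: 56 control participants with one
#' session each and 36 patients with four sessions each, three riding
#' therapists and four therapy horses, childhood-trauma (CTQ) scores
#' spanning the instrument range 25-125, and a linear dependence of
#' the dyadic coupling weights on the rescaled CTQ total:
#' `kappa_dyad = base + effect * (total - 25) / 100`, clipped to
#' `[0, 1]`. A negative `ctq_effect_therapist` with
#' `ctq_effect_horse = 0` encodes the hypothesised dissociation:
#' adversity attenuates therapist-participant coupling while
#' horse-participant coupling is preserved.
#'
#' @param n_control,n_patient participant counts (>= 0).
#' @param sessions_per_patient sessions for patient participants
#'   (controls always get one).
#' @param ctq_effect_therapist,ctq_effect_horse slope of the
#'   therapist-participant / horse-participant kappa on rescaled CTQ.
#' @param favorite_effect additive shift of the horse-therapist kappa
#'   when the therapist works her favorite horse (the study observed
#'   a small negative effect).
#' @param base_kappa named numeric baseline kappas (`hp`, `tp`, `ht`).
#' @param kappa_jitter_sd optional between-participant s.d. added to
#'   the baselines (extra between-dyad heterogeneity); 0 keeps the
#'   kappas an exact deterministic function of CTQ before clipping.
#' @param n_therapists,n_horses staffing; therapist j's favorite horse
#'   is horse j.
#' @param seed master cohort seed.
#' @return list of class `"cohort_config"`.
#' @export
cohort_config <- function(n_control = 56, n_patient = 36,
                          sessions_per_patient = 4,
                          ctq_effect_therapist = 0,
                          ctq_effect_horse = 0,
                          favorite_effect = -0.1,
                          base_kappa = c(hp = 0.35, tp = 0.45, ht = 0.4),
                          kappa_jitter_sd = 0,
                          n_therapists = 3, n_horses = 4,
                          seed = 1L) {
  if (n_control < 0 || n_patient < 0) stop("counts must be >= 0")
  if (n_control + n_patient < 1) stop("cohort must contain a participant")
  structure(list(n_control = n_control, n_patient = n_patient,
                 sessions_per_patient = sessions_per_patient,
                 ctq_effect_therapist = ctq_effect_therapist,
                 ctq_effect_horse = ctq_effect_horse,
                 favorite_effect = favorite_effect,
                 base_kappa = base_kappa,
                 kappa_jitter_sd = kappa_jitter_sd,
                 n_therapists = n_therapists, n_horses = n_horses,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

ctq_subscales <- c("emotional_abuse", "physical_abuse", "sexual_abuse",
                   "emotional_neglect", "physical_neglect")

#' Draw CTQ questionnaire scores
#'
#' Five subscales, each scored 5-25, summing to a total in 25-125.
#' A per-participant latent severity drives all subscales. Patients
#' draw severity uniformly, so patient totals spread over the whole
#' instrument range; controls draw from a low-severity distribution.
#'
#' @param n number of participants.
#' @param group `"control"` or `"patient"` (recycled).
#' @return data.frame with the five subscale columns and `ctq_total`.
#' @export
draw_ctq <- function(n, group = "control") {
  group <- rep_len(group, n)
  u <- ifelse(group == "patient",
              stats::runif(n),
              stats::rbeta(n, 1.3, 4.5))
  sub <- sapply(ctq_subscales, function(s) {
    v <- pmin(1, pmax(0, u + stats::rnorm(n, 0, 0.08)))
    as.integer(round(5 + 20 * v))
  })
  sub <- matrix(sub, nrow = n,
                dimnames = list(NULL, ctq_subscales))
  out <- as.data.frame(sub)
  out$ctq_total <- as.integer(rowSums(sub))
  out
}

#' Generate a synthetic cohort with ground-truth coupling
#'
#' Draws the participant table (group, therapist/horse assignment,
#' favorite-horse flag, CTQ scores, per-subject mean heart rates) and
#' the true dyadic kappas implied by the configuration. With
#' `simulate = TRUE` it also generates every session's RR series via
#' [generate_triad_session()].
#'
#' @param config a [cohort_config()].
#' @param timeline segment timeline used for the simulated sessions.
#' @param simulate logical; generate the RR series too?
#' @param params see [sim_params()].
#' @param artifacts passed to [generate_triad_session()].
#' @return list of class `"cohort"`: `participants` (one row per
#'   participant x session with true kappas), `sessions` (list of
#'   `triad_session`, when simulated), `config`.
#' @export
generate_cohort <- function(config = cohort_config(),
                            timeline = demo_timeline(),
                            simulate = TRUE,
                            params = sim_params(),
                            artifacts = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_control + config$n_patient
  tab <- withr_seed(derive_seed(config$seed, "cohort"), {
    group <- c(rep("control", config$n_control),
               rep("patient", config$n_patient))
    ctq <- draw_ctq(n, group)
    therapist <- sample(config$n_therapists, n, replace = TRUE)
    horse <- sample(config$n_horses, n, replace = TRUE)
    jit_hp <- stats::rnorm(n, 0, config$kappa_jitter_sd)
    jit_tp <- stats::rnorm(n, 0, config$kappa_jitter_sd)
    jit_ht <- stats::rnorm(n, 0, config$kappa_jitter_sd)
    hr_part <- stats::rnorm(n, 70, 6)
    data.frame(participant_id = sprintf("P%02d", seq_len(n)),
               group = group,
               therapist_id = sprintf("T%02d", therapist),
               horse_id = sprintf("H%02d", horse),
               favorite_horse = as.integer(horse == therapist),
               ctq, jit_hp = jit_hp, jit_tp = jit_tp, jit_ht = jit_ht,
               mean_hr_participant = hr_part,
               stringsAsFactors = FALSE)
  })
  # stable per-staff heart rates
  staff_hr <- withr_seed(derive_seed(config$seed, "staff"), {
    list(therapist = stats::rnorm(config$n_therapists, 70, 6),
         horse = stats::rnorm(config$n_horses, 38, 3))
  })

  resc <- (tab$ctq_total - 25) / 100
  clip01 <- function(x) pmin(1, pmax(0, x))
  tab$kappa_tp <- clip01(config$base_kappa[["tp"]] +
                           config$ctq_effect_therapist * resc + tab$jit_tp)
  tab$kappa_hp <- clip01(config$base_kappa[["hp"]] +
                           config$ctq_effect_horse * resc + tab$jit_hp)
  tab$kappa_ht <- clip01(config$base_kappa[["ht"]] +
                           config$favorite_effect * tab$favorite_horse +
                           tab$jit_ht)
  tab$jit_hp <- tab$jit_tp <- tab$jit_ht <- NULL

  n_sess <- ifelse(tab$group == "patient", config$sessions_per_patient, 1L)
  rows <- tab[rep(seq_len(n), n_sess), , drop = FALSE]
  rows$session_index <- unlist(lapply(n_sess, seq_len))
  rows$session_id <- paste0(rows$participant_id, "_s", rows$session_index)
  rownames(rows) <- NULL

  sessions <- NULL
  if (simulate) {
    sessions <- vector("list", nrow(rows))
    names(sessions) <- rows$session_id
    for (i in seq_len(nrow(rows))) {
      r <- rows[i, ]
      th_i <- as.integer(sub("T", "", r$therapist_id))
      ho_i <- as.integer(sub("H", "", r$horse_id))
      sessions[[i]] <- generate_triad_session(
        kappa = list(hp = r$kappa_hp, tp = r$kappa_tp, ht = r$kappa_ht),
        timeline = timeline,
        seed = derive_seed(config$seed, "session", r$session_id),
        params = params,
        mean_hr = c(participant = r$mean_hr_participant,
                    therapist = staff_hr$therapist[th_i],
                    horse = staff_hr$horse[ho_i]),
        subject_ids = c(participant = r$participant_id,
                        therapist = r$therapist_id,
                        horse = r$horse_id),
        session_id = r$session_id,
        artifacts = artifacts)
    }
  }
  structure(list(participants = rows, sessions = sessions, config = config),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  p <- x$participants
  cat(sprintf("<cohort> %d participants (%d control, %d patient), %d session rows%s\n",
              length(unique(p$participant_id)),
              sum(p$group == "control" & p$session_index == 1),
              sum(p$group == "patient" & p$session_index == 1),
              nrow(p),
              if (is.null(x$sessions)) " (metadata only)" else ""))
  invisible(x)
}
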