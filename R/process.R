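#' Process one triad session into band-power rows
#'
#' Runs the full per-session measurement chain: clean each RR series
#' (iterative equine pass for the horse, single pass for the humans),
#' resample the first 240 s of the lying segment into 4 Hz tachograms,
#' form the three dyadic cross-wavelet transforms, and extract the
#' mean HF-band cross power per 10-second interval. Baseline vagal
#' tone (RMSSD over the same four-minute window) is computed for both
#' humans.
#'
#' @param session a [generate_triad_session()] result, or a list with
#'   the same `series`/`timeline` structure built from recorded data.
#' @param cleaning a [cleaning_config()].
#' @param cwt a [cwt_config()].
#' @param bands a [frequency_bands()].
#' @param fs tachogram sampling rate (Hz).
#' @param significance optionally attach pointwise significance masks
#'   (`"none"`, `"analytic"`, `"montecarlo"`).
#' @param alpha significance level when masks are requested.
#' @param keep_xwt keep the three `xwt` objects in the result?
#' @return data.frame of class `"band_power"`: one row per
#'   (dyad, minute, interval, band) with `power`, identifiers and
#'   `rmssd_participant` / `rmssd_therapist` columns. The `xwt`
#'   attribute holds the transforms when requested.
#' @export
process_session <- function(session, cleaning = cleaning_config(),
                            cwt = cwt_config(), bands = frequency_bands(),
                            fs = 4, significance = c("none", "analytic",
                                                     "montecarlo"),
                            alpha = 0.05, keep_xwt = FALSE) {
  significance <- match.arg(significance)
  validate_timeline(session$timeline)
  lying <- timeline_segment(session$timeline, "lying")
  win <- c(lying[["start"]], lying[["start"]] + 240)

  cleaned <- list(
    participant = clean_rr(session$series$participant, cleaning),
    therapist = clean_rr(session$series$therapist, cleaning),
    horse = clean_equine(session$series$horse, cleaning))

  tach <- lapply(cleaned, resample_ibi, fs = fs, window = win)
  cw <- lapply(tach, cwt_morlet, config = cwt)

  dyads <- list(`horse-participant` = c("horse", "participant"),
                `therapist-participant` = c("therapist", "participant"),
                `horse-therapist` = c("horse", "therapist"))
  out <- NULL
  xwts <- list()
  for (d in names(dyads)) {
    pair <- dyads[[d]]
    xw <- cross_wavelet(cw[[pair[1]]], cw[[pair[2]]])
    if (significance != "none")
      xw <- xwt_significance(xw, alpha = alpha, method = significance)
    rows <- extract_interval_power(xw, session$timeline, bands)
    rows <- cbind(dyad = d, rows, stringsAsFactors = FALSE)
    out <- rbind(out, rows)
    if (keep_xwt) xwts[[d]] <- xw
  }
  ids <- session$subject_ids
  out$participant_id <- ids[["participant"]]
  out$therapist_id <- ids[["therapist"]]
  out$horse_id <- ids[["horse"]]
  out$session_id <- session$session_id
  out$rmssd_participant <- rmssd(cleaned$participant, win)
  out$rmssd_therapist <- rmssd(cleaned$therapist, win)
  class(out) <- c("band_power", "data.frame")
  if (keep_xwt) attr(out, "xwt") <- xwts
  attr(out, "cleaning_logs") <- lapply(cleaned, attr, "cleaning_log")
  out
}

#' Process a whole cohort into a normalised band-power table
#'
#' Applies [process_session()] to every simulated session, joins the
#' cohort metadata (group, session index, favorite-horse flag, CTQ
#' scores, true kappas), and z-scores log power within the chosen
#' stratum (default: within dyad type, pooled across sessions). Sessions whose horse recording is unusable
#' are skipped and listed in the `"skipped"` attribute.
#'
#' @param cohort a [generate_cohort()] result with simulated sessions.
#' @param ... passed to [process_session()].
#' @param stratum z-scoring stratum columns (see
#'   [ztransform_power()]).
#' @return a long-format `"band_power"` data.frame with `cwp_z`.
#' @export
process_cohort <- function(cohort, ...,
                           stratum = "dyad") {
  stopifnot(inherits(cohort, "cohort"))
  if (is.null(cohort$sessions))
    stop("cohort has no simulated sessions (generate with simulate = TRUE)")
  meta_cols <- c("participant_id", "group", "session_index", "favorite_horse",
                 ctq_subscales, "ctq_total",
                 "kappa_hp", "kappa_tp", "kappa_ht")
  out <- vector("list", length(cohort$sessions))
  skipped <- character(0)
  for (i in seq_along(cohort$sessions)) {
    ses <- cohort$sessions[[i]]
    rows <- tryCatch(process_session(ses, ...), error = function(e) e)
    if (inherits(rows, "error")) {
      skipped <- c(skipped, paste0(ses$session_id, ": ",
                                   conditionMessage(rows)))
      next
    }
    meta <- cohort$participants[
      cohort$participants$session_id == ses$session_id, meta_cols]
    out[[i]] <- cbind(rows, meta[rep(1, nrow(rows)),
                                 setdiff(meta_cols, "participant_id")])
  }
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(out) <- NULL
  out <- ztransform_power(out, stratum = stratum)
  class(out) <- c("band_power", "data.frame")
  attr(out, "skipped") <- skipped
  out
}
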