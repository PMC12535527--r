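#' Run the full simulate-clean-sync-model pipeline
#'
#' End-to-end driver used by the command-line interface and the
#' worked examples: simulate a cohort, write the per-subject RR logs,
#' process every session into the normalised band-power table, fit
#' the standard model ladders for the three dyadic responses, and
#' write CSV outputs plus a human-readable report. Identical config
#' and seed give identical outputs.
#'
#' @param config a [run_config()].
#' @param outdir output directory (created if missing).
#' @param stages character subset of
#'   `c("simulate", "clean", "sync", "model", "report")`; defaults to
#'   all. Later stages read the CSV outputs of earlier ones, so a
#'   stage run on its own fails with an actionable error if its
#'   inputs are missing.
#' @return invisibly, a list with the main artefacts of the stages
#'   that ran.
#' @export
run_pipeline <- function(config = run_config(), outdir = "triadsync_out",
                         stages = c("simulate", "clean", "sync", "model",
                                    "report")) {
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  save_run_config(config, file.path(outdir, "effective_config.yaml"))
  timeline <- if (identical(config$timeline, "demo")) demo_timeline()
              else session_timeline()
  out <- list()

  raw_dir <- file.path(outdir, "rr_raw")
  band_csv <- file.path(outdir, "band_power.csv")

  if ("simulate" %in% stages) {
    cc <- do.call(cohort_config, c(config$cohort, list(seed = config$seed)))
    cohort <- generate_cohort(cc, timeline = timeline, simulate = TRUE)
    dir.create(raw_dir, showWarnings = FALSE)
    for (ses in cohort$sessions)
      for (role in names(ses$series))
        write_rr_csv(ses$series[[role]],
                     file.path(raw_dir, sprintf("%s_%s.csv",
                                                ses$session_id, role)))
    utils::write.csv(cohort$participants,
                     file.path(outdir, "cohort_metadata.csv"),
                     row.names = FALSE)
    out$cohort <- cohort
  }

  if (any(c("clean", "sync") %in% stages)) {
    if (is.null(out$cohort))
      stop("sync stage needs the simulate stage (or rerun with stages = 'all'): ",
           "no cohort in memory and no ", raw_dir)
    cleaning <- do.call(cleaning_config, config$cleaning)
    cwtc <- do.call(cwt_config, config$cwt)
    bands <- do.call(frequency_bands, config$bands)
    table <- process_cohort(out$cohort, cleaning = cleaning, cwt = cwtc,
                            bands = bands, fs = config$fs,
                            stratum = config$stratum)
    utils::write.csv(table, band_csv, row.names = FALSE)
    out$band_power <- table
  }

  if ("model" %in% stages) {
    if (is.null(out$band_power)) {
      if (!file.exists(band_csv))
        stop("model stage needs ", band_csv,
             " - run the sync stage first")
      out$band_power <- utils::read.csv(band_csv)
    }
    out$ladders <- standard_ladders(out$band_power)
    for (nm in names(out$ladders)) {
      lad <- out$ladders[[nm]]
      utils::write.csv(lad$comparison,
                       file.path(outdir, paste0("ladder_", nm, ".csv")),
                       row.names = FALSE)
      utils::write.csv(lad$best_fit$estimates,
                       file.path(outdir, paste0("estimates_", nm, ".csv")),
                       row.names = FALSE)
    }
  }

  if ("report" %in% stages) {
    rep_file <- file.path(outdir, "report.txt")
    con <- file(rep_file, "w")
    sink(con); on.exit({ sink(); close(con) }, add = TRUE)
    cat("triadsync pipeline report\n")
    cat("package version:", as.character(utils::packageVersion("triadsync")),
        "\n")
    cat("seed:", config$seed, "\n\n")
    if (!is.null(out$band_power)) {
      cat("band-power rows:", nrow(out$band_power), "\n")
      print(utils::head(out$band_power[c("dyad", "session_id", "minute",
                                         "interval", "band", "cwp_z")]))
    }
    if (!is.null(out$ladders)) {
      for (nm in names(out$ladders)) {
        cat("\n== response:", nm, "==\n")
        print(out$ladders[[nm]])
        print(assumption_checks(out$ladders[[nm]]$best_fit))
      }
    }
  }
  invisible(out)
}

#' Standard model ladders for the three dyadic responses
#'
#' Builds, for each response dyad, the design table and the nested
#' formula ladder used throughout: null (random intercept) ->
#' design variables (minute, interval, band and interactions) ->
#' covariates -> the other-dyad synchrony transfer predictor. Session
#' enters only when more than one session per participant is present.
#'
#' @param table a normalised `"band_power"` table.
#' @param alpha per-step level.
#' @return named list of `"hrv_ladder"` objects, one per response
#'   dyad with enough data.
#' @export
standard_ladders <- function(table, alpha = 0.05) {
  out <- list()
  specs <- list(
    `horse-participant` = list(pred = "horse-therapist",
                               unit = "participant_id"),
    `therapist-participant` = list(pred = "horse-therapist",
                                   unit = "participant_id"),
    `horse-therapist` = list(pred = NULL, unit = "therapist_id"))
  for (resp in names(specs)) {
    sp <- specs[[resp]]
    des <- tryCatch(build_design(table, resp, predictor_dyad = sp$pred),
                    error = function(e) NULL)
    if (is.null(des) || nrow(des) < 100) next
    unit <- sp$unit
    # a grouping factor needs at least two sampled levels; small
    # cohorts with a single therapist fall back to participant units
    if (length(unique(des[[unit]])) < 2) unit <- "participant_id"
    if (length(unique(des[[unit]])) < 2) next
    multi_session <- length(unique(des$session)) > 1
    base <- paste0("cwp_z ~ 1 + (1 | ", unit, ")")
    design_terms <- c("minute", "interval", "band",
                      if (multi_session) "session",
                      "minute:interval")
    f <- list(null = base,
              design = paste0("cwp_z ~ ", paste(design_terms, collapse = " + "),
                              " + (1 | ", unit, ")"))
    if (!is.null(sp$pred))
      f$transfer <- paste0(sub("cwp_z ~ ", "cwp_z ~ sync_other + ",
                               f$design, fixed = TRUE))
    if (resp == "horse-therapist" && "favorite_horse" %in% names(des) &&
        length(unique(des$favorite_horse)) > 1)
      f$favorite <- paste0(sub("cwp_z ~ ", "cwp_z ~ favorite_horse + ",
                               f$design, fixed = TRUE))
    ladder <- lapply(f, stats::as.formula)
    out[[resp]] <- model_ladder(des, ladder, alpha = alpha)
  }
  out
}
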