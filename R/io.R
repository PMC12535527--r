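#' Write an RR series to the RR-CSV dialect
#'
#' A minimal open beat-log format: header `time_s,rr_ms,flag`, one row
#' per beat, times and intervals printed with `%.3f`. Role, subject
#' and session are carried in the filename by convention
#' (`<subject>_<session>_<role>.csv`) or supplied on read.
#'
#' @param series an [rr_series()].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_rr_csv <- function(series, path) {
  stopifnot(inherits(series, "rr_series"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("time_s,rr_ms,flag", con)
  writeLines(sprintf("%.3f,%.3f,%s", series$beat_time, series$rr,
                     series$flag), con)
  invisible(path)
}

#' Read an RR series from the RR-CSV dialect
#'
#' Malformed rows (unparseable numbers, non-positive RR) are rejected
#' but collected into the `"rejected_rows"` attribute so a recording
#' is never silently truncated. Beat times must be non-decreasing
#' beyond a 1 ms tolerance.
#'
#' @param path input file path.
#' @param role,subject_id,session_id metadata for the series.
#' @return an [rr_series()] with a `"rejected_rows"` attribute.
#' @export
read_rr_csv <- function(path, role = "participant",
                        subject_id = NA_character_,
                        session_id = NA_character_) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  if (length(lines) < 2) stop("empty RR file: ", path)
  header <- trimws(lines[1])
  if (header != "time_s,rr_ms,flag")
    stop("unexpected header '", header, "' in ", path)
  body <- lines[-1]
  parts <- strsplit(body, ",", fixed = TRUE)
  ok <- lengths(parts) == 3
  t <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 1)))
  r <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2)))
  fl <- vapply(parts, `[`, "", 3)
  ok <- ok & !is.na(t) & !is.na(r) & r > 0
  rejected <- data.frame(line = which(!ok) + 1L,
                         content = body[!ok], stringsAsFactors = FALSE)
  t <- t[ok]; r <- r[ok]; fl <- fl[ok]
  if (length(t) < 1) stop("no valid rows in ", path)
  if (any(diff(t) < -1e-3)) stop("beat times not monotone in ", path)
  ord <- order(t)
  out <- rr_series(t[ord], r[ord], fl[ord], role = role,
                   subject_id = subject_id, session_id = session_id)
  attr(out, "rejected_rows") <- rejected
  out
}

#' Default run configuration
#'
#' The effective configuration of a pipeline run: cleaning, wavelet,
#' band and extraction settings, the z-score stratum, the cohort to
#' simulate and the master seed. Saved alongside every run so that
#' identical config + seed reproduce identical outputs.
#'
#' @param ... overrides of the defaults (unknown keys are rejected).
#' @return nested list of class `"run_config"`.
#' @export
run_config <- function(...) {
  cfg <- list(
    seed = 1L,
    fs = 4,
    alpha = 0.05,
    significance = "none",
    stratum = "dyad",
    cleaning = unclass(cleaning_config()),
    cwt = unclass(cwt_config()),
    bands = unclass(frequency_bands()),
    cohort = list(n_control = 4, n_patient = 2, sessions_per_patient = 2,
                  ctq_effect_therapist = -0.3, ctq_effect_horse = 0,
                  favorite_effect = -0.1),
    timeline = "demo"
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  utils::modifyList(cfg, over)
}

#' Load / save a run configuration as YAML
#'
#' `load_run_config()` reads a YAML file, rejects unknown keys, and
#' materialises all defaults into the returned effective config;
#' `save_run_config()` writes one.
#'
#' @param path YAML file path.
#' @param cfg a [run_config()] list.
#' @return the effective configuration list / invisibly `path`.
#' @export
load_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw %||% list())
}

#' @rdname load_run_config
#' @export
save_run_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}
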