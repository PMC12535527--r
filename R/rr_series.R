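#' Construct a beat-to-beat RR-interval series
#'
#' The central raw-data container: one subject's beat-to-beat record.
#' `beat_time` is seconds from session start; `rr[k]` is the interval
#' (ms) ending at beat `k`, so for a contiguous recording
#' `beat_time[k] - beat_time[k-1] == rr[k]/1000`.
#'
#' @param beat_time numeric, seconds from session start, non-decreasing.
#' @param rr numeric, interbeat intervals in milliseconds, positive.
#' @param flag character per-beat quality flag; one of `"ok"`,
#'   `"outlier"`, `"interpolated"`, `"duplicate_removed"`.
#' @param role one of `"participant"`, `"therapist"`, `"horse"`.
#' @param subject_id,session_id identifiers carried as attributes.
#' @return a `data.frame` of class `"rr_series"` with columns
#'   `beat_time`, `rr`, `flag` and attributes `role`, `subject_id`,
#'   `session_id`.
#' @export
rr_series <- function(beat_time, rr, flag = "ok",
                      role = c("participant", "therapist", "horse"),
                      subject_id = NA_character_,
                      session_id = NA_character_) {
  role <- match.arg(role)
  stopifnot(length(beat_time) == length(rr))
  if (any(rr <= 0)) stop("rr intervals must be positive")
  if (is.unsorted(beat_time)) stop("beat_time must be non-decreasing")
  flag <- rep_len(as.character(flag), length(rr))
  bad <- setdiff(unique(flag),
                 c("ok", "outlier", "interpolated", "duplicate_removed"))
  if (length(bad)) stop("unknown flag value(s): ", paste(bad, collapse = ", "))
  out <- data.frame(beat_time = as.numeric(beat_time),
                    rr = as.numeric(rr),
                    flag = flag,
                    stringsAsFactors = FALSE)
  structure(out,
            role = role, subject_id = subject_id, session_id = session_id,
            class = c("rr_series", "data.frame"))
}

rr_meta <- function(x) {
  list(role = attr(x, "role"),
       subject_id = attr(x, "subject_id"),
       session_id = attr(x, "session_id"))
}

# rebuild an rr_series keeping the metadata of a template
rr_like <- function(template, beat_time, rr, flag = "ok") {
  m <- rr_meta(template)
  rr_series(beat_time, rr, flag,
            role = m$role, subject_id = m$subject_id,
            session_id = m$session_id)
}

#' @export
print.rr_series <- function(x, ...) {
  m <- rr_meta(x)
  dur <- if (nrow(x)) diff(range(x$beat_time)) else 0
  cat(sprintf("<rr_series> %s beats, %.1f s, role=%s, subject=%s, session=%s\n",
              nrow(x), dur, m$role, m$subject_id, m$session_id))
  tab <- table(x$flag)
  cat("  flags:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  invisible(x)
}

#' Duration in seconds spanned by an RR series
#' @param x an `rr_series`.
#' @return numeric scalar.
#' @export
rr_duration <- function(x) {
  if (!nrow(x)) return(0)
  x$beat_time[nrow(x)] - (x$beat_time[1] - x$rr[1] / 1000)
}
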