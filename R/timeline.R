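#' Session segment timelines
#'
#' A timeline is a data.frame of ordered, non-overlapping segments
#' `(segment, start_s, end_s)`. `session_timeline()` follows the
#' standard therapy-session structure: an opening questionnaire block,
#' then contact (5 min), grooming (5 min), riding (15 min), lying on
#' the horse (5 min), farewell, and a closing questionnaire block.
#' `demo_timeline()` keeps the same segment order but compresses the
#' non-analysed segments so that desk-scale simulations stay cheap;
#' the lying segment keeps its full 5 minutes since that is where the
#' synchrony extraction happens.
#'
#' @param lying_s duration of the lying segment (>= 240 s so that four
#'   one-minute analysis intervals fit).
#' @return data.frame with columns `segment`, `start_s`, `end_s`.
#' @export
session_timeline <- function(lying_s = 300) {
  make_timeline(c(questionnaire = 600, contact = 300, grooming = 300,
                  riding = 900, lying = lying_s, farewell = 120,
                  questionnaire2 = 600))
}

#' @rdname session_timeline
#' @export
demo_timeline <- function(lying_s = 300) {
  make_timeline(c(questionnaire = 20, contact = 20, grooming = 20,
                  riding = 40, lying = lying_s, farewell = 20,
                  questionnaire2 = 20))
}

make_timeline <- function(durations) {
  ends <- cumsum(durations)
  tl <- data.frame(segment = names(durations),
                   start_s = c(0, ends[-length(ends)]),
                   end_s = as.numeric(ends),
                   row.names = NULL, stringsAsFactors = FALSE)
  validate_timeline(tl)
  tl
}

validate_timeline <- function(tl) {
  stopifnot(is.data.frame(tl),
            all(c("segment", "start_s", "end_s") %in% names(tl)))
  if (any(tl$end_s <= tl$start_s)) stop("segments must have positive length")
  if (any(diff(as.vector(rbind(tl$start_s, tl$end_s))) < 0))
    stop("segments must be ordered and non-overlapping")
  ly <- tl[tl$segment == "lying", ]
  if (nrow(ly) != 1) stop("timeline must contain exactly one 'lying' segment")
  if (ly$end_s - ly$start_s < 240)
    stop("lying segment must last at least 240 s")
  invisible(tl)
}

timeline_segment <- function(tl, name) {
  row <- tl[tl$segment == name, ]
  if (!nrow(row)) stop("no segment named '", name, "'")
  c(start = row$start_s[1], end = row$end_s[1])
}

timeline_duration <- function(tl) max(tl$end_s)
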