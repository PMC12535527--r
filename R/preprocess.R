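#' Cleaning configuration
#'
#' @param outlier_threshold relative deviation from the local median
#'   above which a beat is flagged; must lie in the physiologically
#'   sensible range `[0.20, 0.50]` (default 0.30).
#' @param short_gap_max_s gaps up to this many seconds are bridged
#'   from the flanking beats (default 2); longer gaps use a linear
#'   trend fitted over `long_gap_flank_s` of data on each side.
#' @param median_window number of neighbouring beats for the running
#'   median (default 11).
#' @param max_passes iteration cap for the equine cleaning loop.
#' @param long_gap_flank_s flank length (s) for long-gap trend fits.
#' @param abs_bounds named list of absolute physiological RR bounds
#'   (ms) per species.
#' @return list of class `"cleaning_config"`.
#' @export
cleaning_config <- function(outlier_threshold = 0.30, short_gap_max_s = 2,
                            median_window = 11, max_passes = 10,
                            long_gap_flank_s = 10,
                            abs_bounds = list(human = c(300, 2000),
                                              horse = c(500, 4000))) {
  if (outlier_threshold < 0.20 || outlier_threshold > 0.50)
    stop("outlier_threshold must lie in [0.20, 0.50]")
  if (short_gap_max_s <= 0) stop("short_gap_max_s must be positive")
  structure(list(outlier_threshold = outlier_threshold,
                 short_gap_max_s = short_gap_max_s,
                 median_window = median_window,
                 max_passes = max_passes,
                 long_gap_flank_s = long_gap_flank_s,
                 abs_bounds = abs_bounds),
            class = "cleaning_config")
}

#' Collapse duplicate beat rows
#'
#' Rows sharing an identical timestamp are collapsed to the first
#' occurrence. The number removed is recorded in the
#' `"n_duplicates_removed"` attribute.
#'
#' @param series an [rr_series()].
#' @return the deduplicated series.
#' @export
remove_duplicates <- function(series) {
  stopifnot(inherits(series, "rr_series"))
  keep <- !duplicated(series$beat_time)
  out <- rr_like(series, series$beat_time[keep], series$rr[keep],
                 series$flag[keep])
  attr(out, "n_duplicates_removed") <- sum(!keep)
  out
}

#' Flag implausible RR intervals
#'
#' A beat is flagged when its RR deviates from the running median over
#' a `median_window`-beat neighbourhood (computed on the beats inside
#' the absolute physiological bounds) by strictly more than
#' `outlier_threshold` (relative), or when it falls outside the
#' absolute bounds of its species (humans 300-2000 ms, horses
#' 500-4000 ms by default).
#'
#' @param series an [rr_series()].
#' @param config a [cleaning_config()].
#' @return logical outlier mask, one element per beat.
#' @export
detect_outliers <- function(series, config = cleaning_config()) {
  stopifnot(inherits(series, "rr_series"), inherits(config, "cleaning_config"))
  n <- nrow(series)
  if (config$median_window >= n)
    stop("median_window must be smaller than the series length")
  species <- if (attr(series, "role") == "horse") "horse" else "human"
  bounds <- config$abs_bounds[[species]]
  rr <- series$rr
  mask <- rr < bounds[1] | rr > bounds[2]
  ok_idx <- which(!mask)
  if (length(ok_idx) <= config$median_window) return(mask)
  w <- config$median_window
  if (w %% 2 == 0) w <- w + 1L   # runmed needs an odd window
  med <- stats::runmed(rr[ok_idx], w, endrule = "median")
  dev <- abs(rr[ok_idx] - med) / med
  mask[ok_idx[dev > config$outlier_threshold]] <- TRUE
  mask
}

#' Fill missing-beat gaps by interpolation
#'
#' A gap exists between consecutive beats where the timestamp step
#' exceeds the recorded RR by more than half the local RR (beats are
#' missing). Gaps up to `short_gap_max_s` are bridged with beats whose
#' RR values interpolate linearly between the flanking RR values;
#' longer gaps are filled following a linear RR trend fitted to
#' `long_gap_flank_s` seconds of real data before and after the gap.
#' Inserted beats carry the flag `"interpolated"`. Gaps at the very
#' edge of the recording, with no flanking data, are left unfilled and
#' listed in the `"unfilled_gaps"` attribute.
#'
#' @param series an [rr_series()] (outliers already deleted).
#' @param config a [cleaning_config()].
#' @return the series with inserted beats.
#' @export
interpolate_gaps <- function(series, config = cleaning_config()) {
  stopifnot(inherits(series, "rr_series"))
  n <- nrow(series)
  if (n < 2) return(series)
  bt <- series$beat_time; rr <- series$rr; fl <- series$flag
  step <- diff(bt)                       # s
  expect <- rr[-1] / 1000                # s implied by the recorded RR
  med_rr <- stats::median(rr) / 1000
  gap_after <- which(step - expect > med_rr / 2)

  new_bt <- list(); new_rr <- list(); new_fl <- list()
  unfilled <- NULL
  for (g in gap_after) {
    gap_start <- bt[g]
    gap_len <- step[g] - expect[g]
    r0 <- rr[g]; r1 <- rr[g + 1]
    if (gap_len <= config$short_gap_max_s) {
      k <- max(1L, round(gap_len * 2000 / (r0 + r1)))
      frac <- (seq_len(k) - 0.5) / k     # midpoint bridge between flanks
      rr_ins <- r0 + frac * (r1 - r0)
    } else {
      flank <- config$long_gap_flank_s
      pre <- which(bt <= gap_start & bt > gap_start - flank & fl != "interpolated")
      post <- which(bt >= bt[g + 1] & bt < bt[g + 1] + flank & fl != "interpolated")
      pts <- c(pre, post)
      if (length(pre) < 2 || length(post) < 2) {
        unfilled <- rbind(unfilled, c(gap_start, gap_len))
        next
      }
      trend <- stats::lm.fit(cbind(1, bt[pts]), rr[pts])$coefficients
      # tile the gap with beats whose RR follows the flank trend,
      # rescaled so the inserted time sums exactly to the gap
      rbar <- max(200, trend[1] + trend[2] * (gap_start + gap_len / 2))
      k <- max(1L, round(gap_len * 1000 / rbar))
      tpos <- gap_start + (seq_len(k) - 0.5) / k * gap_len
      rr_ins <- pmax(200, trend[1] + trend[2] * tpos)
      rr_ins <- rr_ins * (gap_len * 1000) / sum(rr_ins)
    }
    t_ins <- gap_start + cumsum(rr_ins) / 1000
    new_bt[[length(new_bt) + 1L]] <- t_ins
    new_rr[[length(new_rr) + 1L]] <- rr_ins
    new_fl[[length(new_fl) + 1L]] <- rep("interpolated", length(rr_ins))
  }
  if (length(new_bt)) {
    bt2 <- c(bt, unlist(new_bt)); rr2 <- c(rr, unlist(new_rr))
    fl2 <- c(fl, unlist(new_fl))
    ord <- order(bt2)
    out <- rr_like(series, bt2[ord], rr2[ord], fl2[ord])
  } else out <- series
  # the RR of the first real beat after each gap now follows an
  # inserted beat; leave it as recorded (it measures a real interval)
  attr(out, "unfilled_gaps") <- unfilled
  out
}

#' Clean a (human) RR series
#'
#' One pass of the standard pipeline: collapse duplicates, flag and
#' delete outliers, then interpolate the resulting gaps.
#'
#' @param series an [rr_series()].
#' @param config a [cleaning_config()].
#' @return cleaned series with a `"cleaning_log"` attribute
#'   (data.frame of per-pass counts).
#' @export
clean_rr <- function(series, config = cleaning_config()) {
  s <- remove_duplicates(series)
  n_dup <- attr(s, "n_duplicates_removed")
  mask <- detect_outliers(s, config)
  s2 <- rr_like(s, s$beat_time[!mask], s$rr[!mask], s$flag[!mask])
  s3 <- interpolate_gaps(s2, config)
  log <- data.frame(pass = 1L, duplicates = n_dup, outliers = sum(mask),
                    interpolated = sum(s3$flag == "interpolated") -
                      sum(s2$flag == "interpolated"))
  attr(s3, "cleaning_log") <- log
  attr(s3, "unfilled_gaps") <- attr(s3, "unfilled_gaps")
  s3
}

#' Iterative equine artifact cleaning
#'
#' Horse chest-belt recordings are considerably more artifact laden
#' than human ones. This pass repeats detect-delete-interpolate until
#' a pass flags nothing (or `max_passes` is reached), keeping a
#' per-pass audit log. If any single pass flags more than half of the
#' remaining beats the recording is declared unusable.
#'
#' @param series an [rr_series()] with role `"horse"`.
#' @param config a [cleaning_config()].
#' @return cleaned series with a `"cleaning_log"` attribute.
#' @export
clean_equine <- function(series, config = cleaning_config()) {
  if (attr(series, "role") != "horse")
    stop("clean_equine expects a horse series")
  s <- remove_duplicates(series)
  log <- data.frame(pass = integer(0), duplicates = integer(0),
                    outliers = integer(0), interpolated = integer(0))
  n_dup <- attr(s, "n_duplicates_removed")
  for (pass in seq_len(config$max_passes)) {
    mask <- detect_outliers(s, config)
    # never re-flag beats we inserted ourselves
    mask[s$flag == "interpolated"] <- FALSE
    if (!any(mask)) {
      log <- rbind(log, data.frame(pass = pass, duplicates = n_dup,
                                   outliers = 0L, interpolated = 0L))
      break
    }
    if (mean(mask) > 0.5) stop("unusable recording: >50% of beats flagged")
    s2 <- rr_like(s, s$beat_time[!mask], s$rr[!mask], s$flag[!mask])
    s3 <- interpolate_gaps(s2, config)
    log <- rbind(log, data.frame(
      pass = pass, duplicates = n_dup, outliers = sum(mask),
      interpolated = sum(s3$flag == "interpolated") -
        sum(s2$flag == "interpolated")))
    n_dup <- 0L
    s <- s3
  }
  attr(s, "cleaning_log") <- log
  s
}

#' Root mean square of successive differences (RMSSD)
#'
#' The standard time-domain vagal-tone index:
#' `sqrt(mean(diff(rr)^2))` over the beats whose time falls in
#' `[start_s, end_s)`. Interpolated beats count like any other.
#'
#' @param series an [rr_series()].
#' @param window numeric `c(start_s, end_s)`; `NULL` uses the whole
#'   recording.
#' @return RMSSD in milliseconds.
#' @export
rmssd <- function(series, window = NULL) {
  stopifnot(inherits(series, "rr_series"))
  rr <- if (is.null(window)) series$rr else
    series$rr[series$beat_time >= window[1] & series$beat_time < window[2]]
  if (length(rr) < 3) stop("need at least 3 beats in the window")
  sqrt(mean(diff(rr)^2))
}
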