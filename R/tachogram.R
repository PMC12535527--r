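#' Resample an RR series onto a uniform grid
#'
#' Spectral analysis needs an evenly sampled interbeat-interval (IBI)
#' signal. The cleaned series is interpolated with a cubic spline
#' through the (beat time, RR) points and evaluated on a uniform grid
#' at `fs` Hz over the half-open window `[start_s, end_s)`; grid
#' points outside the beat range fall back to linear extrapolation
#' from the two nearest beats.
#'
#' @param series a cleaned [rr_series()].
#' @param fs sampling rate, Hz (default 4; Nyquist 2 Hz covers all
#'   HRV bands).
#' @param window numeric `c(start_s, end_s)`.
#' @param max_gap_s largest tolerated beat spacing inside the window;
#'   a larger hole means the cleaning stage failed and resampling
#'   would fabricate data (default 2 s for humans; pass a larger
#'   value for horses, whose resting RR approaches 1.6 s).
#' @return a list of class `"tachogram"`: `t` (absolute seconds),
#'   `ibi` (ms), `fs`.
#' @export
resample_ibi <- function(series, fs = 4, window, max_gap_s = NULL) {
  stopifnot(inherits(series, "rr_series"), length(window) == 2)
  sel <- series$beat_time >= window[1] - 5 & series$beat_time < window[2] + 5
  bt <- series$beat_time[sel]; rr <- series$rr[sel]
  keep <- !duplicated(bt)
  bt <- bt[keep]; rr <- rr[keep]
  if (length(bt) < 4) stop("too few beats covering the window")
  if (bt[1] > window[1] + 2 || bt[length(bt)] < window[2] - 2)
    stop("cleaned series does not cover the window")
  if (is.null(max_gap_s))
    max_gap_s <- max(2, 2.5 * stats::median(rr) / 1000)
  inside <- bt >= window[1] & bt < window[2]
  if (any(diff(bt[inside]) > max_gap_s))
    stop("coverage gap larger than ", max_gap_s, " s inside the window")
  n <- round((window[2] - window[1]) * fs)
  tout <- window[1] + (seq_len(n) - 1) / fs
  ibi <- numeric(n)
  inrange <- tout >= bt[1] & tout <= bt[length(bt)]
  if (any(inrange))
    ibi[inrange] <- stats::spline(bt, rr, xout = tout[inrange],
                                  method = "fmm", ties = mean)$y
  if (any(!inrange)) {
    m <- length(bt)
    lo <- tout < bt[1]
    if (any(lo)) {
      sl <- (rr[2] - rr[1]) / (bt[2] - bt[1])
      ibi[lo] <- rr[1] + sl * (tout[lo] - bt[1])
    }
    hi <- tout > bt[m]
    if (any(hi)) {
      sl <- (rr[m] - rr[m - 1]) / (bt[m] - bt[m - 1])
      ibi[hi] <- rr[m] + sl * (tout[hi] - bt[m])
    }
  }
  structure(list(t = tout, ibi = ibi, fs = fs), class = "tachogram")
}

#' @export
print.tachogram <- function(x, ...) {
  cat(sprintf("<tachogram> %d samples @ %g Hz, %.1f-%.1f s, mean IBI %.0f ms\n",
              length(x$t), x$fs, x$t[1], x$t[length(x$t)], mean(x$ibi)))
  invisible(x)
}
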