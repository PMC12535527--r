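#' HRV frequency-band boundaries
#'
#' The analysis splits the classical HRV bands in two: the standard
#' high-frequency band 0.15-0.40 Hz becomes lower HF (LHF) and upper
#' HF (UHF), and the low-frequency band 0.04-0.15 Hz becomes lower LF
#' (LLF) and upper LF (ULF). The HF edge at 0.15 Hz corresponds to a
#' wavelet period of 1/0.15 = 6.67 s. The sub-band splits default to
#' the geometric midpoints of the parent bands. All bands are
#' half-open in frequency: `[low, high)`.
#'
#' @param lf_low,lf_split,hf_low,hf_split,hf_high boundaries in Hz.
#' @return list of class `"frequency_bands"`.
#' @export
frequency_bands <- function(lf_low = 0.04, lf_split = 0.0775,
                            hf_low = 0.15, hf_split = 0.245,
                            hf_high = 0.40) {
  if (!(lf_low < lf_split && lf_split < hf_low &&
        hf_low < hf_split && hf_split < hf_high))
    stop("band boundaries must be strictly increasing")
  structure(list(lf_low = lf_low, lf_split = lf_split, hf_low = hf_low,
                 hf_split = hf_split, hf_high = hf_high),
            class = "frequency_bands")
}

#' Assign wavelet periods to HRV bands
#'
#' Maps each period (s) to a band label by its frequency
#' `f = 1/period` using half-open intervals `[low, high)`:
#' LLF `[lf_low, lf_split)`, ULF `[lf_split, hf_low)`,
#' LHF `[hf_low, hf_split)`, UHF `[hf_split, hf_high)`; frequencies
#' outside `[lf_low, hf_high)` are labelled `"out"`.
#'
#' @param period numeric periods in seconds.
#' @param bands a [frequency_bands()].
#' @return character vector of labels.
#' @export
band_partition <- function(period, bands = frequency_bands()) {
  f <- 1 / period
  lab <- rep("out", length(period))
  lab[f >= bands$lf_low  & f < bands$lf_split] <- "LLF"
  lab[f >= bands$lf_split & f < bands$hf_low]  <- "ULF"
  lab[f >= bands$hf_low  & f < bands$hf_split] <- "LHF"
  lab[f >= bands$hf_split & f < bands$hf_high] <- "UHF"
  lab
}

#' Extract mean cross-wavelet power per 10-second interval
#'
#' The synchrony measurements entering the statistical models: over
#' the first 240 s of the lying segment, the cross-power grid is cut
#' into 4 minutes x 6 ten-second intervals (half-open in time), and
#' for each interval and each analysed band the mean power is taken
#' over the grid cells whose period lies in the band and which fall
#' inside the cone of influence. Cells outside the cone are dropped,
#' not zero-filled; intervals losing more than half their cells are
#' flagged.
#'
#' @param xwt an [cross_wavelet()] result covering the window.
#' @param timeline segment timeline containing a `lying` segment of at
#'   least 240 s.
#' @param bands a [frequency_bands()].
#' @param use_bands band labels to extract (default the HF pair).
#' @return data.frame with columns `minute` (1-4), `interval` (1-6),
#'   `band`, `power`, `n_cells`, `coi_frac` (fraction of cells
#'   excluded by the cone), `flagged`.
#' @export
extract_interval_power <- function(xwt, timeline,
                                   bands = frequency_bands(),
                                   use_bands = c("LHF", "UHF")) {
  stopifnot(inherits(xwt, "xwt"))
  lying <- timeline_segment(timeline, "lying")
  if (lying["end"] - lying["start"] < 240)
    stop("lying segment shorter than 240 s")
  t0 <- lying[["start"]]
  lab <- band_partition(xwt$period, bands)
  inside_coi <- outer(xwt$period, xwt$coi, `<=`)  # scales x time
  rows <- expand.grid(minute = 1:4, interval = 1:6,
                      band = use_bands, stringsAsFactors = FALSE)
  rows <- rows[order(rows$minute, rows$interval, rows$band), ]
  rownames(rows) <- NULL
  rows$power <- NA_real_; rows$n_cells <- 0L
  rows$coi_frac <- NA_real_; rows$flagged <- FALSE
  for (i in seq_len(nrow(rows))) {
    a <- t0 + (rows$minute[i] - 1) * 60 + (rows$interval[i] - 1) * 10
    tsel <- xwt$time >= a & xwt$time < a + 10
    ssel <- lab == rows$band[i]
    if (!any(tsel) || !any(ssel)) stop("empty band/time selection")
    sub_p <- xwt$power[ssel, tsel, drop = FALSE]
    sub_c <- inside_coi[ssel, tsel, drop = FALSE]
    rows$coi_frac[i] <- 1 - mean(sub_c)
    rows$n_cells[i] <- sum(sub_c)
    rows$flagged[i] <- rows$coi_frac[i] > 0.5
    rows$power[i] <- if (any(sub_c)) mean(sub_p[sub_c]) else NA_real_
  }
  rows
}

#' Z-score log cross-wavelet power within strata
#'
#' Wavelet power is strongly right-skewed, so the power is logged and
#' then z-scored within each stratum using the sample standard
#' deviation; the default stratum is the dyad type, pooled across
#' sessions so that between-participant differences survive
#' normalisation. A stratum with zero spread gets all
#' zeros.
#'
#' @param rows data.frame with a `power` column (positive).
#' @param stratum character vector of grouping column names present in
#'   `rows`; empty for a single stratum.
#' @return `rows` with a `cwp_z` column appended.
#' @export
ztransform_power <- function(rows, stratum = "dyad") {
  stopifnot(is.data.frame(rows), "power" %in% names(rows))
  ok <- !is.na(rows$power)
  if (any(rows$power[ok] <= 0)) stop("power must be positive")
  stratum <- intersect(stratum, names(rows))
  key <- if (length(stratum))
    interaction(rows[stratum], drop = TRUE) else factor(rep(1, nrow(rows)))
  lp <- log(rows$power)
  z <- rep(NA_real_, nrow(rows))
  for (g in levels(key)) {
    idx <- which(key == g & ok)
    if (length(idx) < 2) stop("need >= 2 rows per stratum")
    s <- stats::sd(lp[idx])
    z[idx] <- if (s > 0) (lp[idx] - mean(lp[idx])) / s else 0
  }
  rows$cwp_z <- z
  rows
}

#' Circular phase statistics over a band and time window
#'
#' Summarises the cross-wavelet phase over the in-cone cells of a band
#' and window by the circular mean angle and the resultant length
#' (concentration, 1 = all cells in phase agreement). Phase 0 means
#' in-phase synchrony, pi anti-phase.
#'
#' @param xwt an [cross_wavelet()] result.
#' @param band band label (see [band_partition()]).
#' @param window numeric `c(start_s, end_s)`; `NULL` for the full
#'   time axis.
#' @param bands a [frequency_bands()].
#' @return list with `mean_phase` (radians) and `concentration`
#'   (`[0, 1]`).
#' @export
phase_stats <- function(xwt, band, window = NULL,
                        bands = frequency_bands()) {
  stopifnot(inherits(xwt, "xwt"))
  ssel <- band_partition(xwt$period, bands) == band
  tsel <- if (is.null(window)) rep(TRUE, length(xwt$time)) else
    xwt$time >= window[1] & xwt$time < window[2]
  inside <- outer(xwt$period, xwt$coi, `<=`)[ssel, tsel, drop = FALSE]
  ph <- xwt$phase[ssel, tsel, drop = FALSE][inside]
  if (!length(ph)) stop("empty band/window selection inside the cone")
  z <- mean(exp(1i * ph))
  list(mean_phase = Arg(z), concentration = Mod(z))
}
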