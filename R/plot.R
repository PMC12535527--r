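#' Plot a cross-wavelet power map
#'
#' Time-period heat map of cross-wavelet power (log2 colour scale,
#' warm colours = strong co-oscillation), with the cone of influence
#' shaded, significance contours drawn where a `sig_mask` is present,
#' and phase arrows on a subsampled grid (rightward = in-phase,
#' leftward = anti-phase). The period axis is logarithmic and
#' inverted, the usual orientation for these maps; dashed horizontal
#' lines mark the analysed band edges.
#'
#' @param x an `"xwt"` object.
#' @param bands a [frequency_bands()] drawn as guide lines (`NULL` to
#'   omit).
#' @param arrows draw phase arrows?
#' @param arrow_density approximate arrow grid `c(n_time, n_period)`.
#' @param main plot title.
#' @param ... unused.
#' @return invisibly, `x`.
#' @export
plot.xwt <- function(x, bands = frequency_bands(), arrows = TRUE,
                     arrow_density = c(24, 12),
                     main = "Cross-wavelet power", ...) {
  lp <- log2(x$period)
  pw <- log2(pmax(x$power, 1e-12))
  pal <- grDevices::hcl.colors(64, "Spectral", rev = TRUE)
  graphics::image(x$time, lp, t(pw), col = pal,
                  xlab = "Time (s)", ylab = "Period (s)",
                  yaxt = "n", ylim = rev(range(lp)), main = main)
  at <- pretty(lp)
  graphics::axis(2, at = at, labels = signif(2^at, 2))
  # cone of influence: shade the unreliable region
  graphics::lines(x$time, log2(x$coi), lty = 1, lwd = 1.5, col = "white")
  ymax <- max(lp)
  graphics::polygon(c(x$time, rev(x$time)),
                    c(pmin(log2(x$coi), ymax), rep(ymax, length(x$time))),
                    border = NA, col = grDevices::adjustcolor("black", 0.25))
  if (!is.null(x$sig_mask))
    graphics::contour(x$time, lp, t(x$sig_mask + 0), levels = 0.5,
                      add = TRUE, drawlabels = FALSE, col = "white",
                      lwd = 2)
  if (!is.null(bands)) {
    for (f in c(bands$hf_low, bands$hf_high))
      graphics::abline(h = log2(1 / f), lty = 2, col = "grey30")
  }
  if (arrows) {
    ti <- unique(round(seq(1, length(x$time), length.out = arrow_density[1])))
    si <- unique(round(seq(1, length(x$period), length.out = arrow_density[2])))
    dx <- diff(range(x$time)) / 40
    dy <- diff(range(lp)) / 40
    for (i in si) for (j in ti) {
      if (x$period[i] > x$coi[j]) next
      ph <- x$phase[i, j]
      graphics::arrows(x$time[j] - dx * cos(ph) / 2,
                       lp[i] + dy * sin(ph) / 2,
                       x$time[j] + dx * cos(ph) / 2,
                       lp[i] - dy * sin(ph) / 2,
                       length = 0.04, col = "black")
    }
  }
  invisible(x)
}
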