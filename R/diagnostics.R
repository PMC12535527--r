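#' Model assumption diagnostics
#'
#' Numeric counterparts of the usual visual checks on a fitted
#' mixed model: residual normality (skewness, excess kurtosis and a
#' Shapiro-Wilk statistic on a capped subsample), homoscedasticity (a
#' Brown-Forsythe-type F statistic across fitted-value bins),
#' multicollinearity (variance-inflation factors among the fixed
#' predictors, with aliasing detection), and the count of extreme
#' standardized residuals (|z| > 4). The report is advisory: mixed
#' models are robust to mild violations, so nothing here blocks an
#' analysis.
#'
#' @param fit an `"hrv_mlm"` object.
#' @param n_shapiro cap on the subsample for the Shapiro-Wilk test.
#' @param n_bins fitted-value bins for the heteroscedasticity check.
#' @param seed seed for the subsample draw.
#' @return list of class `"hrv_diagnostics"`.
#' @export
assumption_checks <- function(fit, n_shapiro = 3000, n_bins = 4,
                              seed = 1L) {
  stopifnot(inherits(fit, "hrv_mlm"))
  if (!fit$converged) stop("diagnostics need a converged fit")
  res <- stats::residuals(fit$fit)
  fitv <- stats::fitted(fit$fit)
  n <- length(res)
  z <- (res - mean(res)) / stats::sd(res)
  skew <- mean(z^3)
  exkurt <- mean(z^4) - 3

  sub <- if (n > n_shapiro)
    withr_seed(seed, sample(n, n_shapiro)) else seq_len(n)
  sw <- stats::shapiro.test(res[sub])

  # Brown-Forsythe across fitted-value bins: absolute deviation from
  # the bin median, one-way F; skipped when the fitted values are too
  # concentrated to form distinct bins
  breaks <- unique(stats::quantile(fitv,
                                   probs = seq(0, 1, length.out = n_bins + 1)))
  bf <- list(statistic = NA_real_, p.value = NA_real_)
  if (length(breaks) >= 3) {
    bins <- cut(fitv, breaks, include.lowest = TRUE)
    admed <- abs(res - stats::ave(res, bins, FUN = stats::median))
    bf <- tryCatch(stats::oneway.test(admed ~ bins, var.equal = TRUE),
                   error = function(e) bf)
  }

  # VIF from the correlation matrix of non-constant fixed-effect columns;
  # columns the fitter dropped for rank deficiency are reported aliased
  x <- as.matrix(lme4::getME(fit$fit, "X"))
  full <- stats::model.matrix(lme4::nobars(stats::formula(fit$fit)),
                              stats::model.frame(fit$fit))
  aliased <- setdiff(colnames(full), colnames(x))
  keep <- apply(x, 2, stats::sd) > 0
  vif <- NULL
  if (sum(keep) >= 2) {
    cx <- stats::cor(x[, keep, drop = FALSE])
    qrx <- qr(cx)
    if (qrx$rank < ncol(cx)) {
      aliased <- union(aliased,
                       colnames(cx)[qrx$pivot[seq(qrx$rank + 1, ncol(cx))]])
    } else {
      vif <- stats::setNames(diag(solve(cx)), colnames(cx))
    }
  } else if (sum(keep) == 1) {
    vif <- stats::setNames(1, colnames(x)[keep])
  }

  structure(list(n = n,
                 skewness = skew, excess_kurtosis = exkurt,
                 shapiro_w = unname(sw$statistic), shapiro_p = sw$p.value,
                 bf_f = unname(bf$statistic), bf_p = bf$p.value,
                 vif = vif, aliased = aliased,
                 n_outliers = sum(abs(z) > 4)),
            class = "hrv_diagnostics")
}

#' @export
print.hrv_diagnostics <- function(x, ...) {
  cat("<hrv_diagnostics>\n")
  cat(sprintf("  residuals (n = %d): skew %.3f, excess kurtosis %.3f\n",
              x$n, x$skewness, x$excess_kurtosis))
  cat(sprintf("  Shapiro-Wilk W = %.4f (p = %.3g, capped subsample)\n",
              x$shapiro_w, x$shapiro_p))
  cat(sprintf("  Brown-Forsythe F = %.3f (p = %.3g) across fitted bins\n",
              x$bf_f, x$bf_p))
  if (length(x$aliased))
    cat("  ALIASED predictors:", paste(x$aliased, collapse = ", "), "\n")
  else if (!is.null(x$vif))
    cat(sprintf("  max VIF = %.2f\n", max(x$vif)))
  cat(sprintf("  |z| > 4 outliers: %d\n", x$n_outliers))
  invisible(x)
}

#' Residual diagnostic plots
#'
#' QQ plot, residual-vs-fitted scatter and a residual histogram for a
#' fitted model, written to a PNG file or drawn on the active device.
#'
#' @param fit an `"hrv_mlm"` object.
#' @param file optional PNG path; `NULL` draws on the current device.
#' @return invisibly, the file path (or `NULL`).
#' @export
diagnostic_plots <- function(fit, file = NULL) {
  stopifnot(inherits(fit, "hrv_mlm"))
  res <- stats::residuals(fit$fit)
  fitv <- stats::fitted(fit$fit)
  if (!is.null(file)) {
    grDevices::png(file, width = 1200, height = 420)
    on.exit(grDevices::dev.off())
  }
  op <- graphics::par(mfrow = c(1, 3))
  on.exit(graphics::par(op), add = TRUE)
  stats::qqnorm(res, main = "Normal QQ"); stats::qqline(res)
  plot(fitv, res, pch = ".", xlab = "fitted", ylab = "residual",
       main = "Residuals vs fitted")
  graphics::abline(h = 0, lty = 2)
  graphics::hist(res, breaks = 40, main = "Residuals", xlab = "residual")
  invisible(file)
}
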