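#' Build a model-ready design table for one response dyad
#'
#' Takes the long band-power table, keeps the rows of the response
#' dyad, and (optionally) aligns another dyad's synchrony as a
#' row-wise predictor by the hierarchical key
#' (participant, session, minute, interval, band) - the "other-dyad
#' synchrony" transfer predictor. Design variables are returned as
#' factors with treatment coding (reference = first sorted level);
#' rows with missing predictors are dropped and counted in the
#' `"n_dropped"` attribute.
#'
#' @param table a `"band_power"` data.frame with `cwp_z`.
#' @param response_dyad dyad whose `cwp_z` is the response.
#' @param predictor_dyad optional dyad whose `cwp_z` becomes the
#'   `sync_other` column.
#' @return data.frame with `cwp_z`, factors `session`, `minute`,
#'   `interval`, `band`, ids, covariates, and `sync_other` when
#'   requested.
#' @export
build_design <- function(table, response_dyad,
                         predictor_dyad = NULL) {
  stopifnot(is.data.frame(table),
            all(c("dyad", "cwp_z", "minute", "interval", "band") %in%
                  names(table)))
  key_cols <- c("participant_id", "session_id", "minute", "interval", "band")
  resp <- table[table$dyad == response_dyad, , drop = FALSE]
  if (!nrow(resp)) stop("no rows for response dyad '", response_dyad, "'")
  n0 <- nrow(resp)
  if (!is.null(predictor_dyad)) {
    pred <- table[table$dyad == predictor_dyad, , drop = FALSE]
    key_r <- do.call(paste, c(resp[key_cols], sep = "\r"))
    key_p <- do.call(paste, c(pred[key_cols], sep = "\r"))
    if (anyDuplicated(key_p)) {
      dup <- key_p[duplicated(key_p)]
      stop("misaligned dyad rows: duplicate predictor keys ",
           paste(utils::head(gsub("\r", "/", dup), 3), collapse = ", "))
    }
    resp$sync_other <- pred$cwp_z[match(key_r, key_p)]
    resp <- resp[!is.na(resp$sync_other), , drop = FALSE]
  }
  resp <- resp[!is.na(resp$cwp_z), , drop = FALSE]
  out <- resp
  out$session <- factor(out$session_index %||% 1L)
  out$minute <- factor(out$minute)
  out$interval <- factor(out$interval)
  out$band <- factor(out$band)
  if ("group" %in% names(out)) out$group <- factor(out$group)
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n0 - nrow(out)
  out
}

#' Fit one repeated-measures multi-level model
#'
#' A thin, audited wrapper around [lme4::lmer()] with maximum
#' likelihood estimation (`REML = FALSE`, required for the
#' likelihood-ratio ladder). Fixed-effect confidence intervals and
#' p-values use the Wald normal approximation (the within-group
#' sample sizes here are large). If a random-slope structure yields a
#' singular fit, the model is refitted with random intercepts only
#' and the fallback is recorded.
#'
#' @param formula an `lmer` model formula (response on `cwp_z` scale).
#' @param data the design table from [build_design()].
#' @param ci_level confidence level for Wald intervals.
#' @return object of class `"hrv_mlm"`: `fit` (the merMod),
#'   `estimates` (term/estimate/se/ci/p), `varcomp`, `loglik`, `aic`,
#'   `n_obs`, `n_groups`, `r2_marginal`, `r2_conditional`,
#'   `converged`, `singular_fallback`.
#' @export
fit_mlm <- function(formula, data, ci_level = 0.95) {
  fit <- suppressMessages(lme4::lmer(formula, data = data, REML = FALSE))
  fallback <- FALSE
  if (lme4::isSingular(fit, tol = 1e-4) && has_random_slope(formula)) {
    formula2 <- strip_random_slopes(formula)
    fit <- suppressMessages(lme4::lmer(formula2, data = data, REML = FALSE))
    fallback <- TRUE
  }
  msgs <- fit@optinfo$conv$lme4$messages
  # a boundary (singular) fit is converged, just degenerate
  msgs <- msgs[!grepl("boundary \\(singular\\)", msgs)]
  conv <- length(msgs) == 0
  beta <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  zq <- stats::qnorm(1 - (1 - ci_level) / 2)
  est <- data.frame(term = names(beta), estimate = unname(beta),
                    se = unname(se),
                    ci_low = unname(beta - zq * se),
                    ci_high = unname(beta + zq * se),
                    p = 2 * stats::pnorm(-abs(unname(beta / se))),
                    stringsAsFactors = FALSE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  r2 <- r2_nakagawa_mer(fit)
  structure(list(fit = fit, formula = stats::formula(fit),
                 estimates = est, varcomp = vc,
                 loglik = as.numeric(stats::logLik(fit)),
                 npar = attr(stats::logLik(fit), "df"),
                 aic = stats::AIC(fit),
                 n_obs = stats::nobs(fit),
                 n_groups = lme4::ngrps(fit),
                 r2_marginal = r2[["r2_marginal"]],
                 r2_conditional = r2[["r2_conditional"]],
                 converged = conv,
                 singular_fallback = fallback),
            class = "hrv_mlm")
}

has_random_slope <- function(formula) {
  bars <- lme4::findbars(formula)
  any(vapply(bars, function(b) deparse(b[[2]]) != "1", logical(1)))
}

strip_random_slopes <- function(formula) {
  bars <- lme4::findbars(formula)
  groups <- unique(vapply(bars, function(b) deparse(b[[3]]), character(1)))
  fixed <- lme4::nobars(formula)
  re <- paste(sprintf("(1 | %s)", groups), collapse = " + ")
  stats::as.formula(paste(deparse(fixed, width.cutoff = 500), "+", re),
                    env = environment(formula))
}

#' @export
print.hrv_mlm <- function(x, ...) {
  cat(sprintf("<hrv_mlm> ML fit, n = %d, logLik = %.2f, AIC = %.1f\n",
              x$n_obs, x$loglik, x$aic))
  cat(sprintf("  R2 marginal = %.3f, conditional = %.3f%s%s\n",
              x$r2_marginal, x$r2_conditional,
              if (x$singular_fallback) " [slope->intercept fallback]" else "",
              if (!x$converged) " [NOT CONVERGED]" else ""))
  print(x$estimates, digits = 3, row.names = FALSE)
  invisible(x)
}

#' @export
summary.hrv_mlm <- function(object, ...) {
  print(object)
  cat("\nVariance components:\n")
  print(object$varcomp, digits = 3, row.names = FALSE)
  invisible(object)
}

#' @export
coef.hrv_mlm <- function(object, ...) {
  stats::setNames(object$estimates$estimate, object$estimates$term)
}

#' @export
residuals.hrv_mlm <- function(object, ...) stats::residuals(object$fit)

#' @export
fitted.hrv_mlm <- function(object, ...) stats::fitted(object$fit)

#' @export
logLik.hrv_mlm <- function(object, ...) stats::logLik(object$fit)

#' Marginal and conditional R-squared of a mixed model
#'
#' Variance-partition R-squared for Gaussian mixed models: the
#' marginal value is the fixed-effect variance share
#' `var_f / (var_f + var_r + var_e)` and the conditional value adds
#' the random-effect variance to the numerator. `var_f` is the
#' variance of the fixed-effect linear predictor over the data and
#' `var_r` the mean, over observations, of the random-effect variance
#' implied by the fitted covariance parameters.
#'
#' @param fit an `"hrv_mlm"` object (converged).
#' @return named numeric `c(r2_marginal, r2_conditional)`.
#' @export
r2_nakagawa <- function(fit) {
  stopifnot(inherits(fit, "hrv_mlm"))
  if (!fit$converged) stop("cannot compute R2 for a non-converged fit")
  r2_nakagawa_mer(fit$fit)
}

r2_nakagawa_mer <- function(mer) {
  x <- lme4::getME(mer, "X")
  var_f <- stats::var(as.vector(x %*% lme4::fixef(mer)))
  # per-observation random-effect variance: diag(Z Lambda Lambda' Z') * sigma^2
  z <- lme4::getME(mer, "Z")
  lt <- lme4::getME(mer, "Lambdat")
  m <- z %*% Matrix::t(lt)
  var_r <- mean(Matrix::rowSums(m^2)) * stats::sigma(mer)^2
  var_e <- stats::sigma(mer)^2
  tot <- var_f + var_r + var_e
  c(r2_marginal = var_f / tot, r2_conditional = (var_f + var_r) / tot)
}

#' Likelihood-ratio comparison of two nested ML fits
#'
#' @param fit_reduced,fit_full `"hrv_mlm"` fits of nested models on
#'   identical rows, both by maximum likelihood.
#' @return list with `chi2` (floored at 0), `df` (parameter-count
#'   difference) and `p`.
#' @export
compare_models <- function(fit_reduced, fit_full) {
  stopifnot(inherits(fit_reduced, "hrv_mlm"), inherits(fit_full, "hrv_mlm"))
  if (fit_reduced$n_obs != fit_full$n_obs)
    stop("models were fitted on different numbers of rows")
  df <- fit_full$npar - fit_reduced$npar
  if (df < 0) stop("'fit_full' has fewer parameters than 'fit_reduced'")
  chi2 <- max(0, 2 * (fit_full$loglik - fit_reduced$loglik))
  p <- if (df == 0) as.numeric(chi2 <= 0) else
    stats::pchisq(chi2, df, lower.tail = FALSE)
  list(chi2 = chi2, df = df, p = p)
}

#' Fit a hierarchical ladder of nested models
#'
#' Implements the sequential model-building strategy: start from a
#' null model, add terms step by step, and keep each step only if the
#' likelihood-ratio ANOVA against the current best model is
#' significant at `alpha`. Covariate screening is expressed the same
#' way: make each covariate one rung of the ladder.
#'
#' @param data design table from [build_design()].
#' @param ladder named list of model formulas, ordered from null to
#'   richest; each must nest the previous kept model.
#' @param alpha per-step significance level (default 0.05).
#' @return object of class `"hrv_ladder"`: `fits`, `comparison`
#'   (model/npar/loglik/aic/chi2/df/p/kept), `best` (name),
#'   `best_fit`.
#' @export
model_ladder <- function(data, ladder, alpha = 0.05) {
  stopifnot(is.list(ladder), length(ladder) >= 1)
  if (is.null(names(ladder)))
    names(ladder) <- paste0("M", seq_along(ladder) - 1)
  fits <- list()
  comp <- NULL
  best <- NULL
  for (nm in names(ladder)) {
    fit <- tryCatch(fit_mlm(ladder[[nm]], data), error = function(e) e)
    if (inherits(fit, "error") || !fit$converged) {
      msg <- if (inherits(fit, "error")) conditionMessage(fit)
             else "did not converge"
      warning("ladder halted at '", nm, "': ", msg, call. = FALSE)
      break
    }
    fits[[nm]] <- fit
    if (is.null(best)) {
      best <- nm
      comp <- rbind(comp, data.frame(
        model = nm, npar = fit$npar, loglik = fit$loglik, aic = fit$aic,
        chi2 = NA_real_, df = NA_integer_, p = NA_real_, kept = TRUE))
      next
    }
    lrt <- compare_models(fits[[best]], fit)
    kept <- lrt$p < alpha
    comp <- rbind(comp, data.frame(
      model = nm, npar = fit$npar, loglik = fit$loglik, aic = fit$aic,
      chi2 = lrt$chi2, df = lrt$df, p = lrt$p, kept = kept))
    if (kept) best <- nm
  }
  if (is.null(best)) stop("no model in the ladder could be fitted")
  rownames(comp) <- NULL
  structure(list(fits = fits, comparison = comp, best = best,
                 best_fit = fits[[best]], alpha = alpha),
            class = "hrv_ladder")
}

#' @export
print.hrv_ladder <- function(x, ...) {
  cat(sprintf("<hrv_ladder> %d models, best = '%s' (alpha = %g)\n",
              nrow(x$comparison), x$best, x$alpha))
  print(x$comparison, digits = 4, row.names = FALSE)
  invisible(x)
}
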