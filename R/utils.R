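#' Derive a child seed from a master seed and a tag path
#'
#' All randomness in the package flows from a single master seed through
#' this function, so that every subject/session/component draws from its
#' own reproducible stream. The derivation is a simple multiplicative
#' string hash folded into the master seed, kept below 2^31 - 1.
#'
#' @param master integer master seed.
#' @param ... character or numeric tags naming the consumer
#'   (e.g. `"subject"`, 3, `"hf"`).
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, ...) {
  tags <- unlist(lapply(list(...), as.character), use.names = FALSE)
  h <- as.double(master) %% 2147483647
  for (tag in tags) {
    for (b in utf8ToInt(tag)) h <- (h * 31 + b) %% 2147483647
  }
  as.integer(h)
}

#' Lag-1 sample autocorrelation
#' @param x numeric vector.
#' @return scalar lag-1 autocorrelation.
#' @export
ar1_coef <- function(x) {
  x <- x - mean(x)
  n <- length(x)
  sum(x[-1] * x[-n]) / sum(x^2)
}

#' Simulate a stationary AR(1) series
#'
#' Used for red-noise surrogates in the Monte-Carlo significance method
#' and in the calibration experiments.
#'
#' @param n length.
#' @param a lag-1 autocorrelation, |a| < 1.
#' @param sd marginal standard deviation.
#' @return numeric vector of length `n`.
#' @export
ar1_sim <- function(n, a, sd = 1) {
  stopifnot(abs(a) < 1)
  innov_sd <- sd * sqrt(1 - a^2)
  as.numeric(stats::filter(stats::rnorm(n, 0, innov_sd), a,
                           method = "recursive",
                           init = stats::rnorm(1, 0, sd)))
}

# Unit-variance narrowband Gaussian-envelope oscillation at centre
# frequency f0 (Hz), built by spectral shaping of white noise.
narrowband_noise <- function(n, dt, f0, rel_bw = 0.2) {
  stopifnot(n > 8, f0 > 0, f0 < 1 / (2 * dt))
  white <- stats::rnorm(n)
  xf <- stats::fft(white)
  f <- (seq_len(n) - 1) / (n * dt)
  f[f > 1 / (2 * dt)] <- f[f > 1 / (2 * dt)] - 1 / dt
  sd_f <- max(0.01, rel_bw * f0)
  h <- exp(-((abs(f) - f0)^2) / (2 * sd_f^2))
  x <- Re(stats::fft(xf * h, inverse = TRUE)) / n
  x / stats::sd(x)
}

next_pow2 <- function(n) 2^ceiling(log2(n))

`%||%` <- function(a, b) if (is.null(a)) b else a
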