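#' Bursting parameter vector
#'
#' The kinetic state of one gene under the instantaneous-burst limit of the
#' two-state (telegraph) model, parameterised as `theta = (mu, a, gamma)`:
#' mean expression level `mu` (transcripts per cell), burst rate `a` (bursts
#' per transcript lifetime) and transcript lifetime `gamma` (minutes).
#' Derived quantities are burst size `b = mu / a` (transcripts per burst),
#' decay rate `delta = 1 / gamma` (per minute) and burst frequency
#' `kappa = a * delta` (bursts per minute).
#'
#' @param mu Mean transcripts per cell; must be positive.
#' @param a Burst rate in bursts per transcript lifetime; must be positive.
#' @param gamma Transcript lifetime in minutes; must be at least 1 (the
#'   lower edge of the uniform prior used during inference).
#' @return An object of class `burst_params`.
#' @examples
#' p <- burst_params(mu = 25, a = 0.5, gamma = 1000)
#' burst_size(p)       # 50
#' burst_frequency(p)  # 5e-4 per minute
#' @export
burst_params <- function(mu, a, gamma = 1) {
  if (!is.numeric(mu) || length(mu) != 1L || !is.finite(mu) || mu <= 0)
    stop("'mu' must be a single positive number")
  if (!is.numeric(a) || length(a) != 1L || !is.finite(a) || a <= 0)
    stop("'a' must be a single positive number")
  if (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma) || gamma < 1)
    stop("'gamma' must be a single number >= 1")
  structure(list(mu = as.numeric(mu), a = as.numeric(a),
                 gamma = as.numeric(gamma)),
            class = "burst_params")
}

#' Build a parameter vector from burst size, frequency and decay rate
#'
#' @param b Burst size (transcripts per burst).
#' @param kappa Burst frequency (bursts per minute).
#' @param delta Decay rate (per minute).
#' @return A [burst_params] object with `mu = b * kappa / delta`,
#'   `a = kappa / delta`, `gamma = 1 / delta`.
#' @export
burst_params_from_rates <- function(b, kappa, delta) {
  burst_params(mu = b * kappa / delta, a = kappa / delta, gamma = 1 / delta)
}

#' @export
print.burst_params <- function(x, ...) {
  cat(sprintf(
    "burst_params: mu=%.4g  a=%.4g  gamma=%.4g  (b=%.4g, kappa=%.4g, delta=%.4g)\n",
    x$mu, x$a, x$gamma, burst_size(x), burst_frequency(x), decay_rate(x)))
  invisible(x)
}

#' Derived bursting quantities
#'
#' @param params A [burst_params] object.
#' @param t Pulse duration in minutes (for [dimensionless_time]).
#' @return A single numeric value.
#' @name derived-params
NULL

#' @rdname derived-params
#' @export
burst_size <- function(params) params$mu / params$a

#' @rdname derived-params
#' @export
decay_rate <- function(params) 1 / params$gamma

#' @rdname derived-params
#' @export
burst_frequency <- function(params) params$a / params$gamma

#' @rdname derived-params
#' @export
dimensionless_time <- function(params, t) {
  if (!is.numeric(t) || t < 0) stop("'t' must be a nonnegative duration")
  t / params$gamma
}

#' T>C conversion rate settings
#'
#' Bundles the per-uracil conversion probabilities and the 4sU pulse
#' duration: `lambda_s`, the gene-specific background T>C rate observed in
#' an unlabelled control; `lambda_n`, the additional, gene-invariant rate
#' caused by 4sU incorporation; and `t`, the labelling pulse duration in
#' minutes.
#'
#' @param lambda_s Background conversion probability per genomic T, in `[0, 1)`.
#' @param lambda_n 4sU-induced conversion probability per genomic T, in `[0, 1)`.
#' @param t Pulse duration in minutes, strictly positive.
#' @return An object of class `conversion_rates`.
#' @export
conversion_rates <- function(lambda_s, lambda_n, t) {
  if (!is.numeric(lambda_s) || lambda_s < 0 || lambda_s >= 1)
    stop("'lambda_s' must lie in [0, 1)")
  if (!is.numeric(lambda_n) || lambda_n < 0 || lambda_n >= 1)
    stop("'lambda_n' must lie in [0, 1)")
  if (!is.numeric(t) || t <= 0) stop("'t' must be a positive duration")
  structure(list(lambda_s = as.numeric(lambda_s),
                 lambda_n = as.numeric(lambda_n), t = as.numeric(t)),
            class = "conversion_rates")
}
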