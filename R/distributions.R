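#' @useDynLib slamburst, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats dnbinom pnbinom qnbinom dpois ppois qpois dbinom rnorm
#'   runif rbinom rpois rbeta rnbinom sd quantile density
NULL

# Probabilities are floored at this value before logging so MCMC can
# traverse deep low-likelihood regions without -Inf arithmetic; clip
# events are counted in a package-level tally (see clip_count()).
.PROB_FLOOR <- 1e-300

.slamburst_state <- new.env(parent = emptyenv())
.slamburst_state$clips <- 0

.clip_log <- function(p) {
  low <- p < .PROB_FLOOR
  if (any(low)) {
    .slamburst_state$clips <- .slamburst_state$clips + sum(low)
    p[low] <- .PROB_FLOOR
  }
  log(p)
}

#' Number of probability-floor clip events so far
#'
#' Likelihood evaluations floor probabilities at 1e-300 before taking logs;
#' this returns (and optionally resets) the running count of floored values.
#'
#' @param reset If `TRUE`, zero the counter after reading it.
#' @return Integer count of clip events.
#' @export
clip_count <- function(reset = FALSE) {
  n <- .slamburst_state$clips
  if (reset) .slamburst_state$clips <- 0
  n
}

#' Steady-state transcript count distribution
#'
#' Under instantaneous geometric bursts arriving as a Poisson process the
#' stationary transcript count is negative binomial with shape `a` and
#' odds `b/(1+b)`: `P(m) = NB(m | a, b/(1+b))`.
#'
#' @param m Nonnegative integer count(s).
#' @param params A [burst_params] object.
#' @param log Return log probabilities?
#' @return Probability (or log probability) of each `m`.
#' @export
nb_steady_state <- function(m, params, log = FALSE) {
  stopifnot(inherits(params, "burst_params"))
  if (any(m < 0)) stop("'m' must be nonnegative")
  b <- burst_size(params)
  dnbinom(m, size = params$a, prob = 1 / (1 + b), log = log)
}

#' Finite state projection bound for the latent transcript count
#'
#' The smallest integer `M` at which the steady-state CDF reaches
#' `quantile`; sums over the latent count are truncated at `M`, leaving at
#' most `1 - quantile` of the mass outside (error 1e-4 at the default).
#'
#' @param params A [burst_params] object.
#' @param quantile Probability level in (0, 1); default 0.9999.
#' @return An object of class `fsp_bound` with elements `M`, `quantile`
#'   and `error = 1 - quantile`.
#' @export
fsp_bound <- function(params, quantile = 0.9999) {
  stopifnot(inherits(params, "burst_params"))
  if (quantile <= 0 || quantile >= 1) stop("'quantile' must be in (0, 1)")
  b <- burst_size(params)
  M <- qnbinom(quantile, size = params$a, prob = 1 / (1 + b))
  structure(list(M = as.integer(M), quantile = quantile,
                 error = 1 - quantile),
            class = "fsp_bound")
}

#' Capture model: observed UMIs given transcripts
#'
#' Poisson approximation to the binomial capture process:
#' `P(l | m, alpha) = Pois(l | m * alpha)`.  The approximation deliberately
#' assigns positive probability to `l > m`, which lets the sampler escape
#' regions where the projection bound falls below an observed count.
#'
#' @param l Observed UMI count(s), nonnegative.
#' @param m Latent transcript count, nonnegative.
#' @param alpha Cell capture efficiency in (0, 1].
#' @param log Return log probabilities?
#' @return Probability of each `l`.
#' @export
capture_pmf <- function(l, m, alpha, log = FALSE) {
  if (any(l < 0) || any(m < 0)) stop("counts must be nonnegative")
  if (any(alpha <= 0) || any(alpha > 1)) stop("'alpha' must be in (0, 1]")
  dpois(l, lambda = m * alpha, log = log)
}

#' Marginal UMI count distribution
#'
#' `P(l | alpha) = sum_{m=0}^{M} P(l | m, alpha) P(m)`, the capture model
#' compounded over the steady-state distribution, truncated at the finite
#' state projection bound.
#'
#' @inheritParams capture_pmf
#' @param params A [burst_params] object.
#' @param bound An [fsp_bound]; computed from `params` if omitted.
#' @param log Return log probabilities?
#' @return Probability of each `l`.
#' @export
umi_marginal <- function(l, alpha, params, bound = fsp_bound(params),
                         log = FALSE) {
  m <- 0:bound$M
  pm <- nb_steady_state(m, params)
  p <- vapply(l, function(li) sum(dpois(li, m * alpha) * pm), numeric(1))
  if (log) .clip_log(p) else p
}

#' Surviving transcripts given the initial count
#'
#' Each pre-pulse transcript independently survives a pulse of
#' dimensionless duration `tau = t / gamma` with probability `exp(-tau)`,
#' so `P(s | m) = Bin(s | m, exp(-tau))`.
#'
#' @param s Number of surviving transcripts, `0 <= s <= m` (0 returned
#'   outside this range).
#' @param m Initial transcript count.
#' @param tau Dimensionless pulse duration, `t * delta`.
#' @param log Return log probabilities?
#' @return Probability of each `s`.
#' @export
surviving_conditional <- function(s, m, tau, log = FALSE) {
  if (tau < 0) stop("'tau' must be nonnegative")
  dbinom(s, size = m, prob = exp(-tau), log = log)
}

#' Marginal surviving transcript distribution
#'
#' Binomial thinning of the negative binomial steady state is again
#' negative binomial with thinned odds:
#' `P(s) = NB(s | a, b e^{-tau} / (1 + b e^{-tau}))`, equal to the explicit
#' compound sum over `m` (exactly, not approximately).
#'
#' @inheritParams surviving_conditional
#' @param params A [burst_params] object.
#' @return Probability of each `s`.
#' @export
surviving_marginal <- function(s, params, tau, log = FALSE) {
  stopifnot(inherits(params, "burst_params"))
  if (tau < 0) stop("'tau' must be nonnegative")
  bt <- burst_size(params) * exp(-tau)
  dnbinom(s, size = params$a, prob = 1 / (1 + bt), log = log)
}

.instability_flag <- function(p) {
  bad <- !is.finite(p) | p < 0
  structure(list(unstable = any(bad),
                 first_negative_n = if (any(bad)) which(bad)[1] - 1L else NA_integer_),
            class = "instability_flag")
}

#' Newly synthesised transcript distribution (approximate)
#'
#' Approximate non-equilibrium solution for the number of transcripts made
#' during a pulse of dimensionless duration `tau`, involving a terminating
#' Gauss hypergeometric factor `2F1(-n, -a, 1-a-n; (1+b)/(e^tau+b))`.  The
#' approximation oscillates and can produce negative values when `a` and/or
#' `b` are large and/or `tau` is small ("unstable parameter space"); such
#' values are returned unaltered and reported through the instability flag
#' so callers can decide how to react.
#'
#' @param n Nonnegative integer count(s).
#' @param params A [burst_params] object.
#' @param tau Dimensionless pulse duration, strictly positive.
#' @return A list with `p` (values at each `n`, possibly negative when
#'   unstable) and `flag` (class `instability_flag` with elements
#'   `unstable` and `first_negative_n`).
#' @export
new_transcript_pmf <- function(n, params, tau) {
  stopifnot(inherits(params, "burst_params"))
  if (tau <= 0) stop("'tau' must be positive")
  if (any(n < 0)) stop("'n' must be nonnegative")
  nmax <- max(n)
  p_all <- new_pmf_cpp(as.integer(nmax), params$a, burst_size(params), tau)
  list(p = p_all[n + 1L], flag = .instability_flag(p_all))
}

#' Posterior over the latent transcript count given one cell's UMI count
#'
#' Bayes inversion of the capture and steady-state models, normalised over
#' the finite state projection support `0..M`.
#'
#' @inheritParams umi_marginal
#' @return Numeric vector of posterior probabilities over `m = 0..M`.
#' @export
posterior_m_given_l <- function(l, alpha, params, bound = fsp_bound(params)) {
  m <- 0:bound$M
  w <- dpois(l, m * alpha) * nb_steady_state(m, params)
  tot <- sum(w)
  if (tot <= 0)
    stop("observation (l = ", l, ") has zero marginal probability under ",
         "the projection bound M = ", bound$M)
  w / tot
}

#' New transcripts conditional on the total count
#'
#' `P(n | m) = P(n) P(s = m - n) / sum_n P(n) P(s = m - n)`; the normalising
#' convolution approximates the steady-state pmf and guarantees the
#' conditional sums to one.  Instability of the new-transcript pmf over
#' `0..m` propagates through the flag.
#'
#' @param m Total transcript count (single value).
#' @param params A [burst_params] object.
#' @param tau Dimensionless pulse duration.
#' @return List with `p` (vector over `n = 0..m`), `flag` and
#'   `normaliser` (the convolution value, approximately the steady-state
#'   probability of `m`).
#' @export
new_given_total <- function(m, params, tau) {
  if (m == 0) {
    return(list(p = 1, flag = .instability_flag(1), normaliser = 1))
  }
  np <- new_transcript_pmf(0:m, params, tau)
  ps <- surviving_marginal(m:0, params, tau)
  joint <- np$p * ps
  tot <- sum(joint)
  p <- if (tot > 0) joint / tot else rep(NA_real_, m + 1)
  list(p = p, flag = np$flag, normaliser = tot)
}

#' Uracil-content distribution of reads
#'
#' Distribution of the number of genomic T bases (`u`) covered by a read,
#' either empirical (tabulated from observed reads) or Poisson with mean
#' `u_hat` as used in simulation.  Support is truncated at the
#' `1 - 1e-8` quantile and renormalised so downstream sums are bounded.
#'
#' @param u Integer vector of per-read genomic-T counts (empirical form).
#' @param u_hat Poisson mean (simulation form).
#' @return An object of class `uracil_dist`: list with `u` (support) and
#'   `p` (probabilities summing to one).
#' @export
empirical_uracil_pmf <- function(u) {
  if (length(u) == 0 || any(u < 0)) stop("'u' must be nonnegative counts")
  tab <- tabulate(u + 1L)
  p <- tab / sum(tab)
  keep <- p > 0
  structure(list(u = (seq_along(p) - 1L)[keep], p = p[keep] / sum(p[keep])),
            class = "uracil_dist")
}

#' @rdname empirical_uracil_pmf
#' @export
poisson_uracil_pmf <- function(u_hat) {
  if (u_hat <= 0) stop("'u_hat' must be positive")
  umax <- qpois(1 - 1e-8, u_hat)
  p <- dpois(0:umax, u_hat)
  structure(list(u = 0:umax, p = p / sum(p)), class = "uracil_dist")
}

# Mixture over read uracil content of Poisson conversion counts at a given
# per-T rate: sum_u P(u) Pois(i | u * rate), vectorised over i.
.uconv_mix <- function(i, udist, rate) {
  stopifnot(inherits(udist, "uracil_dist"))
  lam <- udist$u * rate
  as.numeric(outer(i, lam, function(ii, ll) dpois(ii, ll)) %*% udist$p)
}

#' Conversion count distribution given the total transcript count
#'
#' Poisson mixture over read uracil content and transcript age: a read from
#' a cell with `m` transcripts of which `n` are new carries conversions
#' from rate `lambda_n + lambda_s` with probability `n/m`, else from the
#' background rate `lambda_s`; `n` is mixed over [new_given_total].  For
#' `m = 0` the background-only mixture is returned (a cell without
#' transcripts cannot contribute labelled reads).
#'
#' @param i Conversion count(s) per read.
#' @param m Total transcript count (single value).
#' @param params A [burst_params] object.
#' @param rates A [conversion_rates] object.
#' @param udist A `uracil_dist`.
#' @return List with `p` (probability of each `i`) and `flag`.
#' @export
conversions_given_m <- function(i, m, params, rates, udist) {
  stopifnot(inherits(rates, "conversion_rates"))
  A <- .uconv_mix(i, udist, rates$lambda_n + rates$lambda_s)
  B <- .uconv_mix(i, udist, rates$lambda_s)
  if (m == 0) {
    return(list(p = B, flag = .instability_flag(1)))
  }
  tau <- dimensionless_time(params, rates$t)
  ngt <- new_given_total(m, params, tau)
  w <- sum((0:m) * ngt$p) / m
  list(p = w * A + (1 - w) * B, flag = ngt$flag)
}

#' Conversion count distribution given a cell's UMI count
#'
#' Compounds [conversions_given_m] over the posterior of the latent count,
#' `P(i | l, alpha) = sum_{m=0}^{M} P(i | m) P(m | l, alpha)`.
#'
#' @inheritParams conversions_given_m
#' @param l Observed UMI count of the cell.
#' @param alpha Capture efficiency of the cell.
#' @param bound An [fsp_bound].
#' @return List with `p` and `flag`.
#' @export
conversions_given_umi <- function(i, l, alpha, params, rates, udist,
                                  bound = fsp_bound(params)) {
  post <- posterior_m_given_l(l, alpha, params, bound)
  tau <- dimensionless_time(params, rates$t)
  kern <- conversion_kernel(params, rates, udist, bound, i_support = i)
  if (kern$flag$unstable)
    return(list(p = rep(NA_real_, length(i)), flag = kern$flag))
  list(p = as.numeric(crossprod(kern$K, post)), flag = kern$flag)
}

#' Cell-pooled conversion count distribution
#'
#' Ignores cell identity: a read is from a new transcript with probability
#' `1 - e^{-tau}` and from a surviving one with probability `e^{-tau}`,
#' mixed over the uracil distribution.  Depends on the bursting parameters
#' only through `tau = t / gamma`.
#'
#' @inheritParams conversions_given_m
#' @return Probability of each `i`.
#' @export
pooled_conversion_pmf <- function(i, params, rates, udist) {
  stopifnot(inherits(rates, "conversion_rates"))
  tau <- dimensionless_time(params, rates$t)
  if (tau <= 0) stop("'tau' must be positive")
  A <- .uconv_mix(i, udist, rates$lambda_n + rates$lambda_s)
  B <- .uconv_mix(i, udist, rates$lambda_s)
  (1 - exp(-tau)) * A + exp(-tau) * B
}
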