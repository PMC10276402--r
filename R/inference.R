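#' Uniform prior bounds on the parameter vector
#'
#' Uninformative multivariate uniform prior: `mu ~ U(0, 1e5)`,
#' `a ~ U(0, 1e5)`, `gamma ~ U(1, 1e5)`.  With flat priors the prior only
#' serves to reject proposals outside the supported box.
#'
#' @param mu,a,gamma Length-2 numeric vectors `(lower, upper)`.
#' @return Object of class `prior_config`.
#' @export
prior_config <- function(mu = c(0, 1e5), a = c(0, 1e5), gamma = c(1, 1e5)) {
  structure(list(mu = mu, a = a, gamma = gamma), class = "prior_config")
}

.in_support <- function(theta, priors) {
  theta[1] > priors$mu[1] && theta[1] < priors$mu[2] &&
    theta[2] > priors$a[1] && theta[2] < priors$a[2] &&
    theta[3] >= priors$gamma[1] && theta[3] < priors$gamma[2]
}

#' Chain configuration
#'
#' Chain length and posterior-extraction settings.  Defaults depend on the
#' gene's empirical expression level: genes with `mu_hat < 1000` run 5000
#' steps with a posterior window of the last 2500 steps and a rolling
#' instability window of `w = 500`; high-expression genes run 1500 steps,
#' window 1000, `w = 100`.  Thinning factor 2 gives 1250 or 500 posterior
#' samples.  The model-3 switch fires when at least `w/20` of the last `w`
#' steps (never looking before step `w/2 + 1`) saw a rejection caused by a
#' negative value of the approximate new-transcript pmf.
#'
#' @param n_steps,window,w Override the expression-dependent defaults.
#' @param thin Thinning factor for posterior extraction.
#' @param switch_frac Fraction of the rolling window that must show
#'   instability rejections to trigger the model-3 restart.
#' @param max_init_tries Redraw budget for the semi-random initialisation.
#' @param max_M Cap on the projection bound; proposals needing a larger
#'   latent grid are rejected as numerically out of support.  `NULL` means
#'   50x the bound at initialisation (at least 2000).
#' @return Object of class `chain_config`.
#' @export
chain_config <- function(n_steps = NULL, window = NULL, w = NULL, thin = 2L,
                         switch_frac = 1 / 20, max_init_tries = 1000L,
                         max_M = NULL) {
  structure(list(n_steps = n_steps, window = window, w = w,
                 thin = as.integer(thin), switch_frac = switch_frac,
                 max_init_tries = as.integer(max_init_tries), max_M = max_M),
            class = "chain_config")
}

.resolve_config <- function(config, mu_hat) {
  high <- is.finite(mu_hat) && mu_hat >= 1000
  if (is.null(config$n_steps)) config$n_steps <- if (high) 1500L else 5000L
  if (is.null(config$window)) config$window <- if (high) 1000L else 2500L
  if (is.null(config$w)) config$w <- if (high) 100L else 500L
  config$n_steps <- as.integer(config$n_steps)
  config$window <- as.integer(min(config$window, config$n_steps))
  config$w <- as.integer(config$w)
  config
}

#' Empirical semi-random chain initialisation
#'
#' Sets `mu` to the moment estimate `mu_hat = mean(l_c / alpha_c)`, draws
#' the burst rate log-uniformly on `[1, 10]` and the lifetime from
#' `Normal(gamma_hat, gamma_hat / 5)` where
#' `gamma_hat = -t / log(clamp(1 - (lambda - lambda_s)/lambda_n, 0.1, 0.9))`
#' and `lambda` is the gene's overall observed conversion rate.  Draws are
#' repeated until the target density at the draw is positive (finite
#' log-likelihood, stable, inside the prior box).
#'
#' @param gene A [gene_observations] object.
#' @param rates A [conversion_rates] object.
#' @param priors A [prior_config].
#' @param target_fn Function mapping a [burst_params] to a log-likelihood
#'   (with `unstable` attribute); used to validate draws.
#' @param max_tries Redraw budget.
#' @return A [burst_params] object, with attributes `mu_hat`, `gamma_hat`
#'   and `tries`.  Errors with class `slamburst_init_error` if the budget
#'   is exhausted; the condition carries `all_unstable`.
#' @export
empirical_init <- function(gene, rates, priors = prior_config(),
                           target_fn = NULL, max_tries = 1000L) {
  stopifnot(inherits(gene, "gene_obs"))
  mu_hat <- mean(gene$cells$l / gene$cells$alpha)
  lam <- .observed_conversion_rate(gene)
  frac <- 1 - (lam - gene$lambda_s) / rates$lambda_n
  frac <- min(0.9, max(0.1, frac))
  if (is.na(lam)) frac <- 0.9
  gamma_hat <- -rates$t / log(frac)
  n_unstable <- 0L
  for (try in seq_len(max_tries)) {
    a <- exp(runif(1, log(1), log(10)))
    gamma <- rnorm(1, gamma_hat, gamma_hat / 5)
    theta <- c(mu_hat, a, gamma)
    if (!.in_support(theta, priors)) next
    par <- burst_params(mu_hat, a, gamma)
    if (!is.null(target_fn)) {
      ll <- target_fn(par)
      if (is_unstable(ll)) { n_unstable <- n_unstable + 1L; next }
      if (!is.finite(ll)) next
    }
    attr(par, "mu_hat") <- mu_hat
    attr(par, "gamma_hat") <- gamma_hat
    attr(par, "tries") <- try
    return(par)
  }
  cond <- structure(
    class = c("slamburst_init_error", "error", "condition"),
    list(message = sprintf(
           "initialisation failed for gene '%s' after %d draws (%d unstable)",
           gene$gene_id, max_tries, n_unstable),
         call = sys.call(-1), all_unstable = n_unstable == max_tries,
         mostly_unstable = n_unstable > 0.9 * max_tries))
  stop(cond)
}

#' Langevin proposal for one coordinate
#'
#' Draws from `Normal(theta_k + S_k * grad_k, sd = sqrt(2 * S_k))`: a
#' gradient-informed random walk whose drift uses the current numerical
#' gradient estimate and whose scale is the adaptive constant `S_k`.
#'
#' @param theta_k Current coordinate value.
#' @param S_k Positive adaptive scaling constant.
#' @param grad_k Current gradient estimate (0 gives a pure random walk).
#' @return Proposed coordinate value.
#' @export
mala_propose <- function(theta_k, S_k, grad_k) {
  stopifnot(S_k > 0)
  rnorm(1, mean = theta_k + S_k * grad_k, sd = sqrt(2 * S_k))
}

#' Metropolis accept/reject decision
#'
#' `A = min(1, exp(log_prop - log_cur))`; a proposal with `-Inf` target
#' (outside the prior box, or unstable) has `A = 0`.
#'
#' @param log_target_current,log_target_proposed Log target densities.
#' @return List with `accepted` (logical) and `A` (acceptance probability).
#' @export
mh_accept <- function(log_target_current, log_target_proposed) {
  if (!is.finite(log_target_proposed)) return(list(accepted = FALSE, A = 0))
  A <- min(1, exp(log_target_proposed - log_target_current))
  list(accepted = runif(1) < A, A = A)
}

#' Numerical gradient update after a sub-step
#'
#' Accepted moves estimate the coordinate gradient by the observed secant
#' `(log pi_new - log pi_old) / (theta_new - theta_old)`; rejections reset
#' the estimate to zero.
#'
#' @param theta_old,theta_new Coordinate values.
#' @param log_target_old,log_target_new Log targets at those values.
#' @param accepted Was the proposal accepted?
#' @return Updated gradient estimate.
#' @export
update_gradient <- function(theta_old, theta_new, log_target_old,
                            log_target_new, accepted) {
  if (!accepted) return(0)
  d <- theta_new - theta_old
  if (d == 0) return(0)
  (log_target_new - log_target_old) / d
}

#' Adaptive scaling update
#'
#' Multiplicative stochastic-approximation step toward the MALA-optimal
#' acceptance rate: `S <- exp(log S + eta * (A - 0.574))`, with the decay
#' `eta <- 0.999 * eta` applied after every update.
#'
#' @param S_k Positive scaling constant.
#' @param eta Decay term.
#' @param A Acceptance probability of the last proposal.
#' @param target Target acceptance rate (0.574).
#' @return List with updated `S` and `eta`.
#' @export
update_adaptive <- function(S_k, eta, A, target = 0.574) {
  stopifnot(S_k > 0, A >= 0, A <= 1)
  list(S = exp(log(S_k) + eta * (A - target)), eta = 0.999 * eta)
}

#' One Gibbs sweep of per-coordinate MALA sub-steps
#'
#' Updates `(mu, a, gamma)` in that fixed order; each sub-step's target
#' conditions on the freshest values of the other coordinates.  Rejections
#' from outside the prior box or from unstable likelihood evaluations use
#' `A = 0` in the adaptation.
#'
#' @param theta Numeric vector `(mu, a, gamma)` with positive target.
#' @param lp Log target at `theta`.
#' @param target_fn Function from a numeric `theta` vector to a
#'   log-likelihood (with `unstable` attribute), `-Inf` outside support.
#' @param state List with `S` (length 3), `grad` (length 3), `eta`.
#' @param priors A [prior_config].
#' @param propose_fn Proposal generator (swappable for testing); defaults
#'   to [mala_propose].
#' @return List with updated `theta`, `lp`, `state`, logical `accepted`
#'   (length 3) and `instab` (did any rejection come from instability?).
#' @export
gibbs_sweep <- function(theta, lp, target_fn, state, priors = prior_config(),
                        propose_fn = mala_propose) {
  accepted <- logical(3)
  instab <- FALSE
  for (k in 1:3) {
    prop <- theta
    prop[k] <- propose_fn(theta[k], state$S[k], state$grad[k])
    if (!.in_support(prop, priors)) {
      A <- 0; acc <- FALSE; lp_prop <- -Inf
    } else {
      ll <- target_fn(prop)
      if (is_unstable(ll)) instab <- TRUE
      lp_prop <- as.numeric(ll)
      dec <- mh_accept(lp, lp_prop)
      A <- dec$A; acc <- dec$accepted
    }
    state$grad[k] <- update_gradient(theta[k], prop[k], lp, lp_prop, acc)
    upd <- update_adaptive(state$S[k], state$eta, A)
    state$S[k] <- upd$S
    state$eta <- upd$eta
    if (acc) {
      theta <- prop
      lp <- lp_prop
    }
    accepted[k] <- acc
  }
  list(theta = theta, lp = lp, state = state, accepted = accepted,
       instab = instab)
}

.derived_matrix <- function(samples) {
  cbind(samples,
        b = samples[, "mu"] / samples[, "a"],
        kappa = samples[, "a"] / samples[, "gamma"],
        delta = 1 / samples[, "gamma"])
}

#' Run the adaptive MALA-within-Gibbs chain for one gene
#'
#' Initialises semi-randomly ([empirical_init]) with `S = theta1 / 100`,
#' `grad = 0`, `eta = 0.1`, runs the full cell-specific model (model 2,
#' L1+L2) and monitors a rolling window for rejections caused by negative
#' values of the approximate new-transcript pmf; if at least `w/20` of the
#' windowed steps saw such a rejection, the whole chain restarts from a
#' fresh initialisation under the pooled fallback model (model 3, L1+L3),
#' whose likelihood never evaluates the unstable approximation.  The
#' posterior is the thinned tail window of the chain; point estimates are
#' posterior means and CV = sd/mean, with derived parameters (`b`,
#' `kappa`, `delta`) summarised per sample.
#'
#' @param gene A [gene_observations] object.
#' @param rates A [conversion_rates] object.
#' @param config A [chain_config].
#' @param priors A [prior_config].
#' @param seed Optional integer seed (set before initialisation).
#' @param model Starting model, 2 (default) or 3.
#' @return Object of class `posterior_chain`: list with `samples` (thinned
#'   posterior matrix over mu, a, gamma, b, kappa, delta), `chain` (full
#'   trace of mu, a, gamma), `acceptance` (per-coordinate rates),
#'   `accept_trace` (steps x 3 logical), `model`, `switch_step`,
#'   `summary` (data frame of estimate/sd/cv), `mu_hat`, `config`.
#' @export
run_chain <- function(gene, rates, config = chain_config(),
                      priors = prior_config(), seed = NULL, model = 2L) {
  stopifnot(inherits(gene, "gene_obs"))
  if (!is.null(seed)) set.seed(seed)
  cache <- gene_cache(gene, rates)
  mu_hat <- mean(gene$cells$l / gene$cells$alpha)
  config <- .resolve_config(config, mu_hat)

  make_target <- function(model, max_M) {
    function(theta) {
      if (is.numeric(theta) && !inherits(theta, "burst_params")) {
        if (!.in_support(theta, priors)) return(.ll_value(-Inf))
        par <- burst_params(theta[1], theta[2], theta[3])
      } else par <- theta
      bound <- fsp_bound(par)
      if (bound$M > max_M) return(.ll_value(-Inf))   # numerical guard
      tau <- dimensionless_time(par, rates$t)
      if (!is.finite(tau) || tau <= 0) return(.ll_value(-Inf))
      if (model == 2L) loglik_model2(gene, par, rates, cache, bound)
      else loglik_model3(gene, par, rates, cache, bound)
    }
  }

  switch_step <- NA_integer_
  repeat {
    probe <- make_target(model, max_M = Inf)
    init <- tryCatch(
      empirical_init(gene, rates, priors, target_fn = probe,
                     max_tries = config$max_init_tries),
      slamburst_init_error = function(e) e)
    if (inherits(init, "slamburst_init_error")) {
      if (model == 2L && isTRUE(init$mostly_unstable)) {
        # the gene sits so deep in unstable space that no stable start
        # exists: go straight to the pooled fallback model
        model <- 3L
        switch_step <- 0L
        next
      }
      stop(init)
    }
    theta1 <- c(init$mu, init$a, init$gamma)
    max_M <- if (is.null(config$max_M))
      max(2000L, 50L * fsp_bound(init)$M) else config$max_M
    target <- make_target(model, max_M)

    n <- config$n_steps
    state <- list(S = theta1 / 100, grad = c(0, 0, 0), eta = 0.1)
    theta <- theta1
    lp <- as.numeric(target(theta))
    chain <- matrix(NA_real_, n, 3,
                    dimnames = list(NULL, c("mu", "a", "gamma")))
    acc <- matrix(FALSE, n, 3)
    inst <- logical(n)
    switched <- FALSE
    for (j in seq_len(n)) {
      sw <- gibbs_sweep(theta, lp, target, state, priors)
      theta <- sw$theta; lp <- sw$lp; state <- sw$state
      chain[j, ] <- theta
      acc[j, ] <- sw$accepted
      inst[j] <- sw$instab
      if (model == 2L) {
        lo <- max(config$w %/% 2 + 1, j - config$w + 1)
        if (j >= lo && sum(inst[lo:j]) >= config$w * config$switch_frac) {
          model <- 3L
          switch_step <- j
          switched <- TRUE
          break
        }
      }
    }
    if (!switched) break
  }

  idx <- seq(n - config$window + config$thin, n, by = config$thin)
  thinned <- .derived_matrix(chain[idx, , drop = FALSE])
  est <- colMeans(thinned)
  sds <- apply(thinned, 2, sd)
  summary <- data.frame(parameter = colnames(thinned), estimate = est,
                        sd = sds, cv = sds / est, row.names = NULL)
  structure(list(samples = thinned, chain = chain,
                 acceptance = colMeans(acc), accept_trace = acc,
                 model = model, switch_step = switch_step,
                 summary = summary, mu_hat = mu_hat, init = init,
                 config = config),
            class = "posterior_chain")
}

#' @export
print.posterior_chain <- function(x, ...) {
  cat(sprintf("posterior_chain: model %d%s, %d thinned samples, acceptance %s\n",
              x$model,
              if (!is.na(x$switch_step)) sprintf(" (switched at step %d)",
                                                 x$switch_step) else "",
              nrow(x$samples),
              paste(sprintf("%.3f", x$acceptance), collapse = "/")))
  print(x$summary)
  invisible(x)
}

#' Filter genes by posterior confidence
#'
#' Keeps chains whose coefficient of variation (posterior sd / mean) is at
#' most `cv_max` for every reported parameter (`mu`, `a`, `b`, `kappa`,
#' `delta`).
#'
#' @param results List of `posterior_chain` objects (or a results data
#'   frame from [burst_infer] with `cv_*` columns).
#' @param cv_max Maximum tolerated CV (default 0.45).
#' @return The filtered list (or data frame).
#' @export
select_genes <- function(results, cv_max = 0.45) {
  pars <- c("mu", "a", "b", "kappa", "delta")
  if (is.data.frame(results)) {
    cvs <- results[, paste0("cv_", pars), drop = FALSE]
    return(results[apply(cvs <= cv_max, 1, all), , drop = FALSE])
  }
  keep <- vapply(results, function(r) {
    cv <- r$summary$cv[match(pars, r$summary$parameter)]
    all(cv <= cv_max)
  }, logical(1))
  results[keep]
}
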