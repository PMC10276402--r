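# The five likelihood functions of the ablation study: L1 (UMI counts
# only), L2 (cell-specific conversions), L1+L2 (full cell-specific model),
# L3 (cell-pooled conversions) and L1+L3 (pooled fallback model).  All
# omit the multinomial coefficient, which is constant in the parameters
# and cancels in the Metropolis ratio.  Each returns a numeric scalar
# carrying an "unstable" attribute; an unstable evaluation has value -Inf
# and unstable = TRUE, and the sampler treats it as a rejected proposal.

.ll_value <- function(x, unstable = FALSE) {
  attr(x, "unstable") <- unstable
  x
}

#' Is a likelihood value flagged unstable?
#'
#' @param ll A value returned by one of the `loglik_*` functions.
#' @return `TRUE` if the evaluation hit unstable parameter space.
#' @export
is_unstable <- function(ll) isTRUE(attr(ll, "unstable"))

#' UMI-count log-likelihood (L1)
#'
#' `sum_c log P(l_c | alpha_c)` over cells, with the marginal truncated at
#' the finite state projection bound.  Depends only on `mu` and `a`: the
#' lifetime `gamma` does not enter the steady-state or capture models,
#' which is why UMI counts alone cannot time-resolve bursting.
#'
#' @param gene A [gene_observations] object.
#' @param params A [burst_params] object.
#' @param cache Optional [gene_cache] (built on the fly if omitted; pass
#'   one for repeated evaluations).
#' @param bound Optional [fsp_bound].
#' @return Log-likelihood with an `unstable` attribute (always `FALSE`
#'   for L1).
#' @export
loglik_L1 <- function(gene, params, cache = NULL, bound = fsp_bound(params)) {
  stopifnot(inherits(gene, "gene_obs"))
  if (is.null(cache)) {
    p <- mapply(function(l, a) umi_marginal(l, a, params, bound),
                gene$cells$l, gene$cells$alpha)
    return(.ll_value(sum(.clip_log(p))))
  }
  D <- .cache_D(cache, bound$M)
  nb <- nb_steady_state(0:bound$M, params)
  marg <- colSums(D * nb)
  .ll_value(sum(.clip_log(marg)))
}

#' Cell-specific conversion log-likelihood (L2)
#'
#' `sum_c sum_i y_{c,i} log P(i | l_c, alpha_c)` where the conversion
#' probability conditions on each cell's UMI count through the posterior of
#' the latent transcript count.  Raises the instability flag (value `-Inf`,
#' attribute `unstable = TRUE`) when the approximate new-transcript pmf is
#' negative anywhere on the projection support.
#'
#' @inheritParams loglik_L1
#' @param rates A [conversion_rates] object.
#' @return Log-likelihood with an `unstable` attribute.
#' @export
loglik_L2 <- function(gene, params, rates, cache = NULL,
                      bound = fsp_bound(params)) {
  stopifnot(inherits(gene, "gene_obs"))
  if (is.null(cache)) cache <- gene_cache(gene, rates)
  parts <- .model2_parts(gene, params, rates, cache, bound)
  if (parts$unstable) return(.ll_value(-Inf, unstable = TRUE))
  .ll_value(parts$l2)
}

# Shared plumbing for L1/L2: one pass over the capture-prior product U
# yields both the UMI marginals (column sums) and, through the conversion
# kernel, the per-cell conversion pmfs on the observed support.
.model2_parts <- function(gene, params, rates, cache, bound) {
  kern <- conversion_kernel(params, cache$rates, gene$udist, bound,
                            i_support = cache$i_support, AB = cache$AB)
  if (kern$flag$unstable) return(list(unstable = TRUE))
  D <- .cache_D(cache, bound$M)
  nb <- nb_steady_state(0:bound$M, params)
  U <- D * nb
  cs <- colSums(U)
  Pi <- crossprod(kern$K, U)                  # |i| x cells, unnormalised
  Pi <- Pi / rep(pmax(cs, .PROB_FLOOR), each = nrow(Pi))
  list(unstable = FALSE,
       l1 = sum(.clip_log(cs)),
       l2 = sum(gene$Y * .clip_log(Pi)))
}

#' Full cell-specific model log-likelihood (model 2, L1 + L2)
#'
#' @inheritParams loglik_L2
#' @return Log-likelihood with an `unstable` attribute.
#' @export
loglik_model2 <- function(gene, params, rates, cache = NULL,
                          bound = fsp_bound(params)) {
  if (is.null(cache)) cache <- gene_cache(gene, rates)
  parts <- .model2_parts(gene, params, rates, cache, bound)
  if (parts$unstable) return(.ll_value(-Inf, unstable = TRUE))
  .ll_value(parts$l1 + parts$l2)
}

#' Cell-pooled conversion log-likelihood (L3)
#'
#' `sum_i y_i log P(i)` on the cell-summed histogram, with `P(i)` from
#' [pooled_conversion_pmf].  Depends on the parameters only through
#' `tau = t / gamma`, so it is flat in `(mu, a)` at fixed `gamma`.
#'
#' @inheritParams loglik_L2
#' @return Log-likelihood with an `unstable` attribute (always `FALSE`).
#' @export
loglik_L3 <- function(gene, params, rates, cache = NULL) {
  stopifnot(inherits(gene, "gene_obs"))
  if (sum(gene$pooled_y) == 0) return(.ll_value(0))
  tau <- dimensionless_time(params, rates$t)
  if (is.null(cache)) {
    p <- pooled_conversion_pmf(0:(nrow(gene$Y) - 1L), params, rates,
                               gene$udist)
  } else {
    p <- (1 - exp(-tau)) * cache$AB$A + exp(-tau) * cache$AB$B
  }
  .ll_value(sum(gene$pooled_y * .clip_log(p)))
}

#' Pooled fallback model log-likelihood (model 3, L1 + L3)
#'
#' @inheritParams loglik_L2
#' @return Log-likelihood with an `unstable` attribute (always `FALSE`).
#' @export
loglik_model3 <- function(gene, params, rates, cache = NULL,
                          bound = fsp_bound(params)) {
  if (is.null(cache)) cache <- gene_cache(gene, rates)
  l1 <- loglik_L1(gene, params, cache, bound)
  l3 <- loglik_L3(gene, params, rates, cache)
  .ll_value(as.numeric(l1) + as.numeric(l3))
}

#' Gene inclusion predicate for real data
#'
#' Keep genes with at least one read and at least one observed T>C
#' conversion in both the labelled and the control dataset; the control is
#' summarised by its total read and conversion counts.
#'
#' @param gene A [gene_observations] object (labelled dataset).
#' @param control_reads,control_conversions Totals from the matching
#'   control (no-4sU) dataset.
#' @return `TRUE` if the gene should enter inference.
#' @export
gene_passes_filter <- function(gene, control_reads = 1,
                               control_conversions = 1) {
  reads <- sum(gene$Y)
  conv <- sum(as.integer(rownames(gene$Y)) * gene$pooled_y)
  reads >= 1 && conv >= 1 && control_reads >= 1 && control_conversions >= 1
}
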