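#' Conversion kernel P(i | m)
#'
#' Precomputes the conversion-count distribution for every latent transcript
#' count `m = 0..M` on a fixed support of conversion counts `i`.  Because
#' the per-read mixture is linear in the new-transcript fraction `n/m`, the
#' kernel row for `m` is `w_m * A + (1 - w_m) * B` where
#' `w_m = E[n/m | m]` under [new_given_total], `A` is the labelled
#' uracil-mixture pmf (rate `lambda_n + lambda_s`) and `B` the background
#' one (rate `lambda_s`).  `A` and `B` do not depend on the bursting
#' parameters, so only the weights are rebuilt per parameter proposal.
#'
#' @param params A [burst_params] object.
#' @param rates A [conversion_rates] object.
#' @param udist A `uracil_dist`.
#' @param bound An [fsp_bound].
#' @param i_support Integer vector of conversion counts to tabulate.
#' @param AB Optional precomputed list with elements `A` and `B` matching
#'   `i_support` (cache plumbing; see [gene_cache]).
#' @return Object of class `conversion_kernel`: list with `K`
#'   (`(M+1) x length(i_support)` matrix), `w` (expected new fraction per
#'   `m`), `normaliser` (the convolution, approximately the steady-state
#'   pmf), `flag`, `bound`, `params`, `i_support`.
#' @export
conversion_kernel <- function(params, rates, udist, bound = fsp_bound(params),
                              i_support, AB = NULL) {
  stopifnot(inherits(rates, "conversion_rates"))
  M <- bound$M
  tau <- dimensionless_time(params, rates$t)
  if (is.null(AB)) {
    AB <- list(A = .uconv_mix(i_support, udist, rates$lambda_n + rates$lambda_s),
               B = .uconv_mix(i_support, udist, rates$lambda_s))
  }
  pn <- new_pmf_cpp(M, params$a, burst_size(params), tau)
  flag <- .instability_flag(pn)
  if (flag$unstable) {
    return(structure(list(K = NULL, w = NULL, normaliser = NULL, flag = flag,
                          bound = bound, params = params,
                          i_support = i_support),
                     class = "conversion_kernel"))
  }
  ps <- surviving_marginal(0:M, params, tau)
  cw <- conv_weights_cpp(pn, ps)
  w <- ifelse(cw$den > 0, cw$num / pmax(cw$den, .PROB_FLOOR) / pmax(0:M, 1), 0)
  w <- pmin(pmax(w, 0), 1)
  w[1] <- 0                                   # m = 0: background only
  K <- outer(w, AB$A) + outer(1 - w, AB$B)
  structure(list(K = K, w = w, normaliser = cw$den, flag = flag,
                 bound = bound, params = params, i_support = i_support),
            class = "conversion_kernel")
}

#' Per-gene likelihood cache
#'
#' Holds the parameter-independent pieces of the likelihood so each MCMC
#' proposal only rebuilds the parameter-dependent ones: the Poisson capture
#' matrix `D[m+1, c] = Pois(l_c | m * alpha_c)` on a transcript-count grid
#' that grows on demand, and the uracil-mixture vectors `A`, `B` on the
#' gene's observed conversion support.
#'
#' @param gene A [gene_observations] object.
#' @param rates A [conversion_rates] object.
#' @return An environment of class `gene_cache`.
#' @export
gene_cache <- function(gene, rates) {
  stopifnot(inherits(gene, "gene_obs"), inherits(rates, "conversion_rates"))
  e <- new.env(parent = emptyenv())
  e$gene <- gene
  e$rates <- rates
  e$i_support <- 0:(nrow(gene$Y) - 1L)
  e$AB <- list(
    A = .uconv_mix(e$i_support, gene$udist, rates$lambda_n + rates$lambda_s),
    B = .uconv_mix(e$i_support, gene$udist, rates$lambda_s))
  e$D <- NULL                                 # grown lazily by .cache_D
  class(e) <- "gene_cache"
  e
}

# Return the capture matrix for m = 0..M, extending the cached grid
# geometrically when a larger bound is requested.
.cache_D <- function(cache, M) {
  cur <- if (is.null(cache$D)) -1L else nrow(cache$D) - 1L
  if (M > cur) {
    newmax <- max(M, ceiling(1.5 * max(cur, 64L)))
    lo <- cur + 1L
    cells <- cache$gene$cells
    lam <- outer(lo:newmax, cells$alpha)
    block <- dpois(matrix(rep(cells$l, each = newmax - lo + 1L),
                          nrow = newmax - lo + 1L), lam)
    cache$D <- rbind(cache$D, block)
  }
  cache$D[1:(M + 1L), , drop = FALSE]
}
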