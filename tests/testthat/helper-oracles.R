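# Straight-line reference implementations used as independent oracles.
# These deliberately re-derive every quantity with plain R loops and
# base-R distributions, sharing no code path with the package internals.

# Terminating Gauss hypergeometric series for the new-transcript pmf,
# plain R arithmetic (cross-checks the compiled implementation).
oracle_new_pmf <- function(n, a, b, tau) {
  z <- (1 + b) / (exp(tau) + b)
  vapply(n, function(nn) {
    s <- 1
    term <- 1
    if (nn > 0) for (j in 0:(nn - 1)) {
      term <- term * ((-nn + j) * (-a + j)) / ((1 - a - nn + j) * (j + 1)) * z
      s <- s + term
    }
    exp(lgamma(a + nn) - lgamma(nn + 1) - lgamma(a)) *
      (b / (1 + b))^nn * ((1 + b * exp(-tau)) / (1 + b))^a * s
  }, numeric(1))
}

# P(i | l, alpha) by composing posterior over m, new-given-total weights,
# the uracil mixture and the latent-count compounding, term by term.
oracle_conv_umi <- function(i, l, alpha, a, b, tau, ls, ln, udist, M) {
  pm <- dnbinom(0:M, size = a, prob = 1 / (1 + b))
  post <- dpois(l, (0:M) * alpha) * pm
  post <- post / sum(post)
  mixA <- vapply(i, function(ii) sum(udist$p * dpois(ii, udist$u * (ln + ls))),
                 numeric(1))
  mixB <- vapply(i, function(ii) sum(udist$p * dpois(ii, udist$u * ls)),
                 numeric(1))
  out <- numeric(length(i))
  ps_all <- dnbinom(0:M, size = a, prob = 1 / (1 + b * exp(-tau)))
  pn_all <- oracle_new_pmf(0:M, a, b, tau)
  for (m in 0:M) {
    if (m == 0) {
      pim <- mixB
    } else {
      joint <- pn_all[1:(m + 1)] * ps_all[(m + 1):1]
      pnm <- joint / sum(joint)
      pim <- 0
      for (n in 0:m)
        pim <- pim + pnm[n + 1] *
          ((n / m) * mixA + (1 - n / m) * mixB)
    }
    out <- out + pim * post[m + 1]
  }
  out
}

# Full per-cell log-likelihood of the cell-specific conversion model
# (conversion factor only), composed cell by cell.
oracle_L2 <- function(gene, a, b, tau, ls, ln, M) {
  tot <- 0
  for (c in seq_len(nrow(gene$cells))) {
    yc <- gene$Y[, c]
    if (sum(yc) == 0) next
    i_obs <- which(yc > 0) - 1L
    p <- oracle_conv_umi(i_obs, gene$cells$l[c], gene$cells$alpha[c],
                         a, b, tau, ls, ln, gene$udist, M)
    tot <- tot + sum(yc[i_obs + 1L] * log(p))
  }
  tot
}

# Hand-built three-cell toy gene with a fixed uracil distribution.
toy_gene <- function() {
  ud <- structure(list(u = c(5L, 10L), p = c(0.4, 0.6)),
                  class = "uracil_dist")
  cells <- list(
    cell_observation("c1", l = 2, alpha = 0.2,
                     y = c("0" = 3L, "1" = 1L)),
    cell_observation("c2", l = 0, alpha = 0.1, y = integer(0)),
    cell_observation("c3", l = 5, alpha = 0.3,
                     y = c("0" = 2L, "2" = 1L, "3" = 1L)))
  gene_observations("toy", cells, lambda_s = 0.01, udist = ud)
}

# Small simulated gene reused across inference tests (built once).
.fixture_env <- new.env()
fix_gene <- function() {
  if (is.null(.fixture_env$g)) {
    set.seed(4242)
    truth <- burst_params(mu = 10, a = 1, gamma = 500)  # b=10, tau=1 at t=500
    noise <- seq_noise_config(N = 120, t1 = 500)
    sim <- simulate_gene_dataset(truth, noise, gene_id = "fix")
    .fixture_env$g <- sim
  }
  .fixture_env$g
}
fix_rates <- function() conversion_rates(0.01, 0.075, 500)
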