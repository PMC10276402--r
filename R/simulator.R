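#' Reaction rate constants for the two-pool telegraph model
#'
#' Six reactions over species `(RNA0, RNA1, Gon, Goff)`: transcription into
#' the pre-pulse pool (`beta0`) and in-pulse pool (`beta1`), per-molecule
#' decay of each pool (`delta0`, `delta1`) and gene activation/repression
#' (`kon`, `koff`).
#'
#' @param beta0,beta1 Transcription rates (per minute), active gene only.
#' @param delta0,delta1 Decay rates (per minute, per molecule).
#' @param kon,koff Gene switching rates (per minute).
#' @return Object of class `rate_constants`.
#' @export
rate_constants <- function(beta0, beta1, delta0, delta1, kon, koff) {
  v <- c(beta0 = beta0, beta1 = beta1, delta0 = delta0, delta1 = delta1,
         kon = kon, koff = koff)
  if (any(v < 0)) stop("rate constants must be nonnegative")
  structure(as.list(v), class = "rate_constants")
}

#' Map bursting parameters to simulator rate constants
#'
#' Fixes `koff = 1` per minute (fast relative to decay, honouring the
#' instantaneous-burst limit), sets `beta = b * koff` and `kon = kappa`.
#'
#' @param params A [burst_params] object.
#' @param koff Gene repression rate; default 1.
#' @param pulse If `TRUE`, synthesis goes into the in-pulse pool
#'   (`beta1`), otherwise into the pre-pulse pool (`beta0`).
#' @return A [rate_constants] object.
#' @export
burst_to_rates <- function(params, koff = 1, pulse = FALSE) {
  b <- burst_size(params)
  d <- decay_rate(params)
  k <- burst_frequency(params)
  if (pulse)
    rate_constants(0, b * koff, d, d, k, koff)
  else
    rate_constants(b * koff, 0, d, d, k, koff)
}

#' Exact stochastic simulation to a time endpoint
#'
#' Gillespie's exact algorithm over the six telegraph reactions; returns
#' the system state at `t_end`.  Uses R's RNG stream.
#'
#' @param state0 Numeric vector `(RNA0, RNA1, Gon, Goff)`.
#' @param rates A [rate_constants] object.
#' @param t_end End time in minutes.
#' @return Named numeric state vector at `t_end`.
#' @export
gillespie_run <- function(state0, rates, t_end) {
  stopifnot(inherits(rates, "rate_constants"), t_end >= 0,
            length(state0) == 4, state0[3] + state0[4] == 1)
  out <- ssa_endpoint_cpp(as.numeric(state0), unlist(rates), t_end)
  names(out) <- c("RNA0", "RNA1", "Gon", "Goff")
  out
}

#' Simulate one cell through burn-in and 4sU pulse
#'
#' Burn-in run from `(0, 0, 0, 1)` to `t0` with synthesis into the
#' pre-pulse pool, then a pulse run of duration `t1` continuing from the
#' endpoint with synthesis redirected into the in-pulse pool while both
#' pools keep decaying.
#'
#' @param rates_pre Burn-in rates (`beta1` must be 0).
#' @param rates_pulse Pulse rates (`beta0` must be 0).
#' @param t0 Burn-in duration (minutes).
#' @param t1 Pulse duration (minutes).
#' @return Named vector `(RNA0, RNA1)`: surviving and new transcripts.
#' @export
simulate_cell <- function(rates_pre, rates_pulse, t0, t1) {
  stopifnot(rates_pre$beta1 == 0, rates_pulse$beta0 == 0)
  s <- gillespie_run(c(0, 0, 0, 1), rates_pre, t0)
  s <- gillespie_run(s, rates_pulse, t1)
  s[c("RNA0", "RNA1")]
}

#' Sequencing noise configuration
#'
#' Parameters of the in-silico sequencing generator: capture efficiency
#' `alpha ~ Beta(1, 9)` (or a fixed value), reads per UMI zero-truncated
#' Poisson with intensity `nu = 5`, uracils per read Poisson with mean
#' `u_hat = 60`, background and 4sU conversion rates `lambda_s = 0.01`,
#' `lambda_n = 0.075`, burn-in `t0 = 200000` min, pulse `t1 = 1000` min and
#' `N = 10000` cells.
#'
#' @param alpha_shape Beta shape parameters for the capture efficiency.
#' @param alpha Fixed capture efficiency overriding the Beta draw (used
#'   e.g. to isolate bursting effects), or `NULL`.
#' @param nu Reads-per-UMI intensity.
#' @param u_hat Mean uracils per read.
#' @param lambda_s,lambda_n Conversion rates.
#' @param t0 Burn-in duration (minutes).
#' @param t1 Pulse duration (minutes).
#' @param N Number of cells.
#' @return Object of class `seq_noise_config`.
#' @export
seq_noise_config <- function(alpha_shape = c(1, 9), alpha = NULL, nu = 5,
                             u_hat = 60, lambda_s = 0.01, lambda_n = 0.075,
                             t0 = 200000, t1 = 1000, N = 10000) {
  if (!is.null(alpha) && (alpha <= 0 || alpha > 1))
    stop("fixed 'alpha' must be in (0, 1]")
  stopifnot(nu > 0, u_hat > 0, t0 >= 0, t1 >= 0, N >= 1)
  structure(list(alpha_shape = alpha_shape, alpha = alpha, nu = nu,
                 u_hat = u_hat, lambda_s = lambda_s, lambda_n = lambda_n,
                 t0 = t0, t1 = t1, N = as.integer(N)),
            class = "seq_noise_config")
}

#' Zero-truncated Poisson draws
#'
#' `f(r | nu) = nu^r / ((e^nu - 1) r!)` for `r >= 1`; drawn by inverting
#' the conditional CDF.
#'
#' @param n Number of draws.
#' @param nu Intensity.
#' @return Integer vector of positive counts.
#' @export
rztpois <- function(n, nu) {
  p0 <- dpois(0, nu)
  qpois(p0 + runif(n) * (1 - p0), nu)
}

#' In-silico sequencing of one cell
#'
#' Draws the capture efficiency, binomially captures each transcript pool
#' into UMIs, assigns each UMI a zero-truncated Poisson number of reads,
#' each read a Poisson number of genomic Ts, and binomial conversion
#' counts at the background rate for pre-pulse reads and the elevated rate
#' for in-pulse reads.
#'
#' @param rna0,rna1 Surviving and new transcript counts.
#' @param noise A [seq_noise_config].
#' @param alpha Optional fixed capture efficiency for this cell (overrides
#'   the config; used when several genes share one cell's efficiency).
#' @return A list with `l` (total UMI count), `alpha`, `y` (named
#'   conversion histogram), `reads` (data frame with per-read `u`, `i` and
#'   pool label `new`).
#' @export
sequence_cell <- function(rna0, rna1, noise, alpha = NULL) {
  stopifnot(inherits(noise, "seq_noise_config"), rna0 >= 0, rna1 >= 0)
  if (is.null(alpha))
    alpha <- if (is.null(noise$alpha))
      rbeta(1, noise$alpha_shape[1], noise$alpha_shape[2]) else noise$alpha
  alpha <- max(alpha, 1e-12)
  l0 <- rbinom(1, rna0, alpha)
  l1 <- rbinom(1, rna1, alpha)
  r0 <- if (l0 > 0) sum(rztpois(l0, noise$nu)) else 0L
  r1 <- if (l1 > 0) sum(rztpois(l1, noise$nu)) else 0L
  u <- rpois(r0 + r1, noise$u_hat)
  new <- rep(c(FALSE, TRUE), c(r0, r1))
  rate <- ifelse(new, noise$lambda_s + noise$lambda_n, noise$lambda_s)
  i <- rbinom(r0 + r1, u, rate)
  y <- if (length(i)) {
    tab <- table(i)
    stats::setNames(as.integer(tab), names(tab))
  } else integer(0)
  list(l = l0 + l1, alpha = alpha, y = y,
       reads = data.frame(u = u, i = i, new = new))
}

#' Simulate a full per-gene dataset
#'
#' Runs the two-stage Gillespie simulation for `N` cells and sequences each
#' in silico, assembling a [gene_observations] object with the truncated
#' Poisson uracil distribution and the generating truth attached.
#'
#' @param burst A [burst_params] (mapped to rates via [burst_to_rates]) or
#'   a list with `pre` and `pulse` [rate_constants].
#' @param noise A [seq_noise_config].
#' @param gene_id Identifier for the simulated gene.
#' @param check_burnin If `TRUE`, warn when the burn-in appears too short
#'   (mean transcript count at `t0/2` differs grossly from `t0` over a
#'   probe set of cells); useful when scaling `t0` down in tests.
#' @param alphas Optional vector of per-cell capture efficiencies (length
#'   `noise$N`), for sharing cells across genes.
#' @return A list with `gene` (a [gene_observations]), `truth` (list of
#'   generating parameters), `rna` (N x 2 matrix of transcript counts) and
#'   `reads` (per-read data frame with `cell` index).
#' @export
simulate_gene_dataset <- function(burst, noise = seq_noise_config(),
                                  gene_id = "sim", check_burnin = FALSE,
                                  alphas = NULL) {
  if (inherits(burst, "burst_params")) {
    pre <- burst_to_rates(burst)
    pulse <- burst_to_rates(burst, pulse = TRUE)
    truth <- list(mu = burst$mu, a = burst$a, gamma = burst$gamma,
                  b = burst_size(burst), kappa = burst_frequency(burst),
                  delta = decay_rate(burst))
  } else {
    pre <- burst$pre
    pulse <- burst$pulse
    kappa <- 1 / (1 / pre$kon + 1 / pre$koff)
    b <- pre$beta0 / pre$koff
    truth <- list(mu = b * kappa / pre$delta0, a = kappa / pre$delta0,
                  gamma = 1 / pre$delta0, b = b, kappa = kappa,
                  delta = pre$delta0)
  }
  if (check_burnin) {
    probe <- vapply(seq_len(50), function(i)
      sum(gillespie_run(c(0, 0, 0, 1), pre, noise$t0 / 2)[1:2]), numeric(1))
    probe2 <- vapply(seq_len(50), function(i)
      sum(gillespie_run(c(0, 0, 0, 1), pre, noise$t0)[1:2]), numeric(1))
    if (abs(mean(probe2) - mean(probe)) >
        4 * sqrt(var(probe) / 50 + var(probe2) / 50 + 1e-12))
      warning("burn-in may be too short: half-time and full-time means differ")
  }
  N <- noise$N
  rna <- matrix(0L, N, 2, dimnames = list(NULL, c("RNA0", "RNA1")))
  cells <- vector("list", N)
  read_list <- vector("list", N)
  if (!is.null(alphas)) stopifnot(length(alphas) == N)
  for (c in seq_len(N)) {
    st <- simulate_cell(pre, pulse, noise$t0, noise$t1)
    rna[c, ] <- st
    sc <- sequence_cell(st[1], st[2], noise,
                        alpha = if (is.null(alphas)) NULL else alphas[c])
    cells[[c]] <- cell_observation(sprintf("cell%05d", c), sc$l, sc$alpha,
                                   sc$y)
    if (nrow(sc$reads)) read_list[[c]] <- cbind(cell = c, sc$reads)
  }
  reads <- do.call(rbind, read_list)
  gene <- gene_observations(
    gene_id, cells, lambda_s = noise$lambda_s,
    udist = poisson_uracil_pmf(noise$u_hat),
    total_T = if (is.null(reads)) 0 else sum(reads$u),
    total_TC = if (is.null(reads)) 0 else sum(reads$i))
  list(gene = gene, truth = truth, rna = rna, reads = reads)
}
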