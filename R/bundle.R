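# Tabular dataset bundle: five tab-separated tables with one-line headers.
#   cells.tsv  cell_id  alpha
#   genes.tsv  gene_id  lambda_s
#   umi.tsv    gene_id  cell_id  l
#   reads.tsv  gene_id  cell_id  u  i
#   meta.tsv   t  lambda_n
# Diff-able, stream-able, no binary dependency; reads are stored long-form
# so conversion histograms and the empirical uracil distribution can both
# be rebuilt from them.

#' Dataset bundle of observation tables
#'
#' @param cells Data frame `cell_id`, `alpha`.
#' @param genes Data frame `gene_id`, `lambda_s`.
#' @param umi Data frame `gene_id`, `cell_id`, `l`.
#' @param reads Data frame `gene_id`, `cell_id`, `u`, `i` (one row per
#'   sequenced read).
#' @param meta List or data frame with `t` (pulse minutes) and `lambda_n`.
#' @return Object of class `dataset_bundle`.
#' @export
dataset_bundle <- function(cells, genes, umi, reads, meta) {
  meta <- as.list(meta)
  b <- structure(list(cells = cells, genes = genes, umi = umi,
                      reads = reads, meta = meta[c("t", "lambda_n")]),
                 class = "dataset_bundle")
  validate_bundle(b)
  b
}

#' Validate a dataset bundle
#'
#' Checks schemas, value invariants (`u >= i >= 0`, `l >= 0`,
#' `alpha` in (0,1]) and referential integrity across tables, reporting
#' offending row numbers.
#'
#' @param bundle A `dataset_bundle`.
#' @return The bundle, invisibly; errors on violation.
#' @export
validate_bundle <- function(bundle) {
  need <- list(cells = c("cell_id", "alpha"), genes = c("gene_id", "lambda_s"),
               umi = c("gene_id", "cell_id", "l"),
               reads = c("gene_id", "cell_id", "u", "i"))
  for (tb in names(need)) {
    df <- bundle[[tb]]
    if (!is.data.frame(df) || !all(need[[tb]] %in% names(df)))
      stop(sprintf("table '%s' must have columns: %s", tb,
                   paste(need[[tb]], collapse = ", ")))
  }
  if (is.null(bundle$meta$t) || is.null(bundle$meta$lambda_n))
    stop("meta must provide 't' and 'lambda_n'")
  bad <- which(bundle$cells$alpha <= 0 | bundle$cells$alpha > 1)
  if (length(bad))
    stop("cells rows with alpha outside (0, 1]: ",
         paste(utils::head(bad, 5), collapse = ", "))
  bad <- which(bundle$umi$l < 0)
  if (length(bad))
    stop("umi rows with negative l: ", paste(utils::head(bad, 5), collapse = ", "))
  bad <- which(bundle$reads$i < 0 | bundle$reads$u < bundle$reads$i)
  if (length(bad))
    stop("reads rows violating u >= i >= 0: ",
         paste(utils::head(bad, 5), collapse = ", "))
  for (tb in c("umi", "reads")) {
    bad <- which(!(bundle[[tb]]$cell_id %in% bundle$cells$cell_id))
    if (length(bad))
      stop(sprintf("%s rows referencing unknown cell_id: %s", tb,
                   paste(utils::head(bad, 5), collapse = ", ")))
    bad <- which(!(bundle[[tb]]$gene_id %in% bundle$genes$gene_id))
    if (length(bad))
      stop(sprintf("%s rows referencing unknown gene_id: %s", tb,
                   paste(utils::head(bad, 5), collapse = ", ")))
  }
  invisible(bundle)
}

#' Write / read a dataset bundle as tab-separated text
#'
#' @param bundle A `dataset_bundle`.
#' @param dir Directory to hold `cells.tsv`, `genes.tsv`, `umi.tsv`,
#'   `reads.tsv`, `meta.tsv`.
#' @return `write_bundle` returns `dir` invisibly; `read_bundle` returns a
#'   validated `dataset_bundle`.
#' @export
write_bundle <- function(bundle, dir) {
  validate_bundle(bundle)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name)
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  wr(bundle$cells, "cells.tsv")
  wr(bundle$genes, "genes.tsv")
  wr(bundle$umi, "umi.tsv")
  wr(bundle$reads, "reads.tsv")
  wr(data.frame(t = bundle$meta$t, lambda_n = bundle$meta$lambda_n),
     "meta.tsv")
  invisible(dir)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(dir) {
  rd <- function(name, colClasses) {
    path <- file.path(dir, name)
    if (!file.exists(path)) stop("missing bundle table: ", path)
    utils::read.delim(path, colClasses = colClasses,
                      stringsAsFactors = FALSE)
  }
  cells <- rd("cells.tsv", c(cell_id = "character", alpha = "numeric"))
  genes <- rd("genes.tsv", c(gene_id = "character", lambda_s = "numeric"))
  umi <- rd("umi.tsv", c(gene_id = "character", cell_id = "character",
                         l = "integer"))
  reads <- rd("reads.tsv", c(gene_id = "character", cell_id = "character",
                             u = "integer", i = "integer"))
  meta <- rd("meta.tsv", c(t = "numeric", lambda_n = "numeric"))
  dataset_bundle(cells, genes, umi, reads, as.list(meta))
}

#' Assemble per-gene observation objects from a bundle
#'
#' Builds one [gene_observations] per gene: per-cell UMI counts (cells
#' absent from the umi table count as `l = 0`), per-cell conversion
#' histograms from the reads table, the empirical uracil distribution from
#' the observed per-read genomic-T counts, and read-level totals for the
#' empirical lifetime estimate.
#'
#' @param bundle A `dataset_bundle`.
#' @return Named list of [gene_observations] objects.
#' @export
bundle_to_genes <- function(bundle) {
  validate_bundle(bundle)
  out <- list()
  for (g in bundle$genes$gene_id) {
    um <- bundle$umi[bundle$umi$gene_id == g, ]
    rd <- bundle$reads[bundle$reads$gene_id == g, ]
    l <- stats::setNames(rep(0L, nrow(bundle$cells)), bundle$cells$cell_id)
    l[um$cell_id] <- um$l
    ylist <- lapply(bundle$cells$cell_id, function(cid) {
      ii <- rd$i[rd$cell_id == cid]
      if (!length(ii)) return(integer(0))
      tab <- table(ii)
      stats::setNames(as.integer(tab), names(tab))
    })
    udist <- if (nrow(rd)) empirical_uracil_pmf(rd$u) else
      poisson_uracil_pmf(1)
    out[[g]] <- gene_observations(
      g, cells = data.frame(cell_id = bundle$cells$cell_id,
                            l = as.integer(l),
                            alpha = bundle$cells$alpha,
                            stringsAsFactors = FALSE),
      y = ylist,
      lambda_s = bundle$genes$lambda_s[bundle$genes$gene_id == g],
      udist = udist,
      total_T = sum(rd$u), total_TC = sum(rd$i))
  }
  out
}

#' Pack simulated genes into a dataset bundle
#'
#' @param sims Named list of [simulate_gene_dataset] results (one per gene).
#' @param t Pulse duration (minutes).
#' @param lambda_n 4sU conversion rate.
#' @param lambda_s Background conversion rate recorded per gene.
#' @return A `dataset_bundle`.  Cell ids and capture efficiencies are
#'   shared across genes, so the sims must have been generated with a
#'   common `alphas` vector (as [simulate_bundle] does).
#' @export
sims_to_bundle <- function(sims, t, lambda_n, lambda_s) {
  first <- sims[[1]]$gene
  cells <- data.frame(cell_id = first$cells$cell_id,
                      alpha = first$cells$alpha, stringsAsFactors = FALSE)
  genes <- data.frame(gene_id = names(sims),
                      lambda_s = rep(lambda_s, length(sims)),
                      stringsAsFactors = FALSE)
  umi <- do.call(rbind, lapply(names(sims), function(g) {
    ce <- sims[[g]]$gene$cells
    data.frame(gene_id = g, cell_id = ce$cell_id, l = ce$l,
               stringsAsFactors = FALSE)
  }))
  reads <- do.call(rbind, lapply(names(sims), function(g) {
    rd <- sims[[g]]$reads
    if (is.null(rd)) return(NULL)
    data.frame(gene_id = g,
               cell_id = sims[[g]]$gene$cells$cell_id[rd$cell],
               u = rd$u, i = rd$i, stringsAsFactors = FALSE)
  }))
  if (is.null(reads))
    reads <- data.frame(gene_id = character(), cell_id = character(),
                        u = integer(), i = integer())
  dataset_bundle(cells, genes, umi, reads,
                 list(t = t, lambda_n = lambda_n))
}

#' Simulate a multi-gene dataset bundle
#'
#' Draws one capture efficiency per cell (shared by all genes), simulates
#' each gene at its generating parameters and packs everything into a
#' `dataset_bundle` plus a truth table for recovery scoring.
#'
#' @param truth Data frame with columns `gene_id`, `mu`, `a`, `gamma`.
#' @param noise A [seq_noise_config].
#' @param seed Optional integer seed.
#' @return List with `bundle` (a `dataset_bundle`) and `truth` (the input
#'   table extended with `b`, `kappa`, `delta`).
#' @export
simulate_bundle <- function(truth, noise = seq_noise_config(), seed = NULL) {
  stopifnot(all(c("gene_id", "mu", "a", "gamma") %in% names(truth)))
  if (!is.null(seed)) set.seed(seed)
  alphas <- if (is.null(noise$alpha))
    rbeta(noise$N, noise$alpha_shape[1], noise$alpha_shape[2])
  else rep(noise$alpha, noise$N)
  alphas <- pmax(alphas, 1e-12)
  sims <- list()
  for (r in seq_len(nrow(truth))) {
    par <- burst_params(truth$mu[r], truth$a[r], truth$gamma[r])
    sims[[truth$gene_id[r]]] <-
      simulate_gene_dataset(par, noise, gene_id = truth$gene_id[r],
                            alphas = alphas)
  }
  truth$b <- truth$mu / truth$a
  truth$kappa <- truth$a / truth$gamma
  truth$delta <- 1 / truth$gamma
  list(bundle = sims_to_bundle(sims, t = noise$t1,
                               lambda_n = noise$lambda_n,
                               lambda_s = noise$lambda_s),
       truth = truth)
}
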