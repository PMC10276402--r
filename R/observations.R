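#' One cell's observations for a gene
#'
#' @param cell_id Identifier.
#' @param l UMI count (nonnegative integer).
#' @param alpha Capture efficiency in (0, 1].
#' @param y Conversion histogram: named integer vector mapping the
#'   conversion count `i` (names) to the number of reads showing `i`
#'   conversions.  May be empty.
#' @return Object of class `cell_observation`.
#' @export
cell_observation <- function(cell_id, l, alpha, y = integer(0)) {
  if (l < 0) stop("'l' must be nonnegative")
  if (alpha <= 0 || alpha > 1) stop("'alpha' must be in (0, 1]")
  if (length(y)) {
    if (is.null(names(y))) stop("'y' must be named by conversion count")
    if (any(y < 0)) stop("histogram values must be nonnegative")
  }
  structure(list(cell_id = as.character(cell_id), l = as.integer(l),
                 alpha = as.numeric(alpha), y = y),
            class = "cell_observation")
}

#' All observations for one gene
#'
#' Collects per-cell UMI counts, capture efficiencies and per-read T>C
#' conversion histograms, together with the gene's background conversion
#' rate and uracil-content distribution.  Histograms are stored internally
#' as a dense matrix with rows `i = 0..i_max` and one column per cell; the
#' pooled histogram is the row sum.
#'
#' @param gene_id Identifier.
#' @param cells Either a list of [cell_observation] objects or a data frame
#'   with columns `cell_id`, `l`, `alpha`.
#' @param y When `cells` is a data frame: a list (one per cell) of named
#'   integer vectors as in [cell_observation], or an `i x cells` matrix
#'   whose rows are conversion counts `0..i_max`.
#' @param lambda_s Gene-specific background conversion rate.
#' @param udist A `uracil_dist` for the gene.
#' @param total_T,total_TC Totals of genomic T bases and converted T bases
#'   over all reads of the gene (used for the empirical lifetime estimate);
#'   if `NA` they are reconstructed from the histogram/udist where possible.
#' @return Object of class `gene_obs` with fields `gene_id`, `cells`
#'   (data frame), `Y` (matrix), `pooled_y`, `lambda_s`, `udist`,
#'   `total_T`, `total_TC`.
#' @export
gene_observations <- function(gene_id, cells, y = NULL, lambda_s, udist,
                              total_T = NA_real_, total_TC = NA_real_) {
  if (is.list(cells) && !is.data.frame(cells) &&
      all(vapply(cells, inherits, logical(1), "cell_observation"))) {
    y <- lapply(cells, `[[`, "y")
    cells <- data.frame(
      cell_id = vapply(cells, `[[`, character(1), "cell_id"),
      l = vapply(cells, `[[`, integer(1), "l"),
      alpha = vapply(cells, `[[`, numeric(1), "alpha"),
      stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(cells),
            all(c("cell_id", "l", "alpha") %in% names(cells)))
  n <- nrow(cells)
  if (is.matrix(y)) {
    Y <- y
  } else {
    if (is.null(y)) y <- rep(list(integer(0)), n)
    stopifnot(length(y) == n)
    imax <- max(0L, unlist(lapply(y, function(h)
      if (length(h)) max(as.integer(names(h))) else 0L)))
    Y <- matrix(0, nrow = imax + 1L, ncol = n)
    for (c in seq_len(n)) {
      h <- y[[c]]
      if (length(h)) Y[as.integer(names(h)) + 1L, c] <- as.numeric(h)
    }
  }
  rownames(Y) <- 0:(nrow(Y) - 1L)
  if (lambda_s < 0 || lambda_s >= 1) stop("'lambda_s' must lie in [0, 1)")
  stopifnot(inherits(udist, "uracil_dist"))
  if (is.na(total_TC))
    total_TC <- sum((0:(nrow(Y) - 1L)) * rowSums(Y))
  if (is.na(total_T))
    total_T <- sum(Y) * sum(udist$u * udist$p)
  structure(list(gene_id = as.character(gene_id), cells = cells, Y = Y,
                 pooled_y = rowSums(Y), lambda_s = as.numeric(lambda_s),
                 udist = udist, total_T = as.numeric(total_T),
                 total_TC = as.numeric(total_TC)),
            class = "gene_obs")
}

#' @export
print.gene_obs <- function(x, ...) {
  cat(sprintf(
    "gene_obs '%s': %d cells, %d reads, lambda_s=%.4g, mean UMI=%.3g\n",
    x$gene_id, nrow(x$cells), sum(x$Y), x$lambda_s, mean(x$cells$l)))
  invisible(x)
}

# Observed conversion rate across all reads of the gene (converted Ts over
# genomic Ts), used by the empirical lifetime initialiser.
.observed_conversion_rate <- function(gene) {
  if (gene$total_T <= 0) return(NA_real_)
  gene$total_TC / gene$total_T
}
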