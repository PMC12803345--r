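#' Gene-level p-values by robust rank aggregation
#'
#' Aggregates the p-values of the CpGs mapped to each gene into a single
#' gene-level p-value. With the k CpG p-values of a gene sorted ascending
#' as \eqn{r_{(1)} \le \dots \le r_{(k)}}, the rank-aggregation statistic is
#' \deqn{\rho = \min_j \Pr\{\mathrm{Beta}(j, k - j + 1) \le r_{(j)}\},}
#' i.e. the most surprising order statistic relative to its null Beta
#' distribution, and the gene p-value is the Bonferroni bound
#' \eqn{\min(k\rho, 1)}, which adjusts for genes carrying different numbers
#' of CpGs. The construction is conservative under the global null.
#'
#' @param pvals CpG p-values in [0, 1].
#' @param genes Gene label per CpG (a CpG mapped to several genes appears
#'   once per gene).
#' @return A data.frame with `gene`, `n_cpgs`, `rho`, `p`, sorted by `p`
#'   then gene name.
#' @examples
#' gene_pvalue_rra(c(0.01, 0.5), c("G1", "G1"))
#' @export
gene_pvalue_rra <- function(pvals, genes) {
  stopifnot(length(pvals) == length(genes))
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1] with no NAs")
  by_gene <- split(pvals, as.character(genes))
  rows <- lapply(names(by_gene), function(g) {
    p <- sort(by_gene[[g]])
    k <- length(p)
    rho <- min(stats::pbeta(p, seq_len(k), k - seq_len(k) + 1))
    data.frame(gene = g, n_cpgs = k, rho = rho, p = min(k * rho, 1),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p, out$gene), ]
  rownames(out) <- NULL
  out
}
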