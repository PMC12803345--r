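#' Pre-ranked gene set enrichment analysis
#'
#' Weighted Kolmogorov-Smirnov enrichment on a ranked gene list. Genes are
#' ranked by decreasing score (intended use: -log10 gene-level p-values
#' from [gene_pvalue_rra()]), ties broken by gene name for determinism.
#' Walking down the list, the running sum gains |score|/sum(|score| in set)
#' at set members and loses 1/(N - set size) elsewhere; the enrichment
#' score (ES) is the extremum of the running sum. The permutation null
#' shuffles gene labels (`n_perm` random sets of the same size), the
#' normalized ES divides by the mean |null ES| of the same sign, and the
#' permutation p-value compares against same-sign null ES values. Sets are
#' filtered to `min_size`-`max_size` genes present in the ranking; a set is
#' flagged significant only when its BH FDR is at or below `fdr_threshold`
#' and its leading edge (members contributing before the ES extremum)
#' holds at least `min_leading_edge` genes, so single-gene signals cannot
#' drive a pathway call.
#'
#' @param scores Named numeric vector of gene scores (larger = stronger).
#' @param gene_sets Named list of character vectors (e.g. from
#'   [read_gmt()]).
#' @param n_perm Number of label permutations (default 1000; fewer than 100
#'   triggers a warning).
#' @param seed Integer seed for the permutations.
#' @param min_size,max_size Set size bounds after intersecting with the
#'   ranked genes (defaults 5 and 200).
#' @param fdr_threshold FDR gate for the significance flag (default 0.25).
#' @param min_leading_edge Minimum core-enrichment genes (default 3).
#' @return A data.frame with one row per tested set: `set`, `size`, `es`,
#'   `nes`, `p`, `fdr_q`, `n_leading_edge`, `significant`, and the
#'   `leading_edge` gene list as a list-column.
#' @export
preranked_gsea <- function(scores, gene_sets, n_perm = 1000, seed = 1,
                           min_size = 5, max_size = 200,
                           fdr_threshold = 0.25, min_leading_edge = 3) {
  if (length(scores) < 50) stop("need at least 50 ranked genes")
  if (is.null(names(scores))) stop("scores must be named by gene")
  if (n_perm < 100) warning("fewer than 100 permutations; p-values are coarse")
  ord <- order(-scores, names(scores))
  s <- abs(scores[ord])
  genes <- names(scores)[ord]
  N <- length(genes)

  sets <- lapply(gene_sets, function(g) which(genes %in% g))
  sizes <- lengths(sets)
  keep <- sizes >= min_size & sizes <= max_size
  sets <- sets[keep]
  if (!length(sets))
    return(data.frame(set = character(), size = integer(), es = numeric(),
                      nes = numeric(), p = numeric(), fdr_q = numeric(),
                      n_leading_edge = integer(), significant = logical()))

  es_stat <- function(hit_pos, return_edge = FALSE) {
    k <- length(hit_pos)
    delta <- rep(-1 / (N - k), N)
    nr <- sum(s[hit_pos])
    delta[hit_pos] <- if (nr > 0) s[hit_pos] / nr else 1 / k
    run <- cumsum(delta)
    i_max <- which.max(run); i_min <- which.min(run)
    es <- if (abs(run[i_max]) >= abs(run[i_min])) run[i_max] else run[i_min]
    if (!return_edge) return(es)
    edge <- if (es >= 0) hit_pos[hit_pos <= i_max] else hit_pos[hit_pos >= i_min]
    list(es = es, edge = genes[sort(edge)])
  }

  set.seed(as.integer(seed))
  rows <- lapply(names(sets), function(nm) {
    hit <- sets[[nm]]
    obs <- es_stat(hit, return_edge = TRUE)
    null_es <- vapply(seq_len(n_perm), function(b)
      es_stat(sample.int(N, length(hit))), numeric(1))
    same <- null_es[sign(null_es) == sign(obs$es)]
    p <- (1 + sum(abs(same) >= abs(obs$es))) / (1 + length(same))
    nes <- if (length(same)) obs$es / mean(abs(same)) else NA_real_
    data.frame(set = nm, size = length(hit), es = obs$es, nes = nes, p = p,
               n_leading_edge = length(obs$edge),
               leading_edge = I(list(obs$edge)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr_q <- bh_fdr(out$p)
  out$significant <- out$fdr_q <= fdr_threshold &
    out$n_leading_edge >= min_leading_edge
  out <- out[order(out$p, out$set),
             c("set", "size", "es", "nes", "p", "fdr_q",
               "n_leading_edge", "significant", "leading_edge")]
  rownames(out) <- NULL
  out
}
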