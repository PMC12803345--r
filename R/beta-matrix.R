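#' CpG-by-subject methylation matrix with genomic coordinates
#'
#' Light container pairing a numeric matrix of methylation beta values
#' (rows = CpGs, columns = subjects) with per-CpG genomic annotation.
#' Rows are stored sorted by chromosome then position.
#'
#' @param beta Numeric matrix in (0, 1), one row per CpG, one column per
#'   subject; column names are subject ids.
#' @param cpg_id Character vector of CpG identifiers (unique).
#' @param chrom Chromosome per CpG (e.g. "chr1").
#' @param pos 1-based basepair position per CpG.
#' @return An object of class `beta_matrix` with elements `beta`, `cpg_id`,
#'   `chrom`, `pos`.
#' @export
beta_matrix <- function(beta, cpg_id, chrom, pos) {
  beta <- as.matrix(beta)
  n <- nrow(beta)
  stopifnot(length(cpg_id) == n, length(chrom) == n, length(pos) == n,
            !anyDuplicated(cpg_id))
  if (any(!is.finite(beta)) || any(beta <= 0) || any(beta >= 1))
    stop("beta values must lie strictly inside (0, 1)")
  ord <- order(chrom, pos)
  if (anyDuplicated(cbind(chrom, pos)[ord, , drop = FALSE]))
    stop("duplicate chromosome/position pairs")
  out <- list(beta = beta[ord, , drop = FALSE],
              cpg_id = as.character(cpg_id)[ord],
              chrom = as.character(chrom)[ord],
              pos = as.integer(pos)[ord])
  rownames(out$beta) <- out$cpg_id
  class(out) <- "beta_matrix"
  out
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat("beta_matrix:", nrow(x$beta), "CpGs x", ncol(x$beta), "subjects on",
      length(unique(x$chrom)), "chromosome(s)\n")
  invisible(x)
}

#' @export
dim.beta_matrix <- function(x) dim(x$beta)

#' Subset a beta matrix by CpG id
#'
#' @param x A [beta_matrix()].
#' @param cpg_ids CpG identifiers to retain (all must be present).
#' @return A `beta_matrix` restricted to the requested CpGs.
#' @export
subset_cpgs <- function(x, cpg_ids) {
  stopifnot(inherits(x, "beta_matrix"))
  idx <- match(cpg_ids, x$cpg_id)
  if (anyNA(idx)) stop("unknown CpG id(s): ",
                       paste(cpg_ids[is.na(idx)], collapse = ", "))
  beta_matrix(x$beta[idx, , drop = FALSE], x$cpg_id[idx],
              x$chrom[idx], x$pos[idx])
}
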