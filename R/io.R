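#' Read and write the pipeline's tabular formats
#'
#' Betas travel as TSV with columns `cpg_id`, `chrom`, `pos` (1-based)
#' followed by one column per subject; phenotype and longitudinal tables as
#' plain CSV. These helpers keep the on-disk layout in one place.
#'
#' @param x A [beta_matrix()] (for writing) .
#' @param path File path.
#' @return `read_beta_matrix()` returns a [beta_matrix()];
#'   `write_beta_matrix()` returns `path` invisibly.
#' @name beta_io
NULL

#' @rdname beta_io
#' @export
write_beta_matrix <- function(x, path) {
  stopifnot(inherits(x, "beta_matrix"))
  df <- data.frame(cpg_id = x$cpg_id, chrom = x$chrom, pos = x$pos,
                   x$beta, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname beta_io
#' @export
read_beta_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  beta_matrix(as.matrix(df[, -(1:3), drop = FALSE]),
              df$cpg_id, df$chrom, df$pos)
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated as name, description,
#' then member genes. Parsed with `fgsea::gmtPathways()` when fgsea is
#' installed, otherwise by direct line splitting.
#'
#' @param path Path to a `.gmt` file.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (requireNamespace("fgsea", quietly = TRUE))
    return(fgsea::gmtPathways(path))
  lines <- strsplit(readLines(path), "\t", fixed = TRUE)
  stats::setNames(lapply(lines, function(x) x[-(1:2)]),
                  vapply(lines, `[`, "", 1))
}
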