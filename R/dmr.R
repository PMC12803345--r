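#' Distance-binned autocorrelation of association signals
#'
#' Estimates how correlated nearby probes' test signals are, as a function
#' of genomic distance. p-values are mapped to one-sided normal quantiles
#' z = qnorm(1 - p) and, for every pair of same-chromosome probes whose
#' distance falls inside a bin, the Pearson correlation of the paired z
#' values is computed per bin. The result feeds the correlation-adjusted
#' Stouffer-Liptak combination used for region detection.
#'
#' @param pvals Per-probe p-values.
#' @param chrom,pos Chromosome and 1-based position per probe; positions
#'   must be sorted within chromosome.
#' @param max_dist Largest pair distance considered (bp, default 750).
#' @param bin_width Width of the distance bins (bp, default 50).
#' @return An object of class `acf_table`: data.frame with the bin upper
#'   bounds (`upper`, covering (0, max_dist]) and the per-bin correlation
#'   (`corr`). The lag-0 correlation is 1 by definition and is not stored.
#' @export
estimate_acf <- function(pvals, chrom, pos, max_dist = 750, bin_width = 50) {
  check_sorted_probes(chrom, pos)
  z <- p_to_z(pvals)
  uppers <- seq(bin_width, max_dist, by = bin_width)
  if (uppers[length(uppers)] < max_dist) uppers <- c(uppers, max_dist)
  pairs_a <- vector("list", length(uppers))
  pairs_b <- vector("list", length(uppers))
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    p_ch <- pos[idx]
    for (ii in seq_along(idx)) {
      jj <- ii + 1L
      while (jj <= length(idx) && p_ch[jj] - p_ch[ii] <= max_dist) {
        b <- bin_index(p_ch[jj] - p_ch[ii], uppers)
        pairs_a[[b]] <- c(pairs_a[[b]], z[idx[ii]])
        pairs_b[[b]] <- c(pairs_b[[b]], z[idx[jj]])
        jj <- jj + 1L
      }
    }
  }
  corr <- vapply(seq_along(uppers), function(b) {
    if (length(pairs_a[[b]]) < 2 ||
        stats::sd(pairs_a[[b]]) == 0 || stats::sd(pairs_b[[b]]) == 0) {
      warning("distance bin (", if (b == 1) 0 else uppers[b - 1], ", ",
              uppers[b], "] has no usable probe pairs; correlation set to 0")
      return(0)
    }
    stats::cor(pairs_a[[b]], pairs_b[[b]])
  }, numeric(1))
  out <- data.frame(upper = uppers, corr = corr)
  class(out) <- c("acf_table", "data.frame")
  out
}

bin_index <- function(d, uppers) {
  ## bins are (0, u1], (u1, u2], ...
  which(d <= uppers)[1]
}

## one-sided z transform; p clipped away from {0, 1} to keep z finite
p_to_z <- function(p) {
  p <- pmin(pmax(p, 1e-300), 1 - 1e-16)
  stats::qnorm(p, lower.tail = FALSE)
}

## correlation at distance d from an acf table: 1 at lag 0, binned value
## inside (0, max_dist], 0 beyond; negative estimates clipped to 0 so the
## combined variance is never deflated
acf_rho <- function(d, acf) {
  r <- numeric(length(d))
  r[d == 0] <- 1
  inside <- d > 0 & d <= acf$upper[nrow(acf)]
  if (any(inside)) {
    b <- vapply(d[inside], bin_index, integer(1), uppers = acf$upper)
    r[inside] <- pmax(acf$corr[b], 0)
  }
  r
}

#' Correlation-adjusted Stouffer-Liptak smoothing of probe p-values
#'
#' For each probe, combines the one-sided z scores of all probes within a
#' centered window using the Stouffer-Liptak statistic with the
#' distance-binned correlation: z_comb = sum(z) / sqrt(sum of the pairwise
#' correlation matrix), adjusted p = 1 - Phi(z_comb). A probe with no
#' neighbours in the window keeps its original p-value.
#'
#' @param pvals,chrom,pos Probe p-values and sorted genomic coordinates.
#' @param acf An [estimate_acf()] table.
#' @param window Full window width in bp (default 750; neighbours within
#'   +/- window/2 are combined).
#' @return Adjusted p-value per probe.
#' @export
slk_smooth <- function(pvals, chrom, pos, acf, window = 750) {
  check_sorted_probes(chrom, pos)
  z <- p_to_z(pvals)
  half <- window / 2
  out <- numeric(length(pvals))
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    p_ch <- pos[idx]
    for (ii in seq_along(idx)) {
      nb <- idx[abs(p_ch - p_ch[ii]) <= half]
      if (length(nb) == 1L) { out[idx[ii]] <- pvals[idx[ii]]; next }
      d <- abs(outer(pos[nb], pos[nb], "-"))
      denom <- sum(acf_rho(as.vector(d), acf))
      zc <- sum(z[nb]) / sqrt(denom)
      out[idx[ii]] <- stats::pnorm(zc, lower.tail = FALSE)
    }
  }
  out
}

#' Seed-and-extend candidate region finder
#'
#' Starts a region at any probe whose adjusted p-value falls below `seed_p`
#' and extends it through subsequent sub-threshold probes as long as the gap
#' to the previous included probe is at most `dist` bp (inclusive).
#' Intervals are reported 0-based half-open with end = last probe position
#' + 1.
#'
#' @param adjusted_p Smoothed p-values (see [slk_smooth()]).
#' @param chrom,pos Sorted genomic coordinates.
#' @param seed_p Threshold to start/extend a region (default 0.05).
#' @param dist Maximum gap between consecutive qualifying probes (bp,
#'   default 750).
#' @return A list of candidate regions, each a list with `chrom`, `start`,
#'   `end` and `idx` (indices of member probes in input order).
#' @export
find_regions <- function(adjusted_p, chrom, pos, seed_p = 0.05, dist = 750) {
  check_sorted_probes(chrom, pos)
  regions <- list()
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch & adjusted_p < seed_p)
    if (!length(idx)) next
    gaps <- diff(pos[idx])
    grp <- cumsum(c(1L, as.integer(gaps > dist)))
    for (g in split(idx, grp)) {
      regions[[length(regions) + 1L]] <-
        list(chrom = ch, start = pos[g[1]], end = pos[g[length(g)]] + 1L,
             idx = g)
    }
  }
  regions
}

#' Stouffer-Liptak p-value of a region
#'
#' Combines the original (unsmoothed) p-values of a region's probes with
#' the correlation-adjusted Stouffer statistic, the pairwise correlations
#' coming from the distance-binned autocorrelation table (0 beyond its last
#' bin). A single-probe region keeps its original p-value.
#'
#' @param region_idx Indices of the region's probes.
#' @param pvals,pos Probe p-values and positions (full vectors).
#' @param acf An [estimate_acf()] table.
#' @return The combined region p-value.
#' @export
region_pvalue <- function(region_idx, pvals, pos, acf) {
  stopifnot(length(region_idx) >= 1)
  if (length(region_idx) == 1L) return(pvals[region_idx])
  z <- p_to_z(pvals[region_idx])
  d <- abs(outer(pos[region_idx], pos[region_idx], "-"))
  denom <- sum(acf_rho(as.vector(d), acf))
  stats::pnorm(sum(z) / sqrt(denom), lower.tail = FALSE)
}

#' Sidak multiplicity adjustment for a region
#'
#' Adjusts a region p-value for the number of effective tests, taken as the
#' ratio of the total probe-covered bases to the region length:
#' sidak_p = 1 - (1 - p)^(total/region). Computed via log1p/expm1 so tiny
#' p-values stay accurate.
#'
#' @param p_region Combined region p-value.
#' @param region_len_bp Region length in bp (>= 1).
#' @param total_covered_bp Total bases covered by tested probes
#'   (>= region_len_bp).
#' @return The Sidak-adjusted p-value.
#' @examples
#' sidak_adjust(1e-6, 400, 4e5)
#' @export
sidak_adjust <- function(p_region, region_len_bp, total_covered_bp) {
  stopifnot(region_len_bp >= 1, total_covered_bp >= region_len_bp)
  if (p_region <= 0) return(0)
  if (p_region >= 1) return(1)
  -expm1(total_covered_bp / region_len_bp * log1p(-p_region))
}

#' Consistent-direction filter and DMR records
#'
#' Keeps only regions whose member CpGs all share the sign of the
#' interaction estimate, and builds the per-probe direction string ("+"/"-",
#' in position order). A zero estimate is treated as inconsistent. This
#' guards against regions assembled from probes with opposing moderation
#' directions.
#'
#' @param regions A list of scored regions, each carrying `chrom`, `start`,
#'   `end`, `idx`, `p_region`, `sidak_p`.
#' @param ewas An `ewas_result` whose rows (by position) the region indices
#'   refer to.
#' @return A data.frame of DMR records: `chrom`, `start`, `end` (0-based
#'   half-open), `n_probes`, `p_region`, `sidak_p`, `direction`.
#' @export
direction_filter <- function(regions, ewas) {
  recs <- lapply(regions, function(r) {
    est <- ewas$estimate[r$idx]
    if (anyNA(est)) return(NULL)
    sgn <- sign(est)
    if (any(sgn == 0) || length(unique(sgn)) != 1L) return(NULL)
    data.frame(chrom = r$chrom, start = r$start, end = r$end,
               n_probes = length(r$idx), p_region = r$p_region,
               sidak_p = r$sidak_p,
               direction = paste(ifelse(sgn > 0, "+", "-"), collapse = ""),
               stringsAsFactors = FALSE)
  })
  recs <- recs[!vapply(recs, is.null, logical(1))]
  if (!length(recs))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), n_probes = integer(),
                      p_region = numeric(), sidak_p = numeric(),
                      direction = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Genome-wide differentially methylated region scan
#'
#' Full region pipeline on an EWAS result: estimate the distance-binned
#' autocorrelation of the interaction p-values, smooth them with the
#' correlation-adjusted Stouffer-Liptak window, seed-and-extend candidate
#' regions, score each region from the original p-values, apply the Sidak
#' multiplicity adjustment, and keep regions with at least `min_probes`
#' probes, Sidak p below `sidak_threshold`, and a consistent direction of
#' the interaction estimates.
#'
#' The Sidak denominator uses the total probe-covered bases, computed as the
#' sum over probes of the distance to the next same-chromosome probe capped
#' at 2 * `dist` (the cap also serves as the contribution of each
#' chromosome's last probe).
#'
#' @param ewas An `ewas_result`; rows must be position-sorted within
#'   chromosome (as produced by [run_ewas()]).
#' @param p_col Column holding the per-CpG p-values (default `"p_bacon"`,
#'   falling back to `"p_value"` if absent).
#' @param seed_p,dist Seed threshold and extension distance (defaults 0.05
#'   and 750 bp).
#' @param bin_width Autocorrelation bin width in bp.
#' @param sidak_threshold Reporting threshold on the Sidak p (default 0.05).
#' @param min_probes Minimum probes per reported region (default 3).
#' @return A data.frame of DMR records (see [direction_filter()]), ordered
#'   by `sidak_p`, with the acf table and candidate count as attributes.
#' @export
detect_dmrs <- function(ewas, p_col = "p_bacon", seed_p = 0.05, dist = 750,
                        bin_width = 50, sidak_threshold = 0.05,
                        min_probes = 3) {
  if (!p_col %in% names(ewas)) p_col <- "p_value"
  okf <- !is.na(ewas[[p_col]])
  e <- ewas[okf, , drop = FALSE]
  p <- e[[p_col]]
  acf <- estimate_acf(p, e$chrom, e$pos, max_dist = dist,
                      bin_width = bin_width)
  sm <- slk_smooth(p, e$chrom, e$pos, acf, window = dist)
  cand <- find_regions(sm, e$chrom, e$pos, seed_p = seed_p, dist = dist)
  total_cov <- total_covered_bp(e$chrom, e$pos, cap = 2 * dist)
  cand <- lapply(cand, function(r) {
    r$p_region <- region_pvalue(r$idx, p, e$pos, acf)
    r$sidak_p <- sidak_adjust(r$p_region, max(r$end - r$start, 1), total_cov)
    r
  })
  keep <- vapply(cand, function(r)
    length(r$idx) >= min_probes && r$sidak_p < sidak_threshold, logical(1))
  out <- direction_filter(cand[keep], e)
  out <- out[order(out$sidak_p), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "acf") <- acf
  attr(out, "n_candidates") <- length(cand)
  out
}

total_covered_bp <- function(chrom, pos, cap) {
  total <- 0
  for (ch in unique(chrom)) {
    p_ch <- pos[chrom == ch]
    total <- total + sum(pmin(diff(p_ch), cap)) + cap
  }
  total
}

check_sorted_probes <- function(chrom, pos) {
  for (ch in unique(chrom)) {
    p_ch <- pos[chrom == ch]
    if (is.unsorted(p_ch, strictly = FALSE))
      stop("positions must be sorted within chromosome (", ch, ")")
  }
  invisible(TRUE)
}
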