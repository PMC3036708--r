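#' Per-SNP allele-frequency chi-square scan between two groups
#'
#' For every SNP, a 1-df chi-square (no continuity correction) on the 2x2
#' table of allele counts (A1/A2 x group), using non-missing genotypes
#' only.  SNPs monomorphic across both groups get chi2 = 0, p = 1 and are
#' flagged; SNPs with no data in one of the groups are flagged as
#' degenerate and should be excluded from downstream lambda input.
#'
#' @param G a \code{genotype_matrix}.
#' @param two_group_labels per-sample labels with exactly two levels.
#' @return data.frame (class \code{scan_result}) with columns
#'   \code{locus_id}, \code{chrom}, \code{pos_bp}, \code{chi2}, \code{p},
#'   \code{monomorphic}, \code{degenerate}.
#' @export
chisq_scan <- function(G, two_group_labels) {
  lv <- unique(two_group_labels)
  if (length(lv) != 2) stop("exactly two groups required")
  cs <- .allele_chisq(G$dosage, two_group_labels)
  out <- data.frame(locus_id = G$locus_ids, chrom = G$chrom,
                    pos_bp = G$pos_bp, chi2 = cs$chi2,
                    p = stats::pchisq(cs$chi2, 1, lower.tail = FALSE),
                    monomorphic = cs$monomorphic,
                    degenerate = cs$degenerate)
  class(out) <- c("scan_result", class(out))
  out
}

#' Overdispersion factor lambda of a chi-square scan
#'
#' The ratio of the means of the smallest 90 percent of the observed 1-df
#' chi-square statistics to the means of the corresponding expected
#' order-statistic quantiles, qchisq((i - 0.5) / m, df = 1) for ranks
#' i = 1..floor(0.9 m).  Lambda = 1 indicates no allele-frequency
#' difference beyond sampling noise.
#'
#' @param chi2_values observed statistics (>= 10 finite values).
#' @return lambda (> 0).
#' @export
lambda_overdispersion <- function(chi2_values) {
  x <- chi2_values[is.finite(chi2_values)]
  m <- length(x)
  if (m < 10) stop("need at least 10 finite chi-square statistics")
  if (all(x == 0)) stop("all statistics zero; lambda undefined")
  k <- floor(0.9 * m)
  obs <- sort(x)[seq_len(k)]
  expd <- stats::qchisq((seq_len(k) - 0.5) / m, df = 1)
  mean(obs) / mean(expd)
}

#' QQ-plot coordinates for a chi-square scan
#'
#' @param chi2_values observed statistics.
#' @return data.frame with \code{expected} (1-df quantiles at
#'   (i - 0.5)/m) and \code{observed} (sorted), ascending.
#' @export
qq_coordinates <- function(chi2_values) {
  x <- sort(chi2_values[is.finite(chi2_values)])
  m <- length(x)
  data.frame(expected = stats::qchisq((seq_len(m) - 0.5) / m, df = 1),
             observed = x)
}

#' Fraction of SNPs significant at a threshold
#'
#' @param p_values per-SNP p-values (non-empty).
#' @param alpha significance threshold in (0, 1).
#' @return #\{p < alpha\} / m.
#' @export
significant_fraction <- function(p_values, alpha = 0.05) {
  if (length(p_values) == 0) stop("empty p-value vector")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0,1)")
  mean(p_values < alpha)
}

# gap in bp between a position and a half-open gene interval [start, end)
.gene_gap <- function(pos, start, end) {
  ifelse(pos < start, start - pos,
         ifelse(pos >= end, pos - end + 1L, 0L))
}

#' Annotate top-scan SNPs with their nearest gene
#'
#' For every SNP with p below the cutoff, reports the nearest gene by
#' minimal base-pair gap (0 if the SNP lies inside the gene), omitting SNPs
#' whose nearest gene is farther than \code{max_dist} (200 kb by default).
#' Equidistant genes are all reported; the primary one is the gene with the
#' lower start position.
#'
#' @param scan a \code{\link{chisq_scan}} result.
#' @param genes data.frame with \code{gene_id}, \code{chrom},
#'   \code{start_bp}, \code{end_bp} (1-based start, half-open end), sorted
#'   by start within each chromosome.
#' @param p_cutoff scan p-value cutoff.
#' @param max_dist maximal gap in bp (default 200,000).
#' @return data.frame with \code{locus_id}, \code{p}, \code{gene_id},
#'   \code{distance_bp}, \code{primary}.
#' @export
annotate_top_snps <- function(scan, genes, p_cutoff, max_dist = 200000) {
  stopifnot(all(c("gene_id", "chrom", "start_bp", "end_bp") %in% names(genes)))
  if (any(genes$start_bp >= genes$end_bp)) stop("gene with start >= end")
  for (ch in unique(genes$chrom)) {
    st <- genes$start_bp[genes$chrom == ch]
    if (is.unsorted(st)) stop("gene table not sorted by start on chromosome ", ch)
  }
  top <- scan[scan$p < p_cutoff, , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(top))) {
    g <- genes[genes$chrom == top$chrom[i], , drop = FALSE]
    if (nrow(g) == 0) next
    gaps <- .gene_gap(top$pos_bp[i], g$start_bp, g$end_bp)
    dmin <- min(gaps)
    if (dmin > max_dist) next
    hit <- g[gaps == dmin, , drop = FALSE]
    rows[[length(rows) + 1]] <-
      data.frame(locus_id = top$locus_id[i], p = top$p[i],
                 gene_id = hit$gene_id, distance_bp = dmin,
                 primary = hit$start_bp == min(hit$start_bp))
  }
  if (length(rows) == 0)
    return(data.frame(locus_id = character(), p = numeric(),
                      gene_id = character(), distance_bp = integer(),
                      primary = logical()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Count significant SNPs inside genomic intervals
#'
#' Compares the number of scan-significant SNPs lying inside a set of
#' half-open genomic intervals with the count expected if significant SNPs
#' were spread evenly (interval SNP count times the overall significant
#' fraction), and reports an upper binomial tail p.  The result carries a
#' caveat flag: the binomial model ignores local LD, so the p-value is
#' indicative only.
#'
#' @param scan a \code{\link{chisq_scan}} result.
#' @param intervals data.frame with \code{chrom}, \code{start_bp},
#'   \code{end_bp} (half-open); non-empty.
#' @param alpha significance threshold.
#' @return list with \code{observed}, \code{expected}, \code{n_in},
#'   \code{p_binomial}, \code{ld_caveat} = TRUE.
#' @export
interval_overlap_count <- function(scan, intervals, alpha = 0.05) {
  if (nrow(intervals) == 0) stop("empty interval set")
  inside <- rep(FALSE, nrow(scan))
  for (i in seq_len(nrow(intervals)))
    inside <- inside | (scan$chrom == intervals$chrom[i] &
                          scan$pos_bp >= intervals$start_bp[i] &
                          scan$pos_bp < intervals$end_bp[i])
  n_in <- sum(inside)
  if (n_in == 0) stop("intervals cover no SNPs")
  frac <- significant_fraction(scan$p, alpha)
  observed <- sum(inside & scan$p < alpha)
  list(observed = observed, expected = n_in * frac, n_in = n_in,
       p_binomial = stats::pbinom(observed - 1, n_in, frac,
                                  lower.tail = FALSE),
       ld_caveat = TRUE)
}
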