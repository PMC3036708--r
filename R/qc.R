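#' Quality-control thresholds
#'
#' Bundles the standard GWAS-era filters: per-sample and per-SNP call rate,
#' exact Hardy-Weinberg p, minor allele frequency, near-duplicate IBS
#' distance, cross-platform concordance p, and case/control association p.
#'
#' @param sample_callrate minimum per-sample genotyping success (default
#'   0.99; 0.97 is the conventional relaxation for noisier platforms).
#' @param snp_callrate minimum per-SNP success (default 0.95).
#' @param hwe_p exact HWE p-value below which a SNP is removed (default 1e-7).
#' @param maf minimum minor allele frequency on the retained dataset
#'   (default 0.05).
#' @param dup_ibs_distance IBS distance (1 - IBS) below which a sample pair
#'   counts as near-duplicate (default 0.05).
#' @param concordance_p chi-square p below which a SNP is discordant
#'   between platforms (default 1e-10).
#' @param case_control_p chi-square p below which a SNP is excluded as
#'   case/control-associated (default 0.1).
#' @return a \code{qc_thresholds} list.
#' @export
qc_thresholds <- function(sample_callrate = 0.99, snp_callrate = 0.95,
                          hwe_p = 1e-7, maf = 0.05,
                          dup_ibs_distance = 0.05,
                          concordance_p = 1e-10, case_control_p = 0.1) {
  stopifnot(sample_callrate > 0, sample_callrate <= 1,
            snp_callrate > 0, snp_callrate <= 1,
            maf > 0, maf <= 1, dup_ibs_distance > 0, dup_ibs_distance <= 1,
            hwe_p > 0, hwe_p < 1, concordance_p > 0, concordance_p < 1,
            case_control_p > 0, case_control_p < 1)
  structure(list(sample_callrate = sample_callrate,
                 snp_callrate = snp_callrate, hwe_p = hwe_p, maf = maf,
                 dup_ibs_distance = dup_ibs_distance,
                 concordance_p = concordance_p,
                 case_control_p = case_control_p),
            class = "qc_thresholds")
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact test on a single biallelic genotype table: conditioning
#' on the allele counts, the p-value is the total probability of all
#' heterozygote counts whose conditional probability does not exceed that of
#' the observed count.  Used rather than the asymptotic chi-square because
#' QC thresholds like 1e-7 live deep in the tail.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (non-negative, sum >= 1).
#' @return exact p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop("all genotype counts are zero")
  m <- min(2 * n_AA + n_Aa, 2 * n_aa + n_Aa)  # minor allele count
  if (m == 0) return(1)
  hets <- seq(m %% 2, m, by = 2)
  # log conditional probability of h heterozygotes given n, m
  logp <- lfactorial(n) - lfactorial((m - hets) / 2) - lfactorial(hets) -
    lfactorial(n - (m + hets) / 2) + hets * log(2) +
    lfactorial(m) + lfactorial(2 * n - m) - lfactorial(2 * n)
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  obs <- pr[match(n_Aa, hets)]
  min(1, sum(pr[pr <= obs * (1 + 1e-9)]))
}

# per-locus A1 allele frequency, non-missing count and heterozygote count
.locus_summary <- function(dosage) {
  nm <- colSums(!is.na(dosage))
  s <- colSums(dosage, na.rm = TRUE)
  list(n = nm, p = ifelse(nm > 0, s / (2 * nm), NA_real_),
       het = colSums(dosage == 1, na.rm = TRUE))
}

#' Apply the standard QC filter cascade
#'
#' Filters in a fixed, documented order: (1) samples by call rate, (2) SNPs
#' by call rate, (3) SNPs failing exact HWE in any listed population,
#' (4) SNPs by minor allele frequency on the whole retained dataset.
#'
#' @param G a \code{genotype_matrix}.
#' @param S sample table aligned to \code{G} (used only to resolve
#'   population labels given as a column name); may be NULL.
#' @param thresholds a \code{\link{qc_thresholds}}.
#' @param populations_for_hwe either NULL (HWE on the whole sample), a
#'   character vector of per-sample population labels, or the name of a
#'   column of \code{S}.
#' @return list with the filtered \code{G} and a \code{report} (data.frames
#'   \code{removed_samples}, \code{removed_snps}, and before/after counts).
#' @export
apply_qc <- function(G, S = NULL, thresholds = qc_thresholds(),
                     populations_for_hwe = NULL) {
  stopifnot(inherits(G, "genotype_matrix"))
  pops <- populations_for_hwe
  if (is.character(pops) && length(pops) == 1 && !is.null(S) &&
      pops %in% names(S))
    pops <- S[[pops]][match(G$sample_ids, S$sample_id)]
  removed_samples <- data.frame(sample_id = character(), reason = character(),
                                statistic = numeric())
  removed_snps <- data.frame(locus_id = character(), reason = character(),
                             statistic = numeric())
  n0 <- length(G$sample_ids); L0 <- length(G$locus_ids)

  # 1. sample call rate
  cr_s <- rowMeans(!is.na(G$dosage))
  drop_s <- which(cr_s < thresholds$sample_callrate)
  if (length(drop_s)) {
    removed_samples <- data.frame(sample_id = G$sample_ids[drop_s],
                                  reason = "sample_callrate",
                                  statistic = cr_s[drop_s])
    if (!is.null(pops)) pops <- pops[-drop_s]
    G <- subset_genotypes(G, samples = setdiff(seq_len(n0), drop_s))
  }
  if (length(G$sample_ids) == 0) stop("QC removed every sample")

  # 2. SNP call rate
  cr_l <- colMeans(!is.na(G$dosage))
  drop_l <- which(cr_l < thresholds$snp_callrate)
  if (length(drop_l)) {
    removed_snps <- rbind(removed_snps,
                          data.frame(locus_id = G$locus_ids[drop_l],
                                     reason = "snp_callrate",
                                     statistic = cr_l[drop_l]))
    G <- subset_genotypes(G, loci = setdiff(seq_along(G$locus_ids), drop_l))
  }

  # 3. exact HWE within each listed population
  if (is.null(pops)) pops <- rep("all", length(G$sample_ids))
  hwe_min <- rep(1, length(G$locus_ids))
  for (pop in unique(pops)) {
    dd <- G$dosage[pops == pop, , drop = FALSE]
    nAA <- colSums(dd == 2, na.rm = TRUE)
    nAa <- colSums(dd == 1, na.rm = TRUE)
    naa <- colSums(dd == 0, na.rm = TRUE)
    ok <- (nAA + nAa + naa) > 0
    pv <- rep(1, length(hwe_min))
    pv[ok] <- mapply(hwe_exact_test, nAA[ok], nAa[ok], naa[ok])
    hwe_min <- pmin(hwe_min, pv)
  }
  drop_h <- which(hwe_min < thresholds$hwe_p)
  if (length(drop_h)) {
    removed_snps <- rbind(removed_snps,
                          data.frame(locus_id = G$locus_ids[drop_h],
                                     reason = "hwe",
                                     statistic = hwe_min[drop_h]))
    G <- subset_genotypes(G, loci = setdiff(seq_along(G$locus_ids), drop_h))
  }

  # 4. MAF on the whole retained dataset
  ls <- .locus_summary(G$dosage)
  maf <- pmin(ls$p, 1 - ls$p)
  drop_m <- which(is.na(maf) | maf < thresholds$maf)
  if (length(drop_m)) {
    removed_snps <- rbind(removed_snps,
                          data.frame(locus_id = G$locus_ids[drop_m],
                                     reason = "maf",
                                     statistic = maf[drop_m]))
    G <- subset_genotypes(G, loci = setdiff(seq_along(G$locus_ids), drop_m))
  }
  if (length(G$locus_ids) == 0)
    stop("QC removed every SNP; thresholds too aggressive for this input")
  report <- list(removed_samples = removed_samples,
                 removed_snps = removed_snps,
                 n_samples_before = n0, n_samples_after = length(G$sample_ids),
                 n_snps_before = L0, n_snps_after = length(G$locus_ids))
  list(G = G, report = report)
}

#' Remove near-duplicate samples by IBS distance
#'
#' Builds the graph of sample pairs whose IBS distance falls below the
#' threshold; within each connected component the sample with the highest
#' call rate is kept (ties broken by id order) and the rest removed.
#'
#' @param G a \code{genotype_matrix} with >= 2 samples.
#' @param dup_ibs_distance distance threshold on the 1 - IBS scale.
#' @return list with \code{kept} (ids), \code{removed} (ids) and
#'   \code{pairs} (data.frame of flagged pairs with their distance).
#' @export
remove_duplicates_by_ibs <- function(G, dup_ibs_distance = 0.05) {
  n <- length(G$sample_ids)
  if (n < 2) stop("need at least 2 samples")
  D <- ibs_matrix(G)$values
  hits <- which(upper.tri(D) & D < dup_ibs_distance, arr.ind = TRUE)
  if (nrow(hits) == 0)
    return(list(kept = G$sample_ids, removed = character(),
                pairs = data.frame(id1 = character(), id2 = character(),
                                   distance = numeric())))
  # union-find over flagged pairs
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (k in seq_len(nrow(hits))) {
    a <- find(hits[k, 1]); b <- find(hits[k, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  comp <- vapply(seq_len(n), find, 1L)
  cr <- rowMeans(!is.na(G$dosage))
  removed <- integer()
  for (cc in unique(comp[hits])) {
    members <- which(comp == cc)
    # highest call rate wins; ties go to the earlier id
    keep <- members[order(-cr[members], members)][1]
    removed <- c(removed, setdiff(members, keep))
  }
  list(kept = G$sample_ids[-removed], removed = G$sample_ids[removed],
       pairs = data.frame(id1 = G$sample_ids[hits[, 1]],
                          id2 = G$sample_ids[hits[, 2]],
                          distance = D[hits]))
}

# vectorized 1-df allele-count chi-square between two groups.
# Returns chi2 (0 where monomorphic in both) and the monomorphic flag.
.allele_chisq <- function(dosage, grp) {
  g <- as.integer(factor(grp))
  stopifnot(length(unique(g[!is.na(g)])) == 2)
  d1 <- dosage[g == 1, , drop = FALSE]
  d2 <- dosage[g == 2, , drop = FALSE]
  a1 <- colSums(d1, na.rm = TRUE)                  # A1 copies, group 1
  n1 <- 2 * colSums(!is.na(d1))
  a2 <- colSums(d2, na.rm = TRUE)
  n2 <- 2 * colSums(!is.na(d2))
  b1 <- n1 - a1; b2 <- n2 - a2
  N <- n1 + n2
  rowA <- a1 + a2; rowB <- b1 + b2
  mono <- rowA == 0 | rowB == 0
  degenerate <- n1 == 0 | n2 == 0
  chi2 <- rep(0, length(a1))
  ok <- !mono & !degenerate
  chi2[ok] <- N[ok] * (a1[ok] * b2[ok] - a2[ok] * b1[ok])^2 /
    (rowA[ok] * rowB[ok] * n1[ok] * n2[ok])
  list(chi2 = chi2, monomorphic = mono, degenerate = degenerate)
}

#' Two-group allele-frequency concordance filter
#'
#' Per-SNP 1-df chi-square on the 2x2 allele-count table between two sample
#' groups (e.g. genotyping platforms, or cases vs controls); SNPs with
#' p below the threshold are flagged for removal.  SNPs monomorphic in both
#' groups are never removed.
#'
#' @param G a \code{genotype_matrix}.
#' @param group_labels per-sample labels with exactly two levels.
#' @param p_threshold removal threshold (e.g. 1e-10 for cross-platform
#'   concordance, 0.1 for case/control screening).
#' @return character vector of locus ids to remove.
#' @export
two_group_frequency_filter <- function(G, group_labels, p_threshold) {
  lv <- unique(group_labels)
  if (length(lv) != 2) stop("exactly two groups required")
  if (any(table(group_labels) == 0)) stop("empty group")
  cs <- .allele_chisq(G$dosage, group_labels)
  p <- stats::pchisq(cs$chi2, df = 1, lower.tail = FALSE)
  G$locus_ids[!cs$monomorphic & !cs$degenerate & p < p_threshold]
}

#' Greedy LD pruning on composite-genotype r-squared
#'
#' Slides a window of \code{window_snps} position-sorted SNPs advancing by
#' \code{step_snps}; within each window, while any retained pair has
#' r-squared (squared Pearson correlation of dosages, pairwise-complete)
#' above the threshold, the later-positioned SNP of the first such pair is
#' removed.
#'
#' @param G a \code{genotype_matrix} (SNPs position-sorted per chromosome).
#' @param window_snps window size in SNPs (>= 2).
#' @param step_snps window step in SNPs.
#' @param r2_threshold pruning threshold.
#' @return character vector of retained locus ids.
#' @export
ld_prune <- function(G, window_snps = 50, step_snps = 5, r2_threshold = 0.5) {
  if (window_snps < 2) stop("window_snps must be >= 2")
  keep <- rep(TRUE, length(G$locus_ids))
  for (ch in unique(G$chrom)) {
    idx <- which(G$chrom == ch)
    if (length(idx) < 2) next
    starts <- seq(1L, length(idx), by = step_snps)
    for (s in starts) {
      w <- idx[s:min(s + window_snps - 1L, length(idx))]
      w <- w[keep[w]]
      if (length(w) < 2) next
      repeat {
        cm <- suppressWarnings(
          stats::cor(G$dosage[, w, drop = FALSE],
                     use = "pairwise.complete.obs"))^2
        cm[is.na(cm)] <- 0
        diag(cm) <- 0
        viol <- which(cm > r2_threshold, arr.ind = TRUE)
        viol <- viol[viol[, 1] < viol[, 2], , drop = FALSE]
        if (nrow(viol) == 0) break
        # first violating pair in index order; drop the later-positioned SNP
        v <- viol[order(viol[, 1], viol[, 2]), , drop = FALSE][1, ]
        keep[w[v[2]]] <- FALSE
        w <- w[-v[2]]
        if (length(w) < 2) break
      }
    }
  }
  G$locus_ids[keep]
}
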