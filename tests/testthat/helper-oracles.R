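# Independent oracle implementations used to cross-check the package.
# Each is written from the defining formula by a different route than the
# package code (enumeration, direct scalar evaluation), deliberately slow.

# Exact HWE p by full enumeration of genotype tables with the observed
# allele counts: P(table) proportional to n! / (nAA! nAa! naa!) * 2^nAa.
oracle_hwe <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  tabs <- list()
  for (het in 0:n) {
    hom_A <- (nA - het) / 2
    if (het > nA || hom_A != round(hom_A) || hom_A < 0) next
    hom_a <- n - het - hom_A
    if (hom_a < 0) next
    tabs[[length(tabs) + 1]] <- c(hom_A, het, hom_a)
  }
  w <- vapply(tabs, function(t)
    exp(lfactorial(n) - sum(lfactorial(t)) + t[2] * log(2)), 1)
  w <- w / sum(w)
  obs <- which(vapply(tabs, function(t) t[2] == n_Aa, TRUE))
  sum(w[w <= w[obs] * (1 + 1e-9)])
}

# Mann-Whitney U by direct pair counting
oracle_mwu <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}

# Weir-Cockerham per-locus components evaluated scalar-by-scalar from the
# published diploid formulas (no vectorization shared with the package).
oracle_wc_locus <- function(dosages_by_pop) {
  ni <- vapply(dosages_by_pop, function(d) sum(!is.na(d)), 1)
  pi <- vapply(dosages_by_pop, function(d) mean(d, na.rm = TRUE) / 2, 1)
  hi <- vapply(dosages_by_pop, function(d) mean(d[!is.na(d)] == 1), 1)
  r <- length(ni)
  nbar <- mean(ni)
  nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
  pbar <- sum(ni * pi) / (r * nbar)
  s2 <- sum(ni * (pi - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(ni * hi) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

# Diploid genotypes at two loci from explicit haplotype frequencies
# (gametes drawn independently; phase then discarded).
sim_two_locus_genotypes <- function(n, hap_freqs) {
  haps <- matrix(c(1, 1, 1, 0, 0, 1, 0, 0), 4, 2, byrow = TRUE)
  g1 <- sample.int(4, n, replace = TRUE, prob = hap_freqs)
  g2 <- sample.int(4, n, replace = TRUE, prob = hap_freqs)
  list(a = haps[g1, 1] + haps[g2, 1], b = haps[g1, 2] + haps[g2, 2])
}

# Genotypes with within-individual inbreeding F: with probability F the two
# allele copies are identical by descent (one gamete duplicated).
sim_inbred_dosage <- function(n, L, p, F) {
  ibd <- matrix(stats::runif(n * L) < F, n, L)
  g1 <- matrix(stats::rbinom(n * L, 1, rep(p, each = n)), n, L)
  g2 <- matrix(stats::rbinom(n * L, 1, rep(p, each = n)), n, L)
  g2[ibd] <- g1[ibd]
  g1 + g2
}

# small genotype_matrix from a plain dosage matrix
gm <- function(d, chrom = NULL, pos = NULL) {
  d <- as.matrix(d)
  L <- ncol(d)
  genotype_matrix(d, sprintf("s%03d", seq_len(nrow(d))),
                  sprintf("l%04d", seq_len(L)),
                  if (is.null(chrom)) rep("1", L) else chrom,
                  if (is.null(pos)) seq_len(L) * 1000L else pos,
                  cbind(rep("A", L), rep("B", L)))
}
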