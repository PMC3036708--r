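#' Weir-Cockerham F_ST
#'
#' Multilocus method-of-moments estimator theta for diploids: per locus the
#' variance components a (among populations), b (among individuals within
#' populations) and c (within individuals) are formed from the per-population
#' sample sizes, A1 allele frequencies and observed heterozygote frequencies,
#' and theta is the ratio of sums, sum(a) / sum(a + b + c).  Loci monomorphic
#' across all populations are skipped; negative estimates are reported as-is
#' (no truncation at zero), which keeps the estimator unbiased in the weak
#' differentiation regime.
#'
#' @param G a \code{genotype_matrix}.
#' @param pop_labels per-sample population labels (>= 2 populations, each
#'   with >= 2 samples).
#' @return list with \code{theta}, \code{components} (summed a, b, c) and
#'   \code{n_loci_used}.
#' @export
wc_fst <- function(G, pop_labels) {
  st <- .fst_state(G$dosage, pop_labels)
  res <- .wc_theta(st, seq_len(ncol(st$Z)))
  list(theta = res$theta, components = res$components,
       n_loci_used = res$n_loci_used)
}

# Precompute per-sample matrices shared by observed and permuted estimates.
.fst_state <- function(dosage, pop_labels) {
  f <- factor(pop_labels)
  if (nlevels(f) < 2) stop("need at least 2 populations")
  if (any(table(f) < 2)) stop("every population needs >= 2 samples")
  M <- (!is.na(dosage)) * 1
  Dz <- dosage; Dz[is.na(Dz)] <- 0L
  storage.mode(Dz) <- "double"
  H <- (dosage == 1L & M == 1) * 1
  Z <- t(stats::model.matrix(~ f - 1))  # pops x samples indicator
  list(M = M, Dz = Dz, H = H, Z = Z, X = cbind(M, Dz, H), L = ncol(dosage))
}

# Weir & Cockerham (1984) diploid variance components, vectorized over loci.
# rows: permutation of sample indices applied to the population indicator.
.wc_theta <- function(st, rows, per_locus = FALSE) {
  Z <- st$Z[, rows, drop = FALSE]
  L <- st$L
  agg <- Z %*% st$X                      # pops x 3L
  ncnt <- agg[, seq_len(L), drop = FALSE]            # per-pop non-missing n_i
  sdos <- agg[, L + seq_len(L), drop = FALSE]        # per-pop dosage sums
  shet <- agg[, 2 * L + seq_len(L), drop = FALSE]    # per-pop het counts
  present <- ncnt > 0
  r <- colSums(present)
  nsum <- colSums(ncnt)
  nbar <- nsum / r
  n2sum <- colSums(ncnt^2)
  nc <- (nsum - n2sum / nsum) / (r - 1)
  p_i <- ifelse(present, sdos / (2 * pmax(ncnt, 1)), 0)
  pbar <- colSums(sdos) / (2 * nsum)
  ssq <- colSums(ncnt * (p_i - rep(pbar, each = nrow(ncnt)))^2) /
    ((r - 1) * nbar)
  hbar <- colSums(shet) / nsum
  use <- r >= 2 & pbar > 0 & pbar < 1 & nbar > 1 & nc > 0
  a <- (nbar / nc) * (ssq - (pbar * (1 - pbar) - ((r - 1) / r) * ssq -
                               hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * ssq -
                                ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  a[!use] <- 0; b[!use] <- 0; cc[!use] <- 0
  out <- list(theta = sum(a) / sum(a + b + cc),
              components = c(a = sum(a), b = sum(b), c = sum(cc)),
              n_loci_used = sum(use))
  if (per_locus) out$per_locus <- data.frame(a = a, b = b, c = cc, used = use)
  out
}

#' Weir-Cockerham F_ST with a permutation p-value
#'
#' Permutes the individuals' population labels \code{n_perm} times,
#' recomputes theta for each permutation, and reports the one-sided upper
#' p-value (1 + #\{theta* >= theta\}) / (n_perm + 1).
#'
#' @inheritParams wc_fst
#' @param n_perm number of permutations (>= 1).
#' @param seed RNG seed.
#' @return list with \code{theta}, \code{components}, \code{n_perm},
#'   \code{p_perm}.
#' @export
fst_permutation_p <- function(G, pop_labels, n_perm = 5000, seed = 1) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  st <- .fst_state(G$dosage, pop_labels)
  n <- ncol(st$Z)
  obs <- .wc_theta(st, seq_len(n))
  set.seed(seed)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    th <- .wc_theta(st, sample.int(n))$theta
    if (th >= obs$theta - 1e-15) exceed <- exceed + 1L
  }
  list(theta = obs$theta, components = obs$components,
       n_loci_used = obs$n_loci_used, n_perm = n_perm,
       p_perm = (1 + exceed) / (n_perm + 1))
}

# Nested ANOVA on allele-copy indicators: variance components among regions
# (a), among provinces within regions (b), within provinces (c), summed over
# loci.  rows_prov: province label per sample; prov_region: region of each
# province level.
.hier_components <- function(dosage, prov_f, prov_region) {
  L <- ncol(dosage)
  M <- (!is.na(dosage)) * 1
  Dz <- dosage; Dz[is.na(Dz)] <- 0L
  storage.mode(Dz) <- "double"
  Zp <- t(stats::model.matrix(~ prov_f - 1))        # provinces x samples
  Np <- 2 * (Zp %*% M)                              # allele copies per prov
  Sp <- Zp %*% Dz                                   # A1 copies per prov
  regs <- factor(prov_region)
  Zr <- t(stats::model.matrix(~ regs - 1))          # regions x provinces
  Ng <- Zr %*% Np
  Sg <- Zr %*% Sp
  N <- colSums(Np); S <- colSums(Sp)
  P <- colSums(Np > 0); Gn <- colSums(Ng > 0)
  # sums of squares on 0/1 copies: sum x^2 = sum x
  ratio_p <- ifelse(Np > 0, Sp^2 / pmax(Np, 1), 0)
  ratio_g <- ifelse(Ng > 0, Sg^2 / pmax(Ng, 1), 0)
  ss_c <- S - colSums(ratio_p)
  ss_b <- colSums(ratio_p) - colSums(ratio_g)
  ss_a <- colSums(ratio_g) - S^2 / N
  df_a <- Gn - 1; df_b <- P - Gn; df_c <- N - P
  # unequal-size coefficients of the nested expected mean squares
  sum_np2_over_ng <- colSums(Zr %*% (Np^2) / pmax(Ng, 1))
  n1 <- (N - sum_np2_over_ng) / pmax(df_b, 1)
  n2 <- (sum_np2_over_ng - colSums(Np^2) / N) / pmax(df_a, 1)
  n3 <- (N - colSums(Ng^2) / N) / pmax(df_a, 1)
  use <- df_a >= 1 & df_b >= 1 & df_c >= 1 & S > 0 & S < N
  ms_a <- ss_a / pmax(df_a, 1); ms_b <- ss_b / pmax(df_b, 1)
  ms_c <- ss_c / pmax(df_c, 1)
  sig_c <- ms_c
  sig_b <- (ms_b - sig_c) / n1
  sig_a <- (ms_a - sig_c - n2 * sig_b) / n3
  sig_a[!use] <- 0; sig_b[!use] <- 0; sig_c[!use] <- 0
  c(a = sum(sig_a), b = sum(sig_b), c = sum(sig_c))
}

.hier_f <- function(comp) {
  tot <- sum(comp)
  c(f_ct = comp[["a"]] / tot,
    f_sc = comp[["b"]] / (comp[["b"]] + comp[["c"]]),
    f_st = (comp[["a"]] + comp[["b"]]) / tot)
}

#' Hierarchical F-statistics (region / province / individual)
#'
#' Three-level variance decomposition of allele-copy indicators: among
#' regions (F_CT), among provinces within regions (F_SC), and total
#' (F_ST), satisfying (1 - F_ST) = (1 - F_CT)(1 - F_SC) exactly.
#' Significance by permutation: whole provinces are permuted among regions
#' for F_CT, and individuals among provinces within their region for F_SC
#' (one-sided upper p-values).
#'
#' @param G a \code{genotype_matrix}.
#' @param region_labels,province_labels per-sample labels; each province
#'   must nest inside exactly one region.
#' @param n_perm permutations per test (0 skips the p-values).
#' @param seed RNG seed.
#' @return list with \code{f_ct}, \code{f_sc}, \code{f_st}, \code{p_ct},
#'   \code{p_sc} and the summed \code{components}.
#' @export
hierarchical_fst <- function(G, region_labels, province_labels,
                             n_perm = 5000, seed = 1) {
  prov_f <- factor(province_labels)
  map <- unique(data.frame(p = province_labels, r = region_labels))
  if (anyDuplicated(map$p)) stop("province labels do not nest in regions")
  if (length(unique(map$r)) < 2) stop("need >= 2 regions")
  prov_region <- map$r[match(levels(prov_f), map$p)]
  obs <- .hier_components(G$dosage, prov_f, prov_region)
  fs <- .hier_f(obs)
  p_ct <- p_sc <- NA_real_
  if (n_perm >= 1) {
    set.seed(seed)
    exceed_ct <- 0L
    for (b in seq_len(n_perm)) {
      pr <- sample(prov_region)  # provinces shuffled among regions
      th <- .hier_f(.hier_components(G$dosage, prov_f, pr))[["f_ct"]]
      if (th >= fs[["f_ct"]] - 1e-15) exceed_ct <- exceed_ct + 1L
    }
    p_ct <- (1 + exceed_ct) / (n_perm + 1)
    exceed_sc <- 0L
    reg_of_sample <- prov_region[as.integer(prov_f)]
    for (b in seq_len(n_perm)) {
      newp <- as.integer(prov_f)
      for (rg in unique(reg_of_sample)) {
        idx <- which(reg_of_sample == rg)
        newp[idx] <- sample(newp[idx])  # individuals among provinces, within region
      }
      pf <- factor(levels(prov_f)[newp], levels = levels(prov_f))
      th <- .hier_f(.hier_components(G$dosage, pf, prov_region))[["f_sc"]]
      if (th >= fs[["f_sc"]] - 1e-15) exceed_sc <- exceed_sc + 1L
    }
    p_sc <- (1 + exceed_sc) / (n_perm + 1)
  }
  list(f_ct = fs[["f_ct"]], f_sc = fs[["f_sc"]], f_st = fs[["f_st"]],
       p_ct = p_ct, p_sc = p_sc, components = obs, n_perm = n_perm)
}

#' Downsample populations to equal size
#'
#' Uniform random subset without replacement of \code{n_per_pop} samples
#' from every population; used before allele-frequency and LD comparisons
#' to remove sample-size effects.
#'
#' @param G a \code{genotype_matrix}.
#' @param labels per-sample population labels.
#' @param n_per_pop target size; every population must have at least this
#'   many samples.
#' @param seed RNG seed (same seed, same subset).
#' @return a \code{genotype_matrix} restricted to the selected samples.
#' @export
downsample <- function(G, labels, n_per_pop, seed = 1) {
  tab <- table(labels)
  small <- names(tab)[tab < n_per_pop]
  if (length(small))
    stop("population(s) smaller than n_per_pop: ",
         paste(small, collapse = ", "))
  set.seed(seed)
  keep <- unlist(lapply(split(seq_along(labels), labels), function(idx) {
    if (length(idx) == n_per_pop) idx else sample(idx, n_per_pop)
  }), use.names = FALSE)
  subset_genotypes(G, samples = sort(keep))
}

#' Pairwise F_ST matrix between populations
#'
#' @param G a \code{genotype_matrix}.
#' @param labels per-sample population labels.
#' @return a \code{square_distance_matrix} of kind \code{"fst"} of pairwise
#'   Weir-Cockerham theta values (diagonal 0; negative estimates retained).
#' @export
pairwise_fst_matrix <- function(G, labels) {
  pops <- sort(unique(labels))
  k <- length(pops)
  if (k < 2) stop("need >= 2 populations")
  V <- matrix(0, k, k, dimnames = list(pops, pops))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    sel <- labels %in% c(pops[i], pops[j])
    th <- wc_fst(subset_genotypes(G, samples = which(sel)),
                 labels[sel])$theta
    V[i, j] <- V[j, i] <- th
  }
  square_distance_matrix(V, pops, "fst")
}

#' Write a pairwise F_ST matrix as TSV
#'
#' @param D a \code{square_distance_matrix}.
#' @param path output file.
#' @param times_1e4 if TRUE, values are written multiplied by 10,000 (the
#'   conventional display scale for intra-national F_ST tables).
#' @return invisibly, \code{path}.
#' @export
write_distance_matrix <- function(D, path, times_1e4 = FALSE) {
  V <- D$values
  if (times_1e4) V <- V * 1e4
  utils::write.table(data.frame(id = D$ids, V, check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a square distance matrix written by \code{write_distance_matrix}
#'
#' @param path input TSV (first column \code{id}, then one column per id).
#' @param kind matrix kind.
#' @return a \code{square_distance_matrix}.
#' @export
read_distance_matrix <- function(path, kind = "ibs_distance") {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE)
  ids <- as.character(tab[[1]])
  V <- as.matrix(tab[, -1, drop = FALSE])
  square_distance_matrix(V, ids, kind)
}
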