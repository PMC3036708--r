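#' EM estimation of two-locus haplotype frequencies from unphased diploids
#'
#' Standard two-locus EM: only double heterozygotes are phase-ambiguous;
#' their expected split between the AB/ab and Ab/aB phases is updated from
#' the current haplotype frequencies, starting at linkage equilibrium, until
#' the log-likelihood gain drops below \code{tol}.  The log-likelihood is
#' non-decreasing across iterations.
#'
#' @param dosage_a,dosage_b per-sample A1 dosages at the two loci
#'   (0/1/2/NA); only samples non-missing at both loci are used, and both
#'   loci must be polymorphic in that subset.
#' @param tol convergence tolerance on the log-likelihood.
#' @param max_iter iteration cap.
#' @return list with \code{hap_freqs} = c(p_AB, p_Ab, p_aB, p_ab),
#'   \code{loglik}, \code{converged}, \code{n} (samples used),
#'   \code{n_iter}.
#' @export
em_haplotype_freqs <- function(dosage_a, dosage_b, tol = 1e-8,
                               max_iter = 1000) {
  ok <- !is.na(dosage_a) & !is.na(dosage_b)
  a <- dosage_a[ok]; b <- dosage_b[ok]
  n <- length(a)
  if (n < 2) stop("fewer than 2 samples non-missing at both loci")
  if (length(unique(a)) == 1 || length(unique(b)) == 1)
    stop("monomorphic locus in the pairwise-complete subset; D' undefined")
  # 3x3 genotype table n[i+1, j+1] = #{dosage_a = i, dosage_b = j}
  tab <- matrix(0, 3, 3)
  for (i in 0:2) for (j in 0:2) tab[i + 1, j + 1] <- sum(a == i & b == j)
  # fixed haplotype contributions of unambiguous genotypes (AB, Ab, aB, ab)
  fixed <- c(
    AB = 2 * tab[3, 3] + tab[3, 2] + tab[2, 3],
    Ab = 2 * tab[3, 1] + tab[3, 2] + tab[2, 1],
    aB = 2 * tab[1, 3] + tab[1, 2] + tab[2, 3],
    ab = 2 * tab[1, 1] + tab[1, 2] + tab[2, 1])
  ndh <- tab[2, 2]  # double heterozygotes
  pA <- mean(a) / 2; pB <- mean(b) / 2
  h <- c(pA * pB, pA * (1 - pB), (1 - pA) * pB, (1 - pA) * (1 - pB))
  loglik_fun <- function(h) {
    # P(genotype) products; double het term sums both phases
    probs <- c(h[1]^2, 2 * h[1] * h[2], h[2]^2,
               2 * h[1] * h[3], 2 * (h[1] * h[4] + h[2] * h[3]),
               2 * h[2] * h[4],
               h[3]^2, 2 * h[3] * h[4], h[4]^2)
    cnt <- c(tab[3, 3], tab[3, 2], tab[3, 1],
             tab[2, 3], tab[2, 2], tab[2, 1],
             tab[1, 3], tab[1, 2], tab[1, 1])
    sum(cnt[cnt > 0] * log(probs[cnt > 0]))
  }
  ll <- loglik_fun(h)
  trace <- ll
  converged <- FALSE
  it <- 0
  while (it < max_iter) {
    it <- it + 1
    den <- h[1] * h[4] + h[2] * h[3]
    w <- if (den > 0) h[1] * h[4] / den else 0  # den = 0 only when ndh = 0
    cnt <- fixed + ndh * c(w, 1 - w, 1 - w, w)
    h_new <- cnt / (2 * n)
    ll_new <- loglik_fun(h_new)
    if (ll_new < ll - 1e-9)
      stop("EM log-likelihood decreased; numerical failure")
    h <- h_new
    trace <- c(trace, ll_new)
    if (abs(ll_new - ll) < tol) { ll <- ll_new; converged <- TRUE; break }
    ll <- ll_new
  }
  names(h) <- c("p_AB", "p_Ab", "p_aB", "p_ab")
  list(hap_freqs = h, loglik = ll, converged = converged, n = n,
       n_iter = it, loglik_trace = trace)
}

#' Normalized linkage disequilibrium D'
#'
#' D = p_AB - p_A p_B, scaled by its maximum attainable magnitude given the
#' allele frequencies: D' = D / min(p_A p_b, p_a p_B) for D > 0,
#' D' = D / (-min(p_A p_B, p_a p_b)) for D < 0, and 0 at D = 0; always in
#' [0, 1].
#'
#' @param hap_freqs numeric length-4 vector (p_AB, p_Ab, p_aB, p_ab)
#'   summing to 1.
#' @return D' in [0, 1].
#' @export
dprime <- function(hap_freqs) {
  stopifnot(length(hap_freqs) == 4, all(hap_freqs >= -1e-12),
            abs(sum(hap_freqs) - 1) < 1e-9)
  pA <- hap_freqs[1] + hap_freqs[2]
  pB <- hap_freqs[1] + hap_freqs[3]
  if (pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1)
    stop("marginal allele frequency 0 or 1; D' undefined")
  D <- hap_freqs[1] - pA * pB
  if (D == 0) return(0)
  if (D > 0) unname(D / min(pA * (1 - pB), (1 - pA) * pB))
  else unname(D / (-min(pA * pB, (1 - pA) * (1 - pB))))
}

#' Sample index-SNP LD pairs within a distance cap
#'
#' Draws \code{n_index} loci uniformly without replacement; every other
#' locus on the same chromosome at 0 < distance < \code{max_dist_bp} is
#' paired with it.  Pairs arising twice (two index SNPs that are mutual
#' neighbours) are de-duplicated.
#'
#' @param G a \code{genotype_matrix}.
#' @param n_index number of index SNPs (<= number of loci).
#' @param max_dist_bp distance cap (default 500 kb).
#' @param seed RNG seed.
#' @return data.frame with \code{locus_a}, \code{locus_b}, \code{dist_bp}
#'   (a before b in map order).
#' @export
sample_ld_pairs <- function(G, n_index, max_dist_bp = 500000, seed = 1) {
  L <- length(G$locus_ids)
  if (n_index > L) stop("n_index exceeds number of loci")
  set.seed(seed)
  idx <- sample.int(L, n_index)
  out <- vector("list", n_index)
  for (k in seq_along(idx)) {
    i <- idx[k]
    nb <- which(G$chrom == G$chrom[i] &
                  abs(G$pos_bp - G$pos_bp[i]) > 0 &
                  abs(G$pos_bp - G$pos_bp[i]) < max_dist_bp)
    if (length(nb) == 0) next
    a <- pmin(i, nb); b <- pmax(i, nb)
    out[[k]] <- data.frame(ia = a, ib = b)
  }
  pairs <- do.call(rbind, out)
  if (is.null(pairs))
    return(data.frame(locus_a = character(), locus_b = character(),
                      dist_bp = integer()))
  pairs <- unique(pairs)
  pairs <- pairs[order(pairs$ia, pairs$ib), , drop = FALSE]
  data.frame(locus_a = G$locus_ids[pairs$ia], locus_b = G$locus_ids[pairs$ib],
             dist_bp = abs(G$pos_bp[pairs$ib] - G$pos_bp[pairs$ia]))
}

#' Estimate D' for a list of locus pairs
#'
#' Runs the two-locus EM for each pair; pairs where the EM preconditions
#' fail (monomorphic locus in the pairwise-complete subset) get NA.
#'
#' @param G a \code{genotype_matrix}.
#' @param pairs output of \code{\link{sample_ld_pairs}}.
#' @return \code{pairs} with added columns \code{D}, \code{Dprime},
#'   \code{converged}.
#' @export
ld_pairs_dprime <- function(G, pairs) {
  m <- nrow(pairs)
  D <- Dp <- rep(NA_real_, m)
  conv <- rep(NA, m)
  ia <- match(pairs$locus_a, G$locus_ids)
  ib <- match(pairs$locus_b, G$locus_ids)
  for (k in seq_len(m)) {
    fit <- try(em_haplotype_freqs(G$dosage[, ia[k]], G$dosage[, ib[k]]),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    h <- fit$hap_freqs
    D[k] <- h[1] - (h[1] + h[2]) * (h[1] + h[3])
    Dp[k] <- dprime(h)
    conv[k] <- fit$converged
  }
  cbind(pairs, D = D, Dprime = Dp, converged = conv)
}

#' LD decay profile: median D' in overlapping distance windows
#'
#' Windows are half-open [s, s + window_bp) anchored at multiples of
#' \code{step_bp} starting at 0; a pair contributes to every window
#' containing its distance.  Windows with no pairs are omitted.
#'
#' @param pairs data.frame with \code{dist_bp} and \code{Dprime} (NA
#'   entries dropped).
#' @param window_bp window width (default 40 kb).
#' @param step_bp window step (default 10 kb).
#' @return data.frame with \code{window_start}, \code{window_mid},
#'   \code{n_pairs}, \code{median_dprime}.
#' @export
ld_decay_profile <- function(pairs, window_bp = 40000, step_bp = 10000) {
  pr <- pairs[!is.na(pairs$Dprime), , drop = FALSE]
  if (nrow(pr) == 0)
    return(data.frame(window_start = integer(), window_mid = numeric(),
                      n_pairs = integer(), median_dprime = numeric()))
  starts <- seq(0, max(pr$dist_bp), by = step_bp)
  rows <- lapply(starts, function(s) {
    sel <- pr$dist_bp >= s & pr$dist_bp < s + window_bp
    if (!any(sel)) return(NULL)
    data.frame(window_start = s, window_mid = s + window_bp / 2,
               n_pairs = sum(sel), median_dprime = stats::median(pr$Dprime[sel]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Paired comparison of D' between two populations
#'
#' Wilcoxon signed-rank test on the same pair list evaluated in two
#' populations.  Zero differences are dropped (standard convention); the
#' exact null distribution is used when at most 25 non-zero untied
#' differences remain, otherwise the normal approximation with tie
#' correction.
#'
#' @param dprimes_popA,dprimes_popB aligned D' vectors (NA pairs in either
#'   population dropped).
#' @return list with \code{W}, \code{p}, \code{n_nonzero}, \code{method}.
#' @export
compare_ld_paired <- function(dprimes_popA, dprimes_popB) {
  ok <- !is.na(dprimes_popA) & !is.na(dprimes_popB)
  d <- dprimes_popA[ok] - dprimes_popB[ok]
  nz <- d[d != 0]
  if (length(nz) == 0) {
    warning("all paired differences are zero")
    return(list(W = 0, p = 1, n_nonzero = 0L, method = "degenerate"))
  }
  ties <- anyDuplicated(abs(nz)) > 0
  use_exact <- length(nz) <= 25 && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(dprimes_popA[ok], dprimes_popB[ok], paired = TRUE,
                       exact = use_exact, correct = FALSE))
  list(W = unname(wt$statistic), p = wt$p.value, n_nonzero = length(nz),
       method = if (use_exact) "exact" else "normal approximation")
}
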