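#' Maximum-likelihood admixture decomposition by EM
#'
#' Binomial admixture model: each of a sample's two allele copies at locus
#' l originates from cluster k with probability q_ik and is the A1 allele
#' with probability f_kl, so the dosage is Binomial(2, sum_k q_ik f_kl).
#' Q and F are estimated by block EM (missing genotypes are skipped in the
#' likelihood); the log-likelihood is non-decreasing across iterations.
#' The likelihood is multimodal for K >= 2, so several random restarts are
#' run and the best kept.  Cluster labels are identifiable only up to
#' permutation.
#'
#' @param G a \code{genotype_matrix}.
#' @param K number of clusters (1 <= K <= samples).
#' @param seed RNG seed (restart r uses seed + r - 1).
#' @param tol convergence tolerance on the log-likelihood gain.
#' @param max_iter iteration cap per restart.
#' @param n_restarts random restarts (best final log-likelihood wins).
#' @return list with \code{Q} (samples x K, rows sum to 1), \code{F}
#'   (K x loci cluster allele frequencies), \code{loglik},
#'   \code{loglik_trace}, \code{K}, \code{seed}, \code{converged}.
#' @export
admixture_em <- function(G, K, seed = 1, tol = 1e-6, max_iter = 2000,
                         n_restarts = 3) {
  d <- G$dosage
  n <- nrow(d); L <- ncol(d)
  if (K < 1) stop("K must be >= 1")
  if (K > n) stop("K exceeds the number of samples")
  M <- (!is.na(d)) * 1
  Dz <- d; Dz[is.na(Dz)] <- 0L
  storage.mode(Dz) <- "double"
  Dc <- (2 - Dz) * M  # copies of the A2 allele, missing zeroed
  Da <- Dz * M
  lchoose_term <- sum(lchoose(2, Dz)[M == 1])
  if (K == 1) {
    p <- colSums(Da) / (2 * colSums(M))
    p <- pmin(pmax(p, 1e-6), 1 - 1e-6)
    ll <- sum(Da %*% log(p)) + sum(Dc %*% log(1 - p)) + lchoose_term
    Q <- matrix(1, n, 1, dimnames = list(G$sample_ids, NULL))
    return(list(Q = Q, F = matrix(p, 1, L, dimnames = list(NULL, G$locus_ids)),
                loglik = ll, loglik_trace = ll, K = 1L, seed = seed,
                converged = TRUE))
  }
  nm_i <- rowSums(M)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    set.seed(seed + r - 1L)
    Q <- matrix(stats::rgamma(n * K, 1), n, K)
    Q <- Q / rowSums(Q)
    base_p <- colSums(Da) / (2 * pmax(colSums(M), 1))
    Fm <- matrix(rep(base_p, each = K), K, L) +
      matrix(stats::rnorm(K * L, 0, 0.05), K, L)
    Fm <- pmin(pmax(Fm, 1e-6), 1 - 1e-6)
    ll_old <- -Inf
    trace <- numeric(0)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      P1 <- Q %*% Fm            # prob a copy is A1
      P0 <- Q %*% (1 - Fm)
      # E-step responsibilities, M-step in one pass per cluster
      sumA <- Da / P1           # n x L
      sumB <- Dc / P0
      Qnew <- matrix(0, n, K)
      Fnum <- matrix(0, K, L)
      Fden <- matrix(0, K, L)
      for (k in seq_len(K)) {
        ak <- (Q[, k] %o% Fm[k, ]) * sumA       # expected A1 copies from k
        bk <- (Q[, k] %o% (1 - Fm[k, ])) * sumB
        Qnew[, k] <- rowSums(ak + bk)
        Fnum[k, ] <- colSums(ak)
        Fden[k, ] <- colSums(ak + bk)
      }
      Q <- Qnew / (2 * nm_i)
      Q <- Q / rowSums(Q)       # guard against float drift
      Fm <- pmin(pmax(Fnum / Fden, 1e-6), 1 - 1e-6)
      P1 <- Q %*% Fm; P0 <- Q %*% (1 - Fm)
      ll <- sum(Da * log(P1)) + sum(Dc * log(P0)) + lchoose_term
      if (ll < ll_old - 1e-6)
        stop("EM log-likelihood decreased; numerical failure")
      trace <- c(trace, ll)
      if (is.finite(ll_old) && ll - ll_old < tol) { converged <- TRUE; break }
      ll_old <- ll
    }
    if (is.null(best) || ll > best$loglik)
      best <- list(Q = Q, F = Fm, loglik = ll, loglik_trace = trace,
                   K = as.integer(K), seed = seed, converged = converged)
  }
  dimnames(best$Q) <- list(G$sample_ids, NULL)
  colnames(best$F) <- G$locus_ids
  best
}

#' Align cluster labels of an estimated Q to a reference Q
#'
#' Ancestry matrices are identifiable only up to column permutation; this
#' picks the permutation minimizing mean absolute error.
#'
#' @param Q estimated samples x K matrix.
#' @param Q_ref reference samples x K matrix.
#' @return \code{Q} with columns permuted to best match \code{Q_ref}.
#' @export
align_q <- function(Q, Q_ref) {
  K <- ncol(Q)
  perms <- .all_permutations(K)
  errs <- apply(perms, 1, function(p) mean(abs(Q[, p] - Q_ref)))
  Q[, perms[which.min(errs), ], drop = FALSE]
}

#' Evanno delta-K statistic over replicate clustering runs
#'
#' From replicate log-likelihoods L(K) at consecutive K values:
#' L'(K) = mean L(K) - mean L(K-1), |L''(K)| = |L'(K+1) - L'(K)|, and
#' delta K = |L''(K)| / sd(L(K)), defined for interior K only.  The K
#' maximizing delta K is the supported number of clusters.
#'
#' @param logliks named list: element "2" holds the replicate log-likelihood
#'   vector for K = 2, etc.; >= 3 consecutive K values, >= 2 replicates
#'   each.
#' @return data.frame with \code{K}, \code{mean_loglik}, \code{sd_loglik},
#'   \code{delta_k} (NA at the boundary K values).
#' @export
evanno_delta_k <- function(logliks) {
  Ks <- sort(as.integer(names(logliks)))
  if (length(Ks) < 3) stop("need >= 3 consecutive K values")
  if (any(diff(Ks) != 1)) stop("K values must be consecutive")
  mu <- vapply(as.character(Ks), function(k) mean(logliks[[k]]), 1)
  sdv <- vapply(as.character(Ks), function(k) stats::sd(logliks[[k]]), 1)
  if (any(vapply(logliks, length, 1L) < 2))
    stop("need >= 2 replicates per K")
  delta <- rep(NA_real_, length(Ks))
  for (i in seq(2, length(Ks) - 1)) {
    if (sdv[i] == 0) stop("sd of log-likelihoods is 0 at K = ", Ks[i],
                          "; delta K undefined")
    lpp <- (mu[i + 1] - mu[i]) - (mu[i] - mu[i - 1])
    delta[i] <- abs(lpp) / sdv[i]
  }
  data.frame(K = Ks, mean_loglik = unname(mu), sd_loglik = unname(sdv),
             delta_k = delta)
}

#' Write a Q matrix in the conventional whitespace-delimited layout
#'
#' @param Q samples x K matrix with sample ids as row names.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
write_q_matrix <- function(Q, path) {
  utils::write.table(data.frame(sample_id = rownames(Q), Q),
                     path, quote = FALSE, row.names = FALSE, sep = " ")
  invisible(path)
}
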