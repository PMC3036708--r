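#' Construct a square distance matrix object
#'
#' @param values symmetric non-negative numeric matrix with zero diagonal.
#' @param ids identifiers for rows/columns.
#' @param kind one of \code{"ibs_distance"}, \code{"km"}, \code{"fst"}.
#' @return a \code{square_distance_matrix}.
#' @export
square_distance_matrix <- function(values, ids, kind) {
  kind <- match.arg(kind, c("ibs_distance", "km", "fst"))
  values <- as.matrix(values)
  stopifnot(nrow(values) == ncol(values), nrow(values) == length(ids))
  if (max(abs(values - t(values))) > 1e-12) stop("matrix not symmetric")
  if (kind != "fst" && any(abs(diag(values)) > 0))
    stop("diagonal must be exactly 0")
  if (kind == "ibs_distance" && (min(values) < 0 || max(values) > 1))
    stop("IBS distances must lie in [0, 1]")
  dimnames(values) <- list(ids, ids)
  structure(list(ids = as.character(ids), values = values, kind = kind),
            class = "square_distance_matrix")
}

#' @export
print.square_distance_matrix <- function(x, ...) {
  cat("square_distance_matrix (", x$kind, "): ", length(x$ids), " x ",
      length(x$ids), "\n", sep = "")
  invisible(x)
}

#' Pairwise identity-by-state distance matrix
#'
#' For each sample pair, over the loci non-missing in both, the per-locus
#' shared-allele fraction is 1 - |d_i - d_j| / 2 and the IBS distance is one
#' minus its mean: the proportion of allele comparisons not identical by
#' state.  Missing entries are handled pairwise-complete.
#'
#' @param G a \code{genotype_matrix} with >= 2 samples.
#' @return a \code{square_distance_matrix} of kind \code{"ibs_distance"}.
#' @export
ibs_matrix <- function(G) {
  d <- G$dosage
  n <- nrow(d)
  if (n < 2) stop("need at least 2 samples")
  M <- (!is.na(d)) * 1
  Dz <- d; Dz[is.na(Dz)] <- 0L
  storage.mode(Dz) <- "double"
  A0 <- (Dz == 0L & M == 1) * 1
  A2 <- (Dz == 2L) * 1
  N <- tcrossprod(M)                       # shared non-missing loci
  Q <- Dz^2
  S2 <- tcrossprod(Q, M) + tcrossprod(M, Q) - 2 * tcrossprod(Dz)
  cross02 <- tcrossprod(A0, A2) + tcrossprod(A2, A0)
  sum_abs <- S2 - 2 * cross02              # sum over loci of |d_i - d_j|
  if (any(N[upper.tri(N)] == 0)) {
    bad <- which(upper.tri(N) & N == 0, arr.ind = TRUE)[1, ]
    stop("no overlapping loci for pair ", G$sample_ids[bad[1]], " / ",
         G$sample_ids[bad[2]])
  }
  D <- sum_abs / (2 * N)
  D[N == 0] <- 0
  D <- pmin(pmax(D, 0), 1)  # clamp float noise
  diag(D) <- 0
  D <- (D + t(D)) / 2  # exact symmetry against float noise
  square_distance_matrix(D, G$sample_ids, "ibs_distance")
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centers the squared distances and eigendecomposes (via
#' \code{stats::cmdscale}); coordinates are eigenvectors scaled by the
#' square roots of the positive eigenvalues.  The variance explained by
#' axis k is its eigenvalue divided by the sum of the positive eigenvalues
#' (negative eigenvalues, which arise for non-Euclidean inputs such as IBS
#' distances, are excluded from both coordinates and the denominator).
#'
#' @param D a \code{square_distance_matrix} (or plain symmetric matrix).
#' @param dims number of axes requested (>= 1); silently truncated with a
#'   warning if it exceeds the number of positive eigenvalues.
#' @return list with \code{coordinates} (samples x dims, rownames = ids),
#'   \code{eigenvalues} (all, descending) and \code{variance_explained}.
#' @export
classical_mds <- function(D, dims = 2) {
  stopifnot(dims >= 1)
  V <- if (inherits(D, "square_distance_matrix")) D$values else as.matrix(D)
  n <- nrow(V)
  # cmdscale warns when fewer than k eigenvalues are positive; truncation
  # is handled (with our own warning) below
  fit <- suppressWarnings(stats::cmdscale(V, k = n - 1, eig = TRUE))
  eig <- fit$eig
  npos <- sum(eig > max(eig) * 1e-12)
  if (dims > npos) {
    warning("only ", npos, " positive eigenvalues; truncating dims from ",
            dims, " to ", npos)
    dims <- npos
  }
  coords <- fit$points[, seq_len(dims), drop = FALSE]
  rownames(coords) <- rownames(V)
  colnames(coords) <- paste0("dim", seq_len(dims))
  list(coordinates = coords,
       eigenvalues = sort(eig, decreasing = TRUE),
       variance_explained = eig[seq_len(dims)] / sum(eig[eig > 0]))
}

# Mann-Whitney U of x vs y (number of (x, y) pairs with x > y, + ties/2)
.mwu <- function(x, y) {
  r <- rank(c(x, y))
  sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}

# within-group pairwise values for a set of individual indices
.within_values <- function(V, idx) {
  if (length(idx) < 2) stop("group with fewer than 2 individuals")
  sub <- V[idx, idx, drop = FALSE]
  sub[upper.tri(sub)]
}

#' Permutation Mann-Whitney test on within-group IBS distributions
#'
#' Compares the distribution of within-group pairwise values (e.g. IBS
#' distances) between two groups of individuals.  Because pairwise values
#' sharing an individual are dependent, the null distribution is built by
#' permuting the individuals' group labels and rebuilding both sets, not by
#' permuting pooled pair values.  The empirical two-sided p doubles the
#' smaller tail, counting the observed statistic once:
#' p = min(1, 2 min((1 + #\{U* >= U\}), (1 + #\{U* <= U\})) / (n_perm + 1)).
#'
#' @param D a \code{square_distance_matrix} (or plain symmetric matrix with
#'   dimnames) of pairwise values.
#' @param labels per-individual group labels aligned with \code{D}'s ids.
#' @param groupA,groupB the two label values to compare.
#' @param n_perm number of label permutations (>= 1).
#' @param seed RNG seed.
#' @param exact if TRUE, enumerate every assignment of the pooled
#'   individuals into the two group sizes instead of sampling; p is then the
#'   exact proportion of assignments at least as extreme (two-sided).
#' @return list with \code{U}, \code{p}, \code{n_perm}.
#' @export
permutation_mannwhitney <- function(D, labels, groupA, groupB,
                                    n_perm = 10000, seed = 1, exact = FALSE) {
  V <- if (inherits(D, "square_distance_matrix")) D$values else as.matrix(D)
  ia <- which(labels == groupA); ib <- which(labels == groupB)
  if (length(ia) < 2 || length(ib) < 2)
    stop("each group needs >= 2 individuals for within-group pairs")
  obsU <- .mwu(.within_values(V, ia), .within_values(V, ib))
  pool <- c(ia, ib); na <- length(ia)
  if (exact) {
    combs <- utils::combn(length(pool), na)
    Us <- apply(combs, 2, function(sel) {
      .mwu(.within_values(V, pool[sel]), .within_values(V, pool[-sel]))
    })
    p_up <- mean(Us >= obsU - 1e-12)
    p_lo <- mean(Us <= obsU + 1e-12)
    return(list(U = obsU, p = min(1, 2 * min(p_up, p_lo)),
                n_perm = length(Us)))
  }
  if (n_perm < 1) stop("n_perm must be >= 1")
  set.seed(seed)
  Us <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    perm <- sample(pool)
    Us[b] <- .mwu(.within_values(V, perm[seq_len(na)]),
                  .within_values(V, perm[-seq_len(na)]))
  }
  p_up <- (1 + sum(Us >= obsU - 1e-12)) / (n_perm + 1)
  p_lo <- (1 + sum(Us <= obsU + 1e-12)) / (n_perm + 1)
  list(U = obsU, p = min(1, 2 * min(p_up, p_lo)), n_perm = n_perm)
}

#' Bonferroni correction
#'
#' @param p_values numeric vector of p-values.
#' @param m number of tests (defaults to \code{length(p_values)}; must be at
#'   least that).
#' @return adjusted p-values, \code{pmin(1, p * m)}.
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  if (m < length(p_values)) stop("m must be >= number of p-values")
  pmin(1, p_values * m)
}
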