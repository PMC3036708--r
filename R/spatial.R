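# IUGG mean Earth radius, km
.EARTH_RADIUS_KM <- 6371.0088

# haversine distance in km between two coordinate matrices (lon, lat degrees)
.gc_km <- function(p1, p2) {
  geosphere::distHaversine(p1, p2, r = .EARTH_RADIUS_KM)
}

#' Great-circle distance matrix between samples
#'
#' Haversine distances (Earth radius 6371.0088 km, the IUGG mean) between
#' all sample coordinates.
#'
#' @param S a sample table with \code{sample_id}, \code{lat}, \code{lon}.
#' @return a \code{square_distance_matrix} of kind \code{"km"}.
#' @export
great_circle_matrix <- function(S) {
  bad <- which(is.na(S$lat) | is.na(S$lon))
  if (length(bad))
    stop("missing coordinates for sample(s): ",
         paste(S$sample_id[bad], collapse = ", "))
  xy <- cbind(S$lon, S$lat)
  V <- geosphere::distm(xy, fun = function(a, b)
    geosphere::distHaversine(a, b, r = .EARTH_RADIUS_KM))
  V <- (V + t(V)) / 2
  diag(V) <- 0
  square_distance_matrix(V, S$sample_id, "km")
}

# upper-triangle vector of a square matrix
.ut <- function(V) V[upper.tri(V)]

#' Mantel test of two distance matrices
#'
#' Pearson correlation over the off-diagonal upper triangles; the null
#' distribution permutes one matrix's row/column order jointly (object
#' labels), and the one-sided upper p is (1 + #\{r* >= r\}) / (n_perm + 1).
#'
#' @param D_gen,D_geo \code{square_distance_matrix} objects (or plain
#'   matrices) over the same ids; \code{D_geo} is reordered to match.
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @param exact if TRUE, enumerate all n! permutations (small n only).
#' @return list with \code{r}, \code{p}, \code{n_perm}.
#' @export
mantel_test <- function(D_gen, D_geo, n_perm = 9999, seed = 1,
                        exact = FALSE) {
  A <- if (inherits(D_gen, "square_distance_matrix")) D_gen$values else as.matrix(D_gen)
  B <- if (inherits(D_geo, "square_distance_matrix")) D_geo$values else as.matrix(D_geo)
  if (inherits(D_gen, "square_distance_matrix") &&
      inherits(D_geo, "square_distance_matrix")) {
    if (!setequal(D_gen$ids, D_geo$ids)) stop("matrix ids do not match")
    B <- B[match(D_gen$ids, D_geo$ids), match(D_gen$ids, D_geo$ids)]
  }
  n <- nrow(A)
  if (n < 3) stop("need at least 3 objects")
  if (stats::sd(.ut(A)) == 0 || stats::sd(.ut(B)) == 0)
    stop("constant distance matrix; correlation undefined")
  r_obs <- stats::cor(.ut(A), .ut(B))
  if (exact) {
    perms <- .all_permutations(n)
    rs <- apply(perms, 1, function(p) stats::cor(.ut(A), .ut(B[p, p])))
    return(list(r = r_obs, p = mean(rs >= r_obs - 1e-12),
                n_perm = nrow(perms)))
  }
  set.seed(seed)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    p <- sample.int(n)
    if (stats::cor(.ut(A), .ut(B[p, p])) >= r_obs - 1e-12)
      exceed <- exceed + 1L
  }
  list(r = r_obs, p = (1 + exceed) / (n_perm + 1), n_perm = n_perm)
}

.all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .all_permutations(n - 1)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

#' Per-sample inbreeding coefficients (observed vs expected homozygotes)
#'
#' For each locus, the expected homozygosity under Hardy-Weinberg with the
#' small-sample correction is 1 - 2 p (1 - p) (2n / (2n - 1)), with p the
#' total-sample A1 frequency and 2n the total allele count at the locus.
#' Per sample, F = (O_hom - E_hom) / (L - E_hom) over its non-missing loci;
#' F = 1 for a fully homozygous sample.
#'
#' @param G a \code{genotype_matrix} (>= 2 samples, polymorphic loci).
#' @return data.frame with \code{sample_id}, \code{F}, \code{O_hom},
#'   \code{E_hom}, \code{L}.
#' @export
inbreeding_coefficients <- function(G) {
  d <- G$dosage
  if (nrow(d) < 2) stop("need at least 2 samples")
  nm <- colSums(!is.na(d))
  if (any(rowSums(!is.na(d)) == 0))
    stop("sample with all loci missing: ",
         G$sample_ids[which(rowSums(!is.na(d)) == 0)[1]])
  p <- colSums(d, na.rm = TRUE) / (2 * nm)
  e_hom_l <- 1 - 2 * p * (1 - p) * (2 * nm) / (2 * nm - 1)
  obs_hom <- (d == 0L | d == 2L) * 1
  M <- (!is.na(d)) * 1
  O <- rowSums(obs_hom, na.rm = TRUE)
  E <- as.vector(M %*% e_hom_l)
  L <- rowSums(M)
  data.frame(sample_id = G$sample_ids, F = (O - E) / (L - E),
             O_hom = O, E_hom = E, L = L)
}

#' Kruskal-Wallis rank-sum test of values across regions
#'
#' Thin wrapper over \code{stats::kruskal.test} (tie-corrected H,
#' chi-square approximation with k - 1 df).
#'
#' @param values numeric vector (e.g. per-sample inbreeding coefficients).
#' @param region_labels per-value group labels (>= 2 groups).
#' @return list with \code{H}, \code{df}, \code{p}.
#' @export
kruskal_wallis_by_region <- function(values, region_labels) {
  if (length(unique(region_labels)) < 2) stop("need >= 2 groups")
  kt <- stats::kruskal.test(values, factor(region_labels))
  list(H = unname(kt$statistic), df = unname(kt$parameter), p = kt$p.value)
}

#' Grid-circle local statistics on a map
#'
#' Lays a regular latitude/longitude grid (approximately
#' \code{grid_spacing_km} apart) over the samples' bounding box; at each
#' grid point the members are the samples within \code{radius_km}
#' great-circle distance.  For kinds \code{median_inbreeding} /
#' \code{median_ancestry} the cell value is the median of the members'
#' \code{values} (cells with fewer than \code{min_n} members omitted;
#' default 20).  For kind \code{local_correlation} the value is the plain
#' Pearson correlation between the genetic and geographic distances over
#' all member pairs, emitted only for cells with at least \code{min_n}
#' members (default 40 for this kind).
#'
#' @param S a sample table.
#' @param values per-sample values (median kinds).
#' @param D_gen,D_geo \code{square_distance_matrix} objects over the sample
#'   ids (correlation kind).
#' @param kind one of \code{"median_inbreeding"}, \code{"median_ancestry"},
#'   \code{"local_correlation"}.
#' @param radius_km circle radius (default 150).
#' @param min_n minimum members per emitted cell (default 20; 40 for
#'   \code{local_correlation}).
#' @param grid_spacing_km grid resolution (default 25).
#' @return data.frame with \code{lat}, \code{lon}, \code{n}, \code{kind},
#'   \code{value}.
#' @export
grid_local_statistic <- function(S, values = NULL, D_gen = NULL,
                                 D_geo = NULL,
                                 kind = c("median_inbreeding",
                                          "median_ancestry",
                                          "local_correlation"),
                                 radius_km = 150, min_n = NULL,
                                 grid_spacing_km = 25) {
  kind <- match.arg(kind)
  if (is.null(min_n)) min_n <- if (kind == "local_correlation") 40 else 20
  if (min_n < 2) stop("min_n must be >= 2")
  if (kind == "local_correlation") {
    stopifnot(!is.null(D_gen), !is.null(D_geo))
    Vg <- D_gen$values[match(S$sample_id, D_gen$ids),
                       match(S$sample_id, D_gen$ids)]
    Vd <- D_geo$values[match(S$sample_id, D_geo$ids),
                       match(S$sample_id, D_geo$ids)]
  } else {
    stopifnot(!is.null(values), length(values) == nrow(S))
  }
  lat_step <- grid_spacing_km / 111.195
  lat_seq <- seq(min(S$lat), max(S$lat) + lat_step / 2, by = lat_step)
  mid_lat <- mean(range(S$lat))
  lon_step <- grid_spacing_km / (111.195 * cos(mid_lat * pi / 180))
  lon_seq <- seq(min(S$lon), max(S$lon) + lon_step / 2, by = lon_step)
  if (length(lat_seq) == 0 || length(lon_seq) == 0) stop("empty grid")
  xy <- cbind(S$lon, S$lat)
  rows <- list()
  for (la in lat_seq) for (lo in lon_seq) {
    dkm <- .gc_km(cbind(lo, la), xy)
    members <- which(dkm <= radius_km)
    if (length(members) < min_n) next
    val <- if (kind == "local_correlation") {
      g <- .ut(Vg[members, members]); d <- .ut(Vd[members, members])
      if (stats::sd(g) == 0 || stats::sd(d) == 0) next
      stats::cor(g, d)
    } else stats::median(values[members])
    rows[[length(rows) + 1]] <-
      data.frame(lat = la, lon = lo, n = length(members), kind = kind,
                 value = val)
  }
  if (length(rows) == 0)
    return(data.frame(lat = numeric(), lon = numeric(), n = integer(),
                      kind = character(), value = numeric()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
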