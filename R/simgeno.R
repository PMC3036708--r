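#' Simulation configuration for synthetic genotype panels
#'
#' Describes a panel with hierarchical (region > province) Balding-Nichols
#' differentiation, an optional latitudinal cline, map coordinates, and the
#' artifacts of multi-platform genotyping (missingness, batch SNPs,
#' near-duplicate individuals, null case/control labels).
#'
#' @param n_snps number of SNPs.
#' @param provinces data.frame with columns \code{name}, \code{region},
#'   \code{lat}, \code{lon} (centroid degrees) and \code{n} (samples).
#' @param maf_range ancestral allele-frequency range, within (0, 0.5];
#'   frequencies are drawn uniformly on it (MAF-ascertained panel).
#' @param f_region,f_province Balding-Nichols drift parameters (>= 0); each
#'   equals the expected F_ST of its level.
#' @param clinal_weight in [0,1]: weight of the two-gradient latitudinal
#'   cline relative to hierarchical drift in each sample's SNP frequencies.
#' @param jitter_km isotropic Gaussian scatter (sd, km) of sample
#'   coordinates around the province centroid.
#' @param missing_rate_by_platform named numeric vector, platform -> missing
#'   rate in [0, 1); samples are assigned platforms uniformly at random.
#' @param n_duplicate_pairs number of near-duplicate sample pairs to append.
#' @param n_batch_snps number of SNPs given a platform-restricted frequency
#'   shift (a batch artifact).
#' @param freq_shift frequency shift, in (0,1), applied to batch SNPs on the
#'   first platform (clipped to [0.01, 0.99]).
#' @param case_fraction in [0,1]: fraction labelled "case" (labels are null,
#'   i.e. independent of genotype); 0 leaves all statuses "unknown".
#' @param seed integer RNG seed; all outputs are deterministic given it.
#' @return A \code{sim_config} list.
#' @export
sim_config <- function(n_snps = 5000,
                       provinces = default_provinces(),
                       maf_range = c(0.05, 0.5),
                       f_region = 4e-4,
                       f_province = 3e-4,
                       clinal_weight = 0,
                       jitter_km = 30,
                       missing_rate_by_platform = c(illumina = 0.002),
                       n_duplicate_pairs = 0,
                       n_batch_snps = 0,
                       freq_shift = 0.2,
                       case_fraction = 0,
                       seed = 1L) {
  stopifnot(n_snps >= 1, is.data.frame(provinces),
            all(c("name", "region", "lat", "lon", "n") %in% names(provinces)))
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2])
    stop("maf_range must lie within (0, 0.5]")
  if (f_region < 0 || f_province < 0) stop("f parameters must be >= 0")
  if (clinal_weight < 0 || clinal_weight > 1)
    stop("clinal_weight must be in [0,1]")
  if (clinal_weight > 0 && f_region == 0)
    stop("clinal mode needs f_region > 0 to separate the two gradients")
  if ((f_region > 0 || f_province > 0) && nrow(provinces) < 2)
    stop("differentiation > 0 needs at least 2 provinces")
  if (any(missing_rate_by_platform < 0 | missing_rate_by_platform >= 1))
    stop("missing rates must be in [0, 1)")
  if (freq_shift <= 0 || freq_shift >= 1) stop("freq_shift must be in (0,1)")
  if (case_fraction < 0 || case_fraction > 1)
    stop("case_fraction must be in [0,1]")
  structure(list(n_snps = as.integer(n_snps), provinces = provinces,
                 maf_range = maf_range, f_region = f_region,
                 f_province = f_province, clinal_weight = clinal_weight,
                 jitter_km = jitter_km,
                 missing_rate_by_platform = missing_rate_by_platform,
                 n_duplicate_pairs = as.integer(n_duplicate_pairs),
                 n_batch_snps = as.integer(n_batch_snps),
                 freq_shift = freq_shift, case_fraction = case_fraction,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Default province layout: three latitudinal regions of two provinces each
#'
#' A stylized south-to-north map (about 55-67 degrees N) with larger samples
#' in the south, echoing the uneven provincial sampling of national cohorts.
#'
#' @param n_per_province optional single sample size overriding the defaults.
#' @return data.frame of provinces.
#' @export
default_provinces <- function(n_per_province = NULL) {
  d <- data.frame(
    name = c("P_S1", "P_S2", "P_M1", "P_M2", "P_N1", "P_N2"),
    region = c("South", "South", "Middle", "Middle", "North", "North"),
    lat = c(56.0, 57.5, 59.5, 61.0, 64.0, 66.5),
    lon = c(14.0, 12.5, 17.0, 15.0, 19.5, 21.0),
    n = c(120, 100, 80, 60, 50, 40),
    stringsAsFactors = FALSE)
  if (!is.null(n_per_province)) d$n <- n_per_province
  d
}

# Balding-Nichols draw: Beta(p(1-f)/f, (1-p)(1-f)/f) around ancestral p.
# f = 0 degenerates to p itself.
.bn_draw <- function(p, f) {
  if (f == 0) return(p)
  q <- stats::rbeta(length(p), p * (1 - f) / f, (1 - p) * (1 - f) / f)
  pmin(pmax(q, 1e-9), 1 - 1e-9)
}

#' Simulate a synthetic genotype panel with ground truth
#'
#' Ancestral frequencies are uniform on \code{maf_range}; region frequencies
#' are Balding-Nichols draws around them with \code{f_region}, province
#' frequencies Balding-Nichols draws around their region with
#' \code{f_province}.  In clinal mode each sample's expected frequency mixes
#' its province frequency with a two-endpoint latitudinal gradient weighted
#' by the sample's true ancestry proportions (which are a linear function of
#' latitude).  Genotypes are Binomial(2, freq); coordinates are the province
#' centroid plus isotropic jitter.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with \code{G} (\code{genotype_matrix}), \code{S} (sample
#'   table) and \code{truth} (list: \code{ancestral_freq},
#'   \code{group_freq} provinces x loci, \code{true_Q} samples x 2 or NULL,
#'   \code{true_f}).
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  L <- config$n_snps
  prov <- config$provinces
  n_tot <- sum(prov$n)
  p_anc <- stats::runif(L, config$maf_range[1], config$maf_range[2])

  regions <- unique(prov$region)
  reg_freq <- matrix(NA_real_, length(regions), L,
                     dimnames = list(regions, NULL))
  for (r in regions) reg_freq[r, ] <- .bn_draw(p_anc, config$f_region)
  grp_freq <- matrix(NA_real_, nrow(prov), L, dimnames = list(prov$name, NULL))
  for (i in seq_len(nrow(prov)))
    grp_freq[i, ] <- .bn_draw(reg_freq[prov$region[i], ], config$f_province)

  province <- rep(prov$name, prov$n)
  region <- rep(prov$region, prov$n)
  cen_lat <- rep(prov$lat, prov$n)
  cen_lon <- rep(prov$lon, prov$n)
  sd_deg <- config$jitter_km / 111.195
  lat <- cen_lat + stats::rnorm(n_tot, 0, sd_deg)
  lon <- cen_lon + stats::rnorm(n_tot, 0, sd_deg / cos(cen_lat * pi / 180))

  true_Q <- NULL
  freq_s <- grp_freq[province, , drop = FALSE]  # samples x loci expectation
  if (config$clinal_weight > 0) {
    g1 <- .bn_draw(p_anc, config$f_region)  # northern gradient endpoint
    g2 <- .bn_draw(p_anc, config$f_region)  # southern gradient endpoint
    w <- (lat - min(lat)) / (max(lat) - min(lat))
    true_Q <- cbind(q_north = w, q_south = 1 - w)
    clin <- true_Q %*% rbind(g1, g2)
    cw <- config$clinal_weight
    freq_s <- (1 - cw) * freq_s + cw * clin
  }
  dosage <- matrix(stats::rbinom(n_tot * L, 2L, freq_s), n_tot, L)

  ids <- sprintf("S%04d", seq_len(n_tot))
  locus_ids <- sprintf("snp%06d", seq_len(L))
  pos_bp <- sort(sample.int(L * 5000L, L))
  alleles <- cbind(rep("A", L), rep("B", L))
  G <- genotype_matrix(dosage, ids, locus_ids, rep("1", L), pos_bp, alleles)

  platforms <- names(config$missing_rate_by_platform)
  S <- data.frame(sample_id = ids, lat = lat, lon = lon,
                  province = province, region = region,
                  platform = sample(platforms, n_tot, replace = TRUE),
                  status = "unknown", stringsAsFactors = FALSE)
  truth <- list(ancestral_freq = p_anc, group_freq = grp_freq,
                true_Q = true_Q,
                true_f = c(f_region = config$f_region,
                           f_province = config$f_province))
  list(G = G, S = S, truth = truth)
}

#' Inject genotyping artifacts into a simulated panel
#'
#' Adds, in order: near-duplicate samples (genotype copies of randomly
#' chosen sources), a platform-restricted frequency shift on a random set of
#' "batch" SNPs, per-platform entry-wise missingness (applied independently
#' to duplicates, making them near- rather than exact duplicates), and null
#' case/control labels.
#'
#' @param G,S outputs of \code{\link{simulate_panel}}.
#' @param config the same \code{\link{sim_config}}.
#' @return list with modified \code{G} and \code{S}; duplicates get ids
#'   \code{<source>_dup}.
#' @export
inject_artifacts <- function(G, S, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 104729L)  # distinct stream from simulate_panel
  n <- length(G$sample_ids); L <- length(G$locus_ids)
  if (config$n_duplicate_pairs > n)
    stop("n_duplicate_pairs exceeds sample count")
  d <- G$dosage
  if (config$n_duplicate_pairs > 0) {
    src <- sample.int(n, config$n_duplicate_pairs)
    d <- rbind(d, d[src, , drop = FALSE])
    S2 <- S[src, , drop = FALSE]
    S2$sample_id <- paste0(S$sample_id[src], "_dup")
    S <- rbind(S, S2)
  }
  ids <- S$sample_id
  if (config$n_batch_snps > 0) {
    if (length(config$missing_rate_by_platform) < 2)
      stop("batch SNPs need at least two platforms")
    pf <- names(config$missing_rate_by_platform)[1]
    on_pf <- which(S$platform == pf)
    batch <- sample.int(L, config$n_batch_snps)
    for (l in batch) {
      p0 <- mean(d[on_pf, l], na.rm = TRUE) / 2
      p1 <- min(max(p0 + config$freq_shift, 0.01), 0.99)
      d[on_pf, l] <- stats::rbinom(length(on_pf), 2L, p1)
    }
    attr(d, "batch_loci") <- G$locus_ids[batch]
  }
  for (pf in names(config$missing_rate_by_platform)) {
    rate <- config$missing_rate_by_platform[[pf]]
    if (rate <= 0) next
    rows <- which(S$platform == pf)
    mask <- matrix(stats::runif(length(rows) * L) < rate, length(rows), L)
    d[rows, ][mask] <- NA_integer_
  }
  if (config$case_fraction > 0)
    S$status <- ifelse(stats::runif(nrow(S)) < config$case_fraction,
                       "case", "control")
  batch_loci <- attr(d, "batch_loci")
  G2 <- genotype_matrix(d, ids, G$locus_ids, G$chrom, G$pos_bp, G$alleles)
  if (!is.null(batch_loci)) attr(G2, "batch_loci") <- batch_loci
  list(G = G2, S = S)
}
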