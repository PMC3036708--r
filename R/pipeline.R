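#' Assemble a pipeline run configuration
#'
#' Either \code{sim} (a \code{\link{sim_config}}) or \code{ped}/\code{map}/
#' \code{metadata} paths must be given.  Permutation counts default to the
#' conventional 5000 (F_ST) and 10,000 (Mann-Whitney / Mantel); the
#' \code{fast} flag scales them down for smoke runs.
#'
#' @param sim optional \code{\link{sim_config}} for a simulated input.
#' @param ped,map,metadata input paths (ignored when \code{sim} given).
#' @param thresholds a \code{\link{qc_thresholds}}.
#' @param n_perm_fst,n_perm_mw permutation counts.
#' @param downsample_n equal-size downsampling target for frequency and LD
#'   comparisons (NULL disables).
#' @param k_range K values for the admixture scan.
#' @param n_admix_replicates replicate admixture runs per K.
#' @param grid_radius_km,grid_min_n grid-circle parameters.
#' @param n_barriers barriers to trace.
#' @param out_dir output directory (created).
#' @param seed master seed; stage s uses seed + 1000 * s.
#' @param fast if TRUE, permutation counts are divided by 50.
#' @return a \code{run_config} list.
#' @export
run_config <- function(sim = NULL, ped = NULL, map = NULL, metadata = NULL,
                       thresholds = qc_thresholds(),
                       n_perm_fst = 5000, n_perm_mw = 10000,
                       downsample_n = 115, k_range = 1:3,
                       n_admix_replicates = 2,
                       grid_radius_km = 150, grid_min_n = 20,
                       n_barriers = 2, out_dir = tempfile("svepop_run"),
                       seed = 1L, fast = FALSE) {
  if (is.null(sim)) {
    for (p in c(ped, map, metadata))
      if (!file.exists(p)) stop("input path does not exist: ", p)
    if (is.null(ped) || is.null(map) || is.null(metadata))
      stop("either sim or all of ped/map/metadata must be given")
  }
  if (fast) {
    n_perm_fst <- max(20, n_perm_fst %/% 50)
    n_perm_mw <- max(20, n_perm_mw %/% 50)
  }
  structure(list(sim = sim, ped = ped, map = map, metadata = metadata,
                 thresholds = thresholds, n_perm_fst = n_perm_fst,
                 n_perm_mw = n_perm_mw, downsample_n = downsample_n,
                 k_range = k_range, n_admix_replicates = n_admix_replicates,
                 grid_radius_km = grid_radius_km, grid_min_n = grid_min_n,
                 n_barriers = n_barriers, out_dir = out_dir,
                 seed = as.integer(seed), fast = fast),
            class = "run_config")
}

.stage_seed <- function(config, stage_index) config$seed + 1000L * stage_index

#' Run the full population-structure workflow
#'
#' Stages, in order: input (simulate or read) -> QC -> IBS/MDS -> F_ST
#' (global, pairwise, hierarchical) -> frequency scan (lambda, significant
#' fraction) -> LD decay -> spatial (Mantel, inbreeding, grid) -> admixture
#' (+ Evanno) -> barriers.  Every stage writes its tables into
#' \code{out_dir} as TSV before the next stage starts, so a failed run
#' leaves its partial outputs behind; the failure error names the stage.
#' A manifest records the seeds and parameters.
#'
#' @param config a \code{\link{run_config}}.
#' @return invisibly, a list of the principal in-memory results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  res <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  stage("input", {
    if (!is.null(config$sim)) {
      pan <- simulate_panel(config$sim)
      pan2 <- inject_artifacts(pan$G, pan$S, config$sim)
      G <- pan2$G; S <- pan2$S
      res$truth <- pan$truth
    } else {
      G <- read_ped_map(config$ped, config$map)
      S <- read_sample_metadata(config$metadata)
      al <- align_samples(G, S)
      G <- al$G; S <- al$S
    }
    res$G_raw <- G; res$S <- S
  })
  G <- res$G_raw; S <- res$S

  stage("qc", {
    dup <- remove_duplicates_by_ibs(G, config$thresholds$dup_ibs_distance)
    if (length(dup$removed)) {
      G <- subset_genotypes(G, samples = dup$kept)
      S <- S[S$sample_id %in% dup$kept, , drop = FALSE]
    }
    qr <- apply_qc(G, S, config$thresholds, populations_for_hwe = "province")
    G <- qr$G
    S <- S[match(G$sample_ids, S$sample_id), , drop = FALSE]
    utils::write.table(qr$report$removed_snps, out("qc_removed_snps.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(qr$report$removed_samples,
                       out("qc_removed_samples.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    res$qc_report <- qr$report
    res$duplicates <- dup
  })

  stage("ibs_mds", {
    ibs <- ibs_matrix(G)
    mds <- classical_mds(ibs, dims = 2)
    write_distance_matrix(ibs, out("ibs_matrix.tsv"))
    utils::write.table(
      data.frame(sample_id = rownames(mds$coordinates), mds$coordinates),
      out("mds_coordinates.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    res$ibs <- ibs; res$mds <- mds
  })

  stage("fst", {
    sd1 <- .stage_seed(config, 4L)
    fst <- fst_permutation_p(G, S$province, n_perm = config$n_perm_fst,
                             seed = sd1)
    pw <- pairwise_fst_matrix(G, S$province)
    hier <- hierarchical_fst(G, S$region, S$province,
                             n_perm = config$n_perm_fst, seed = sd1)
    write_distance_matrix(pw, out("pairwise_fst_x1e4.tsv"), times_1e4 = TRUE)
    utils::write.table(
      data.frame(theta = fst$theta, p_perm = fst$p_perm,
                 f_ct = hier$f_ct, f_sc = hier$f_sc, f_st = hier$f_st,
                 p_ct = hier$p_ct, p_sc = hier$p_sc),
      out("fst_summary.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    res$fst <- fst; res$pairwise_fst <- pw; res$hier_fst <- hier
  })

  stage("freq_scan", {
    # scan the two most distant regions (first vs last by latitude)
    regs <- names(sort(tapply(S$lat, S$region, mean)))
    gsel <- S$region %in% c(regs[1], regs[length(regs)])
    Gs <- subset_genotypes(G, samples = which(gsel))
    lb <- S$region[gsel]
    if (!is.null(config$downsample_n) &&
        all(table(lb) >= config$downsample_n)) {
      Gs <- downsample(Gs, lb, config$downsample_n,
                       seed = .stage_seed(config, 5L))
      lb <- S$region[gsel][match(Gs$sample_ids, S$sample_id[gsel])]
    }
    scan <- chisq_scan(Gs, lb)
    okrows <- !scan$monomorphic & !scan$degenerate
    lam <- lambda_overdispersion(scan$chi2[okrows])
    frac <- significant_fraction(scan$p[okrows], 0.05)
    utils::write.table(scan, out("chisq_scan.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(qq_coordinates(scan$chi2[okrows]),
                       out("qq_coordinates.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(data.frame(lambda = lam, frac_sig_0.05 = frac,
                                  groupA = regs[1],
                                  groupB = regs[length(regs)]),
                       out("scan_summary.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    res$scan <- scan; res$lambda <- lam; res$frac_sig <- frac
  })

  stage("ld", {
    sd2 <- .stage_seed(config, 6L)
    n_index <- min(200L, length(G$locus_ids))
    pairs <- sample_ld_pairs(G, n_index, max_dist_bp = 500000, seed = sd2)
    if (nrow(pairs) > 2000) pairs <- pairs[seq_len(2000), , drop = FALSE]
    prof <- NULL
    if (nrow(pairs) > 0) {
      pairs <- ld_pairs_dprime(G, pairs)
      prof <- ld_decay_profile(pairs)
      utils::write.table(pairs, out("ld_pairs.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      utils::write.table(prof, out("ld_profile.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    res$ld_pairs <- pairs; res$ld_profile <- prof
  })

  stage("spatial", {
    sd3 <- .stage_seed(config, 7L)
    geo <- great_circle_matrix(S)
    mt <- mantel_test(res$ibs, geo, n_perm = config$n_perm_mw, seed = sd3)
    inb <- inbreeding_coefficients(G)
    kw <- kruskal_wallis_by_region(inb$F, S$region)
    grid_f <- grid_local_statistic(S, values = inb$F,
                                   kind = "median_inbreeding",
                                   radius_km = config$grid_radius_km,
                                   min_n = config$grid_min_n)
    utils::write.table(inb, out("inbreeding.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(grid_f, out("grid_inbreeding.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(data.frame(mantel_r = mt$r, mantel_p = mt$p,
                                  kruskal_H = kw$H, kruskal_p = kw$p),
                       out("spatial_summary.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    res$geo <- geo; res$mantel <- mt; res$inbreeding <- inb
    res$kruskal <- kw; res$grid_inbreeding <- grid_f
  })

  stage("admix", {
    sd4 <- .stage_seed(config, 8L)
    logliks <- list()
    best_fit <- NULL
    for (K in config$k_range) {
      ll <- numeric(config$n_admix_replicates)
      for (r in seq_len(config$n_admix_replicates)) {
        fit <- admixture_em(G, K, seed = sd4 + 10L * K + r,
                            n_restarts = 1, tol = 1e-4, max_iter = 300)
        ll[r] <- fit$loglik
        if (K == 2 && (is.null(best_fit) || fit$loglik > best_fit$loglik))
          best_fit <- fit
      }
      logliks[[as.character(K)]] <- ll
    }
    ev <- if (length(config$k_range) >= 3 &&
              all(vapply(logliks, stats::sd, 1) > 0))
      evanno_delta_k(logliks) else NULL
    if (!is.null(best_fit)) {
      write_q_matrix(best_fit$Q, out("admixture_Q_K2.txt"))
      grid_a <- grid_local_statistic(S, values = best_fit$Q[, 1],
                                     kind = "median_ancestry",
                                     radius_km = config$grid_radius_km,
                                     min_n = config$grid_min_n)
      utils::write.table(grid_a, out("grid_ancestry.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      res$grid_ancestry <- grid_a
    }
    if (!is.null(ev))
      utils::write.table(ev, out("evanno.tsv"), sep = "\t", quote = FALSE,
                         row.names = FALSE)
    res$admixture <- best_fit; res$evanno <- ev
    res$admix_logliks <- logliks
  })

  stage("barrier", {
    cen <- stats::aggregate(cbind(lat, lon) ~ province, data = S, FUN = mean)
    names(cen)[1] <- "name"
    if (nrow(cen) >= 3) {
      rf <- residual_fst(res$pairwise_fst, cen)
      br <- monmonier_barriers(rf$residuals, cen,
                               n_barriers = min(config$n_barriers,
                                                nrow(cen) - 1))
      write_barriers(br, out("barriers.tsv"))
      res$residual_fst <- rf; res$barriers <- br
    }
  })

  stage("manifest", {
    man <- list(package = "svepop",
                version = as.character(utils::packageVersion("svepop")),
                seed = config$seed,
                stage_seeds = stats::setNames(
                  as.list(config$seed + 1000L * (1:8)),
                  c("input", "qc", "ibs_mds", "fst", "freq_scan", "ld",
                    "spatial", "admix")),
                n_perm_fst = config$n_perm_fst,
                n_perm_mw = config$n_perm_mw,
                downsample_n = config$downsample_n,
                k_range = config$k_range,
                thresholds = unclass(config$thresholds),
                fast = config$fast)
    yaml::write_yaml(man, out("manifest.yaml"))
  })
  invisible(res)
}
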