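test_that("chi-square scan matches the textbook 2x2 evaluation", {
  # group1 30/170, group2 50/150 minor/major alleles (100 diploids each)
  g1 <- c(rep(1L, 30), rep(0L, 70))   # 30 minor copies in 200
  g2 <- c(rep(1L, 50), rep(0L, 50))   # 50 minor copies in 200
  G <- gm(matrix(c(g1, g2), ncol = 1))
  scan <- chisq_scan(G, rep(c("a", "b"), each = 100))
  tab <- rbind(c(30, 170), c(50, 150))
  ref <- suppressWarnings(chisq.test(tab, correct = FALSE))
  expect_equal(scan$chi2, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(scan$p, ref$p.value, tolerance = 1e-12)
  # direct sum((O-E)^2/E) route as well
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(scan$chi2, sum((tab - E)^2 / E), tolerance = 1e-12)
})

test_that("scan flags degenerate loci and zeroes equal-frequency loci", {
  d <- cbind(c(2L, 0L, 2L, 0L), c(NA, NA, 1L, 1L), c(1L, 1L, 1L, 1L))
  scan <- chisq_scan(gm(d), c("a", "a", "b", "b"))
  expect_equal(scan$chi2[1], 0)          # identical counts in both groups
  expect_equal(scan$p[1], 1)
  expect_true(scan$degenerate[2])        # missing in all of group a
  expect_false(scan$monomorphic[1])
  expect_error(chisq_scan(gm(d), rep("a", 4)), "two groups")
})

test_that("scan is symmetric in group order and allele relabeling", {
  set.seed(30)
  d <- matrix(rbinom(60 * 40, 2, 0.3), 60, 40)
  labs <- rep(c("a", "b"), each = 30)
  s1 <- chisq_scan(gm(d), labs)
  s2 <- chisq_scan(gm(d), rev(labs))
  expect_equal(s1$chi2, s2$chi2, tolerance = 1e-12)
  dsw <- d; dsw[, 1:20] <- 2L - dsw[, 1:20]
  s3 <- chisq_scan(gm(dsw), labs)
  expect_equal(s1$chi2, s3$chi2, tolerance = 1e-12)
})

test_that("lambda is the smallest-90% ratio with chi2(1) quantile expectation", {
  m <- 1000
  expd_full <- qchisq((seq_len(m) - 0.5) / m, df = 1)
  expect_equal(lambda_overdispersion(expd_full), 1, tolerance = 1e-12)
  expect_equal(lambda_overdispersion(2 * expd_full), 2, tolerance = 1e-12)
  expect_error(lambda_overdispersion(rep(0, 100)), "zero")
  expect_error(lambda_overdispersion(1:5), "at least 10")
})

test_that("lambda is calibrated at 1 on exact null chi-square draws", {
  lam <- vapply(1:5, function(s) {
    set.seed(300 + s)
    lambda_overdispersion(rchisq(50000, df = 1))
  }, 1)
  expect_true(all(abs(lam - 1) < 0.02))
})

test_that("lambda grows with the differentiation parameter", {
  lam <- vapply(c(0, 0.005, 0.02), function(f) {
    mean(vapply(1:3, function(s) {
      set.seed(1000 * s + round(1e4 * f))
      p <- runif(5000, 0.05, 0.5)
      fr1 <- if (f == 0) p else rbeta(5000, p * (1 - f) / f,
                                      (1 - p) * (1 - f) / f)
      fr2 <- if (f == 0) p else rbeta(5000, p * (1 - f) / f,
                                      (1 - p) * (1 - f) / f)
      d <- rbind(matrix(rbinom(115 * 5000, 2, rep(fr1, each = 115)), 115),
                 matrix(rbinom(115 * 5000, 2, rep(fr2, each = 115)), 115))
      scan <- chisq_scan(gm(d), rep(c("a", "b"), each = 115))
      lambda_overdispersion(scan$chi2[!scan$monomorphic & !scan$degenerate])
    }, 1))
  }, 1)
  expect_true(all(diff(lam) > 0))
})

test_that("significant fraction counts strictly below alpha", {
  expect_equal(significant_fraction(c(0.01, 0.2, 0.04, 0.8), 0.05), 0.5)
  expect_equal(significant_fraction(rep(1e-6, 7), 0.05), 1)
  expect_error(significant_fraction(numeric(0)), "empty")
  expect_error(significant_fraction(0.5, alpha = 1), "alpha")
})

test_that("nearest-gene annotation applies the 200 kb cap and tie rule", {
  genes <- data.frame(gene_id = c("g1", "g2", "g3"),
                      chrom = c("1", "1", "2"),
                      start_bp = c(1000L, 5000L, 100L),
                      end_bp = c(2000L, 6000L, 200L))
  scan <- data.frame(locus_id = c("in_g1", "between", "far", "tie"),
                     chrom = "1",
                     pos_bp = c(1500L, 2500L, 300000L, 3499L),
                     p = c(1e-5, 1e-5, 1e-5, 1e-5))
  # tie SNP: gap to g1 end (2000..) = 3499-1999 = 1500; to g2 start = 1501
  ann <- annotate_top_snps(scan, genes, p_cutoff = 1e-3)
  expect_equal(ann$distance_bp[ann$locus_id == "in_g1"], 0)
  expect_equal(ann$gene_id[ann$locus_id == "in_g1"], "g1")
  expect_false("far" %in% ann$locus_id)  # nearest gene 294 kb away
  # exact equidistance: gap to g1 end = 3500 - 1999 = 1501 = 5001 - 3500
  genes_tie <- data.frame(gene_id = c("g1", "g2"), chrom = "1",
                          start_bp = c(1000L, 5001L),
                          end_bp = c(2000L, 6000L))
  scan2 <- data.frame(locus_id = "mid", chrom = "1", pos_bp = 3500L,
                      p = 1e-5)
  ann2 <- annotate_top_snps(scan2, genes_tie, p_cutoff = 1e-3)
  expect_equal(nrow(ann2), 2)
  expect_equal(ann2$gene_id[ann2$primary], "g1")
  genes_bad <- genes[c(2, 1, 3), ]
  expect_error(annotate_top_snps(scan, genes_bad, 1e-3), "sorted")
})

test_that("interval overlap counting is exact-binomial against saturation", {
  scan <- data.frame(locus_id = sprintf("s%d", 1:100), chrom = "1",
                     pos_bp = seq(1000L, 100000L, by = 1000L),
                     p = c(rep(0.01, 10), rep(0.5, 90)))
  all_iv <- data.frame(chrom = "1", start_bp = 1L, end_bp = 200000L)
  res <- interval_overlap_count(scan, all_iv, alpha = 0.05)
  expect_equal(res$observed, 10)
  expect_equal(res$expected, 10)
  expect_true(res$ld_caveat)
  # enrichment: all significant SNPs inside a small interval
  iv <- data.frame(chrom = "1", start_bp = 1L, end_bp = 10500L)
  res2 <- interval_overlap_count(scan, iv, alpha = 0.05)
  expect_equal(res2$observed, 10)
  expect_equal(res2$p_binomial,
               pbinom(9, res2$n_in, 0.1, lower.tail = FALSE))
  expect_lt(res2$p_binomial, 0.01)
  expect_error(interval_overlap_count(scan, all_iv[0, ], 0.05), "empty")
  off <- data.frame(chrom = "2", start_bp = 1L, end_bp = 10L)
  expect_error(interval_overlap_count(scan, off, 0.05), "no SNPs")
})
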