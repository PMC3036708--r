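test_that("exact HWE test matches full enumeration and its symmetries", {
  expect_equal(hwe_exact_test(10, 0, 0), 1)
  expect_equal(hwe_exact_test(3, 4, 3), oracle_hwe(3, 4, 3))
  expect_equal(hwe_exact_test(3, 4, 3), hwe_exact_test(3, 4, 3))
  # allele relabeling symmetry
  for (tr in list(c(5, 2, 1), c(0, 6, 2), c(7, 1, 4)))
    expect_equal(hwe_exact_test(tr[1], tr[2], tr[3]),
                 hwe_exact_test(tr[3], tr[2], tr[1]))
  expect_error(hwe_exact_test(0, 0, 0), "zero")
})

test_that("exact HWE test equals enumeration for all tables up to 30 alleles", {
  for (n in 1:15) {
    for (nAA in 0:n) for (nAa in 0:(n - nAA)) {
      naa <- n - nAA - nAa
      expect_equal(hwe_exact_test(nAA, nAa, naa),
                   oracle_hwe(nAA, nAa, naa),
                   tolerance = 1e-12,
                   label = sprintf("table (%d,%d,%d)", nAA, nAa, naa))
    }
  }
})

test_that("QC cascade removes low call-rate samples then SNPs, HWE, MAF", {
  set.seed(1)
  d <- matrix(rbinom(40 * 200, 2, 0.4), 40, 200)
  d[1, 1:5] <- NA                      # sample 1 call rate 195/200 < 0.99
  d[2:3, 5] <- NA                      # SNP 5 call rate 37/39 after s1 gone
  d[, 10] <- rep(1L, 40)               # all-heterozygote SNP: HWE failure
  d[, 20] <- c(1L, rep(0L, 39))        # MAF = 1/80 < 0.05
  G <- gm(d)
  res <- apply_qc(G, thresholds = qc_thresholds(sample_callrate = 0.99,
                                                snp_callrate = 0.95,
                                                hwe_p = 1e-4, maf = 0.05))
  rep_ <- res$report
  expect_equal(rep_$removed_samples$sample_id, "s001")
  expect_true("l0005" %in%
                rep_$removed_snps$locus_id[rep_$removed_snps$reason == "snp_callrate"])
  expect_true("l0010" %in%
                rep_$removed_snps$locus_id[rep_$removed_snps$reason == "hwe"])
  expect_true("l0020" %in%
                rep_$removed_snps$locus_id[rep_$removed_snps$reason == "maf"])
  # counts reconcile with matrix dimensions
  expect_equal(rep_$n_samples_before - nrow(rep_$removed_samples),
               rep_$n_samples_after)
  expect_equal(rep_$n_snps_before - nrow(rep_$removed_snps),
               rep_$n_snps_after)
  # idempotence
  res2 <- apply_qc(res$G, thresholds = qc_thresholds(sample_callrate = 0.99,
                                                     snp_callrate = 0.95,
                                                     hwe_p = 1e-4, maf = 0.05))
  expect_identical(res2$G$dosage, res$G$dosage)
  expect_equal(nrow(res2$report$removed_snps), 0)
})

test_that("a clean well-behaved matrix passes QC untouched", {
  set.seed(2)
  d <- matrix(rbinom(50 * 30, 2, 0.3), 50, 30)
  res <- apply_qc(gm(d))
  expect_equal(dim(res$G$dosage), c(50L, 30L))
  expect_equal(nrow(res$report$removed_snps), 0)
  expect_equal(nrow(res$report$removed_samples), 0)
})

test_that("duplicate removal keeps the highest-call-rate member per component", {
  set.seed(3)
  base <- rbinom(200, 2, 0.5)
  d <- rbind(base, base, rbinom(200, 2, 0.5))
  d[2, 1:2] <- NA  # the copy has 2 extra missing entries
  G <- gm(d)
  res <- remove_duplicates_by_ibs(G, 0.05)
  expect_equal(res$removed, "s002")
  expect_true(all(c("s001", "s003") %in% res$kept))
  # no pair under threshold: everything kept
  set.seed(4)
  G2 <- gm(matrix(rbinom(3 * 200, 2, 0.5), 3, 200))
  res2 <- remove_duplicates_by_ibs(G2, 0.05)
  expect_equal(length(res2$removed), 0)
  # triangle of three mutual near-duplicates: exactly one kept
  d3 <- rbind(base, base, base, rbinom(200, 2, 0.5))
  d3[1, 1] <- NA; d3[3, 1:3] <- NA
  res3 <- remove_duplicates_by_ibs(gm(d3), 0.05)
  expect_setequal(res3$removed, c("s001", "s003"))  # s002 has top call rate
  expect_true("s002" %in% res3$kept)
})

test_that("two-group frequency filter behaves at the bounds", {
  set.seed(5)
  d <- matrix(rbinom(40 * 25, 2, 0.4), 40, 25)
  d[, 5] <- 0L  # monomorphic everywhere: never removed
  grp <- rep(c("x", "y"), each = 20)
  # identical groups -> mirrored genotypes, chi-square 0
  dd <- rbind(d[1:20, ], d[1:20, ])
  expect_length(two_group_frequency_filter(gm(dd), grp, 0.5), 0)
  # threshold 1 removes every polymorphic SNP with any frequency difference
  rem <- two_group_frequency_filter(gm(d), grp, 1.0)
  expected <- vapply(1:25, function(l) {
    cx <- sum(d[1:20, l]); cy <- sum(d[21:40, l])
    tab <- rbind(c(cx, 40 - cx), c(cy, 40 - cy))
    sum(tab[, 1]) > 0 && sum(tab[, 2]) > 0 &&
      suppressWarnings(chisq.test(tab, correct = FALSE)$statistic) > 0
  }, TRUE)
  expect_setequal(rem, sprintf("l%04d", which(expected)))
  expect_error(two_group_frequency_filter(gm(d), rep("x", 40), 0.5),
               "two groups")
})

test_that("LD pruning drops one of a duplicated column and keeps singletons", {
  set.seed(6)
  d <- matrix(rbinom(100 * 10, 2, 0.5), 100, 10)
  d[, 7] <- d[, 4]  # perfect LD pair (positions 4 < 7)
  kept <- ld_prune(gm(d), window_snps = 10, step_snps = 5,
                   r2_threshold = 0.5)
  expect_true("l0004" %in% kept)
  expect_false("l0007" %in% kept)
  expect_equal(length(kept), 9)
  # single SNP: retained, no pairs to test
  expect_equal(ld_prune(gm(matrix(rbinom(20, 2, 0.5), 20, 1))), "l0001")
  expect_error(ld_prune(gm(d), window_snps = 1), "window")
})

test_that("independent SNPs survive pruning at r2 = 0.5", {
  set.seed(7)
  d <- matrix(rbinom(500 * 40, 2, 0.3), 500, 40)
  kept <- ld_prune(gm(d), window_snps = 20, step_snps = 5,
                   r2_threshold = 0.5)
  expect_equal(length(kept), 40)
})
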