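st <- function(lat, lon, ids = sprintf("s%02d", seq_along(lat))) {
  data.frame(sample_id = ids, lat = lat, lon = lon, province = "P",
             region = "R", platform = "i", status = "unknown")
}

test_that("great-circle distances use the IUGG radius and are symmetric", {
  S <- st(c(0, 0), c(0, 1))
  D <- great_circle_matrix(S)
  expect_equal(D$values[1, 2], pi * 6371.0088 / 180, tolerance = 1e-9)
  S2 <- st(c(60, 60), c(15, 15))
  expect_equal(great_circle_matrix(S2)$values[1, 2], 0)
  set.seed(50)
  S3 <- st(runif(6, 55, 68), runif(6, 11, 24))
  V <- great_circle_matrix(S3)$values
  expect_equal(V, t(V))
  S3$lat[2] <- NA
  expect_error(great_circle_matrix(S3), "s02")
})

test_that("Mantel r and p behave for proportional and exact-null inputs", {
  set.seed(51)
  X <- matrix(rnorm(16), 8, 2)
  A <- as.matrix(dist(X)); B <- 2 * A
  res <- mantel_test(A, B, n_perm = 199, seed = 3)
  expect_equal(res$r, 1, tolerance = 1e-12)
  expect_equal(res$p, 1 / 200)
  expect_error(mantel_test(matrix(0, 4, 4), A[1:4, 1:4], 99), "constant")
})

test_that("exact Mantel enumeration matches a brute-force oracle at n = 4", {
  set.seed(52)
  A <- as.matrix(dist(matrix(rnorm(8), 4, 2)))
  B <- as.matrix(dist(matrix(rnorm(8), 4, 2)))
  res <- mantel_test(A, B, exact = TRUE)
  allp <- expand.grid(rep(list(1:4), 4))
  allp <- allp[apply(allp, 1, function(p) length(unique(p)) == 4), ]
  ut <- function(M) M[upper.tri(M)]
  rs <- apply(allp, 1, function(p) {
    p <- as.integer(p); cor(ut(A), ut(B[p, p]))
  })
  r_obs <- cor(ut(A), ut(B))
  expect_equal(res$n_perm, 24)
  expect_equal(res$r, r_obs)
  expect_equal(res$p, mean(rs >= r_obs - 1e-12))
})

test_that("Mantel r agrees with vegan and is invariant to joint relabeling", {
  skip_if_not_installed("vegan")
  set.seed(53)
  A <- as.matrix(dist(matrix(rnorm(20), 10, 2)))
  B <- as.matrix(dist(matrix(rnorm(20), 10, 2)))
  res <- mantel_test(A, B, n_perm = 99, seed = 1)
  vg <- vegan::mantel(as.dist(A), as.dist(B), permutations = 99)
  expect_equal(res$r, unname(vg$statistic), tolerance = 1e-12)
  p <- sample(10)
  res2 <- mantel_test(A[p, p], B[p, p], n_perm = 99, seed = 1)
  expect_equal(res2$r, res$r, tolerance = 1e-12)
})

test_that("inbreeding coefficients hit their closed-form extremes", {
  set.seed(54)
  d <- matrix(rbinom(40 * 200, 2, 0.4), 40, 200)
  d[1, ] <- ifelse(d[1, ] == 1L, 2L, d[1, ])   # fully homozygous sample
  d[2, ] <- 1L                                 # fully heterozygous sample
  inb <- inbreeding_coefficients(gm(d))
  expect_equal(inb$F[1], 1)
  expect_equal(inb$F[2], -inb$E_hom[2] / (inb$L[2] - inb$E_hom[2]))
  expect_lt(inb$F[2], 0)
  expect_equal(inb$O_hom[2], 0)
})

test_that("inbreeding is centred at zero under Hardy-Weinberg", {
  set.seed(55)
  p <- runif(10000, 0.05, 0.5)
  d <- matrix(rbinom(500 * 10000, 2, rep(p, each = 500)), 500, 10000)
  inb <- inbreeding_coefficients(gm(d))
  expect_lt(abs(mean(inb$F)), 0.01)
})

test_that("inbreeding detects gamete self-pairing excess homozygosity", {
  set.seed(56)
  p <- runif(3000, 0.1, 0.5)
  d0 <- sim_inbred_dosage(60, 3000, p, 0)
  d1 <- sim_inbred_dosage(60, 3000, p, 0.1)
  inb <- inbreeding_coefficients(gm(rbind(d0, d1)))
  labs <- rep(c("outbred", "inbred"), each = 60)
  expect_gt(mean(inb$F[labs == "inbred"]), mean(inb$F[labs == "outbred"]))
  kw <- kruskal_wallis_by_region(inb$F, labs)
  expect_lt(kw$p, 0.01)
})

test_that("Kruskal-Wallis wrapper matches stats and handles degeneracy", {
  x <- c(1, 2, 3, 1, 2, 3)
  g <- rep(c("a", "b"), each = 3)
  kw <- kruskal_wallis_by_region(x, g)
  expect_equal(kw$H, 0)
  expect_equal(kw$p, 1)
  set.seed(57)
  y <- c(rnorm(50), rnorm(50, 3))
  kw2 <- kruskal_wallis_by_region(y, rep(c("a", "b"), each = 50))
  expect_lt(kw2$p, 1e-6)
  ref <- kruskal.test(y, factor(rep(c("a", "b"), each = 50)))
  expect_equal(kw2$H, unname(ref$statistic))
  expect_error(kruskal_wallis_by_region(x, rep("a", 6)), "2 groups")
})

test_that("grid cells respect min_n and compute the right statistic", {
  set.seed(58)
  # 19 samples in one tight cluster: no cell at min_n = 20
  S <- st(59 + rnorm(19, 0, 0.05), 15 + rnorm(19, 0, 0.05))
  g0 <- grid_local_statistic(S, values = rep(1, 19),
                             kind = "median_inbreeding", min_n = 20)
  expect_equal(nrow(g0), 0)
  # 25 samples, constant value v: every cell reports v with n >= 20
  S2 <- st(59 + rnorm(25, 0, 0.05), 15 + rnorm(25, 0, 0.05),
           ids = sprintf("t%02d", 1:25))
  g1 <- grid_local_statistic(S2, values = rep(0.37, 25),
                             kind = "median_inbreeding", min_n = 20)
  expect_gt(nrow(g1), 0)
  expect_true(all(g1$value == 0.37))
  expect_true(all(g1$n >= 20))
})

test_that("local correlation is 1 when genetic distance equals geography", {
  set.seed(59)
  S <- st(59 + rnorm(45, 0, 0.3), 15 + rnorm(45, 0, 0.3),
          ids = sprintf("u%02d", 1:45))
  geo <- great_circle_matrix(S)
  gen <- square_distance_matrix(geo$values / max(geo$values), S$sample_id,
                                "ibs_distance")
  gc <- grid_local_statistic(S, D_gen = gen, D_geo = geo,
                             kind = "local_correlation",
                             grid_spacing_km = 30)
  expect_gt(nrow(gc), 0)
  expect_true(all(abs(gc$value - 1) < 1e-10))
  expect_true(all(gc$n >= 40))  # the stricter default for correlations
})

test_that("emitted cells always satisfy min_n on randomized layouts", {
  set.seed(60)
  for (rep_ in 1:5) {
    n <- sample(30:80, 1)
    S <- st(runif(n, 56, 66), runif(n, 12, 22),
            ids = sprintf("r%03d", 1:n))
    mn <- sample(3:10, 1)
    g <- grid_local_statistic(S, values = rnorm(n),
                              kind = "median_inbreeding", min_n = mn,
                              grid_spacing_km = 100)
    if (nrow(g)) expect_true(all(g$n >= mn))
  }
})
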