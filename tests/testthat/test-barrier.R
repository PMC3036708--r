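cent <- function(lat, lon, names = LETTERS[seq_along(lat)]) {
  data.frame(name = names, lat = lat, lon = lon)
}

test_that("residuals vanish for a perfect linear distance relation", {
  cen <- cent(c(56, 58, 61, 64), c(14, 15, 17, 19))
  geo <- great_circle_matrix(data.frame(sample_id = cen$name,
                                        lat = cen$lat, lon = cen$lon))
  V <- 0.001 + 2e-6 * geo$values
  diag(V) <- 0
  fst <- square_distance_matrix(V, cen$name, "fst")
  rf <- residual_fst(fst, cen)
  expect_lt(max(abs(rf$residuals$values)), 1e-12)
})

test_that("three-population residuals equal the normal-equations solution", {
  cen <- cent(c(56, 60, 63), c(14, 18, 15))
  geo <- great_circle_matrix(data.frame(sample_id = cen$name,
                                        lat = cen$lat, lon = cen$lon))
  g <- geo$values[upper.tri(geo$values)]
  f <- c(0.0004, 0.0011, 0.0007)
  V <- matrix(0, 3, 3); V[upper.tri(V)] <- f; V <- V + t(V)
  fst <- square_distance_matrix(V, cen$name, "fst")
  rf <- residual_fst(fst, cen)
  X <- cbind(1, g)
  beta <- solve(t(X) %*% X, t(X) %*% f)
  expect_equal(rf$residuals$values[upper.tri(V)],
               as.vector(f - X %*% beta), tolerance = 1e-12)
  # intercept absorption: constant shifts leave residuals unchanged
  fst2 <- square_distance_matrix(V + 0.01 * (1 - diag(3)), cen$name, "fst")
  rf2 <- residual_fst(fst2, cen)
  expect_equal(rf2$residuals$values, rf$residuals$values, tolerance = 1e-12)
})

test_that("a single triangle's barrier starts at the largest residual", {
  cen <- cent(c(56, 60, 58), c(14, 15, 19))
  V <- matrix(0, 3, 3)
  V[1, 2] <- V[2, 1] <- 0.005
  V[1, 3] <- V[3, 1] <- 0.001
  V[2, 3] <- V[3, 2] <- 0.0005
  R <- square_distance_matrix(V, cen$name, "fst")
  br <- monmonier_barriers(R, cen, n_barriers = 1)
  first <- br$barriers[[1]][1, ]
  expect_setequal(c(first$pop_a, first$pop_b), c("A", "B"))
})

test_that("a planted wall is traced exactly along its inflated edges", {
  # 2 columns x 3 rows of centroids; the wall separates west from east
  cen <- cent(rep(c(56, 60, 64), each = 2), rep(c(14, 20), times = 3),
              names = c("W1", "E1", "W2", "E2", "W3", "E3"))
  west <- c("W1", "W2", "W3")
  k <- nrow(cen)
  V <- matrix(0.001, k, k, dimnames = list(cen$name, cen$name))
  for (i in 1:k) for (j in 1:k) {
    if (xor(cen$name[i] %in% west, cen$name[j] %in% west))
      V[i, j] <- 0.01
  }
  diag(V) <- 0
  R <- square_distance_matrix(V, cen$name, "fst")
  br <- monmonier_barriers(R, cen, n_barriers = 1)
  crossed <- br$barriers[[1]]
  # oracle: the crossed edges must be exactly the Delaunay edges that join
  # a west and an east centroid
  dd <- deldir::deldir(cen$lon, cen$lat, suppressMsge = TRUE)
  tri <- deldir::triMat(dd)
  edges <- unique(t(apply(rbind(tri[, 1:2], tri[, 2:3], tri[, c(1, 3)]),
                          1, sort)))
  wall_edges <- edges[xor(cen$name[edges[, 1]] %in% west,
                          cen$name[edges[, 2]] %in% west), , drop = FALSE]
  got <- paste(pmin(crossed$pop_a, crossed$pop_b),
               pmax(crossed$pop_a, crossed$pop_b))
  want <- paste(pmin(cen$name[wall_edges[, 1]], cen$name[wall_edges[, 2]]),
                pmax(cen$name[wall_edges[, 1]], cen$name[wall_edges[, 2]]))
  expect_setequal(got, want)
  expect_true(all(crossed$residual > 0.005))
})

test_that("equal residuals still terminate with the documented tie rule", {
  cen <- cent(c(56, 60, 58, 62), c(14, 15, 19, 18))
  V <- matrix(0.001, 4, 4); diag(V) <- 0
  R <- square_distance_matrix(V, cen$name, "fst")
  br <- monmonier_barriers(R, cen, n_barriers = 2)
  expect_true(length(br$barriers) >= 1)
  for (b in br$barriers) expect_true(nrow(b) >= 1)
  # the same call repeats identically (deterministic ties)
  br2 <- monmonier_barriers(R, cen, n_barriers = 2)
  expect_identical(br$barriers, br2$barriers)
})

test_that("barriers are invariant to uniform residual scaling", {
  set.seed(80)
  cen <- cent(runif(7, 56, 66), runif(7, 12, 22),
              names = sprintf("p%d", 1:7))
  V <- matrix(0, 7, 7)
  V[upper.tri(V)] <- runif(21, 0, 0.01)
  V <- V + t(V)
  R1 <- square_distance_matrix(V, cen$name, "fst")
  R2 <- square_distance_matrix(5 * V, cen$name, "fst")
  b1 <- monmonier_barriers(R1, cen, 2)
  b2 <- monmonier_barriers(R2, cen, 2)
  for (i in seq_along(b1$barriers)) {
    expect_identical(b1$barriers[[i]][, c("pop_a", "pop_b")],
                     b2$barriers[[i]][, c("pop_a", "pop_b")])
  }
})

test_that("every barrier terminates on randomized configurations", {
  set.seed(81)
  for (rep_ in 1:5) {
    n <- sample(5:9, 1)
    cen <- cent(runif(n, 50, 68), runif(n, 5, 25),
                names = sprintf("q%d", 1:n))
    V <- matrix(0, n, n)
    V[upper.tri(V)] <- runif(n * (n - 1) / 2)
    V <- V + t(V)
    R <- square_distance_matrix(V, cen$name, "fst")
    br <- monmonier_barriers(R, cen, n_barriers = 3)
    all_edges <- do.call(rbind, br$barriers)
    expect_equal(anyDuplicated(all_edges[, c("pop_a", "pop_b")]), 0L)
    # barrier 1 crosses the globally maximal edge among triangulation edges
    dd <- deldir::deldir(cen$lon, cen$lat, suppressMsge = TRUE)
    tri <- deldir::triMat(dd)
    edges <- unique(t(apply(rbind(tri[, 1:2], tri[, 2:3], tri[, c(1, 3)]),
                            1, sort)))
    wmax <- max(V[edges])
    expect_true(any(abs(do.call(rbind, br$barriers)$residual - wmax) < 1e-15))
    expect_equal(max(vapply(br$barriers, function(b) max(b$residual), 1)),
                 wmax)
  }
})

test_that("degenerate geometries are rejected", {
  cen <- cent(c(56, 58, 60), c(14, 14, 14))  # collinear
  V <- matrix(0.001, 3, 3); diag(V) <- 0
  R <- square_distance_matrix(V, cen$name, "fst")
  expect_error(monmonier_barriers(R, cen, 1), "riangulation")
  expect_error(monmonier_barriers(R, cen, 0), "n_barriers")
})
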