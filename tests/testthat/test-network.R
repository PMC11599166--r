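test_that("correlation_network matches the Pearson definition entry by entry", {
  set.seed(3)
  X <- matrix(rnorm(50), 10, 5)
  res <- fake_residuals(X, rep(c("A", "B"), 5))
  net <- correlation_network(res, "A")
  XA <- X[seq(1, 9, 2), ]
  oracle <- matrix(NA_real_, 5, 5)
  for (i in 1:5) for (j in 1:5) {
    xi <- XA[, i] - mean(XA[, i]); xj <- XA[, j] - mean(XA[, j])
    oracle[i, j] <- sum(xi * xj) / sqrt(sum(xi^2) * sum(xj^2))
  }
  expect_equal(unname(net$r), oracle, tolerance = 1e-12)
})

test_that("identical and opposite residual vectors give r of +1 and -1", {
  x <- rnorm(8)
  X <- cbind(a = x, b = x, c = -x, d = rnorm(8))
  res <- fake_residuals(X, rep("A", 8))
  net <- correlation_network(res, "A")
  expect_equal(net$r["a", "b"], 1)
  expect_equal(net$r["a", "c"], -1)
})

test_that("zero-variance regions are rejected by name", {
  X <- cbind(a = rnorm(6), flatroi = rep(2, 6), c = rnorm(6))
  res <- fake_residuals(X, rep("A", 6))
  expect_error(correlation_network(res, "A"), "flatroi")
})

test_that("absolute thresholding is an elementwise comparison", {
  r <- matrix(0.5, 4, 4)
  net <- make_network(r)
  g <- threshold_absolute(net, 0.1)
  expect_equal(g$density, 1)
  expect_equal(g$E, 6L)

  net2 <- make_network(matrix(0.05, 4, 4))
  g2 <- threshold_absolute(net2, 0.1)
  expect_equal(g2$E, 0L)

  set.seed(5)
  r3 <- matrix(runif(16, -1, 1), 4, 4)
  r3 <- (r3 + t(r3)) / 2
  g3 <- threshold_absolute(make_network(r3), 0.1)
  expected <- (r3 > 0.1) * 1L
  diag(expected) <- 0L
  expect_equal(unname(g3$a), expected)
})

test_that("density thresholding keeps exactly the top-ranked positive edges", {
  # N = 90, D = 0.33 -> 1322 edges (round half away from zero)
  set.seed(8)
  z <- matrix(rnorm(90 * 90), 90)
  r <- cor(z)
  g <- threshold_density(make_network(r), 0.33)
  expect_equal(g$E, 1322L)
  expect_equal(g$density, 1322 / (90 * 89 / 2))

  # 6-node matrix: kept edges equal the top-6 found by exhaustive sort
  set.seed(9)
  r6 <- matrix(rnorm(36), 6); r6 <- (r6 + t(r6)) / 2; diag(r6) <- 1
  g6 <- threshold_density(make_network(r6), 0.4)
  expect_equal(g6$E, 6L)
  vals <- r6[upper.tri(r6)]
  cutoff <- sort(vals, decreasing = TRUE)[6]
  expected <- (r6 >= cutoff) * 1L; diag(expected) <- 0L
  expect_equal(unname(g6$a), expected)

  # D = 1 on an all-positive matrix -> complete graph
  rp <- matrix(0.5, 5, 5)
  gc <- threshold_density(make_network(rp), 1)
  expect_equal(unname(gc$a), complete_graph(5))

  # not enough positive entries -> error
  rn <- matrix(-0.5, 5, 5)
  expect_error(threshold_density(make_network(rn), 0.5), "positive")
})

test_that("density grids step without floating-point drift", {
  g <- density_grid()
  expect_identical(g, (33:50) / 100)
  expect_length(density_grid(0.1, 0.9, 0.2), 5)
})

test_that("edge sets are nested along the density grid and D = E/[N(N-1)/2] is exact", {
  set.seed(10)
  for (rep in 1:5) {
    # a shared factor keeps most correlations positive so high densities
    # stay reachable
    r <- cor(matrix(rnorm(30 * 12), 30, 12) + rnorm(30))
    net <- make_network(r)
    grid <- c(0.2, 0.35, 0.5, 0.8)
    prev <- NULL
    for (D in grid) {
      g <- threshold_density(net, D)
      expect_identical(g$density, g$E / (g$N * (g$N - 1) / 2))
      if (!is.null(prev)) expect_true(all(g$a[prev == 1] == 1))
      prev <- g$a
    }
  }
})

test_that("absolute and density thresholding agree at the E-th largest r", {
  set.seed(11)
  r <- cor(matrix(rnorm(25 * 8), 25, 8))
  net <- make_network(r)
  g <- threshold_density(net, 0.4)
  vals <- sort(r[upper.tri(r)], decreasing = TRUE)
  t_star <- vals[g$E + 1] # just below the E-th largest (no ties in random data)
  ga <- threshold_absolute(net, t_star)
  expect_equal(ga$a, g$a)
})

test_that("min_connected_density finds the first fully connected grid point", {
  # 3 ROIs: one edge leaves a node isolated, two edges connect all
  r <- matrix(c(1, 0.9, 0.8, 0.9, 1, 0.1, 0.8, 0.1, 1), 3)
  net <- make_network(r)
  expect_equal(min_connected_density(net, grid = c(1 / 3, 2 / 3, 1)), 2 / 3)

  # star-shaped top edges: density supplying N-1 edges connects everything
  n <- 6
  rs <- matrix(0.01, n, n)
  rs[1, 2:n] <- rs[2:n, 1] <- 0.9
  diag(rs) <- 1
  grid <- seq(0.1, 1, by = 0.1)
  exp_d <- grid[which.max(sapply(grid, function(D) round(D * n * (n - 1) / 2) >= n - 1))]
  expect_equal(min_connected_density(make_network(rs), grid), exp_d)

  # agreement with a BFS connectivity oracle on random 8-node matrices
  set.seed(12)
  for (rep in 1:10) {
    r8 <- cor(matrix(rnorm(20 * 8), 20, 8))
    net8 <- make_network(r8)
    grid8 <- seq(0.15, 1, by = 0.05)
    oracle <- NA_real_
    for (D in grid8) {
      g <- tryCatch(threshold_density(net8, D), error = function(e) NULL)
      if (!is.null(g) && bf_largest_component(g$a) == 8) { oracle <- D; break }
    }
    expect_equal(min_connected_density(net8, grid8), oracle)
  }
})

test_that("networks export as matrix, edge list, and GraphML", {
  set.seed(13)
  r <- cor(matrix(rnorm(40), 10, 4))
  g <- threshold_density(make_network(r), 0.5)
  for (fmt in c("matrix", "edgelist", "graphml")) {
    path <- withr::local_tempfile(fileext = ".txt")
    write_network(g, path, format = fmt)
    expect_gt(file.size(path), 0)
  }
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_network(g, p2, format = "edgelist")
  el <- readr::read_tsv(p2, show_col_types = FALSE)
  expect_equal(nrow(el), g$E)
})
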