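test_that("closed-form metric values hold on canonical small graphs", {
  # path 1-2-3: middle node carries all betweenness
  p3 <- as_scn_graph(path_graph(3))
  nm <- nodal_metrics(p3)
  expect_equal(nm$betweenness, c(0, 1, 0))
  gm <- global_metrics(p3)
  expect_equal(gm$eglob, (1 + 1 + 0.5) / 3)
  expect_equal(gm$lp, 1.2)
  expect_equal(gm$eglob * gm$lp, 1)

  # triangle: full clustering everywhere
  k3 <- as_scn_graph(complete_graph(3))
  nm3 <- nodal_metrics(k3)
  expect_equal(nm3$clustering, rep(1, 3))
  expect_equal(nm3$degree, rep(2L, 3))
  gm3 <- global_metrics(k3)
  expect_equal(gm3$transitivity, 1)
  expect_equal(gm3$cp, 1)
  expect_equal(gm3$eloc, 1)

  # star with 4 leaves: no triangles, perfectly disassortative
  st <- as_scn_graph(star_graph(4))
  gst <- global_metrics(st)
  expect_equal(gst$transitivity, 0)
  expect_equal(gst$assortativity, -1)

  # two disconnected 4-cliques: modularity of the 2-block split is 1/2
  two <- matrix(0L, 8, 8)
  two[1:4, 1:4] <- complete_graph(4)
  two[5:8, 5:8] <- complete_graph(4)
  expect_equal(global_metrics(as_scn_graph(two))$modularity, 0.5)
})

test_that("nodal and global metrics match brute-force oracles on random graphs", {
  set.seed(21)
  for (rep in 1:40) {
    n <- sample(4:8, 1)
    a <- rand_adjacency(n, runif(1, 0.25, 0.7))
    if (sum(a) == 0) next
    g <- as_scn_graph(a)
    nm <- nodal_metrics(g)
    expect_equal(nm$degree, unname(rowSums(a)))
    expect_equal(nm$clustering, bf_clustering(a), tolerance = 1e-12)
    expect_equal(nm$betweenness, bf_betweenness(a), tolerance = 1e-10)

    gm <- global_metrics(g)
    expect_equal(gm$transitivity, bf_transitivity(a), tolerance = 1e-12)
    expect_equal(gm$cp, mean(bf_clustering(a)), tolerance = 1e-12)
    d <- bf_distances(a)
    s <- sum(1 / d[d > 0 & is.finite(d)])
    expect_equal(gm$eglob, s / (n * (n - 1)), tolerance = 1e-12)
  }
})

test_that("triangle counts and distances agree with exhaustive computation", {
  set.seed(22)
  for (rep in 1:20) {
    n <- sample(4:8, 1)
    a <- rand_adjacency(n, 0.5)
    res <- scnet:::cpp_metrics_adjacency(a, rep(FALSE, 6))
    expect_equal(res$n_triangles, bf_triangles(a))
    expect_equal(unname(scnet:::cpp_distances(a)), unname(bf_distances(a)))
  }
})

test_that("harmonic path length is the exact reciprocal of global efficiency", {
  set.seed(23)
  for (rep in 1:20) {
    n <- sample(5:12, 1)
    a <- rand_adjacency(n, runif(1, 0.15, 0.8)) # includes fragmented graphs
    if (sum(a) == 0) next
    gm <- global_metrics(as_scn_graph(a))
    expect_equal(gm$eglob * gm$lp, 1, tolerance = 1e-12)
  }
})

test_that("adding an edge never hurts efficiency and never lengthens paths", {
  set.seed(24)
  for (rep in 1:10) {
    a <- rand_adjacency(8, 0.3)
    zeros <- which(upper.tri(a) & a == 0)
    if (length(zeros) == 0 || sum(a) == 0) next
    pick <- sample(zeros, 1)
    a2 <- a
    a2[pick] <- 1L
    a2[lower.tri(a2)] <- t(a2)[lower.tri(a2)]
    m1 <- global_metrics(as_scn_graph(a))
    m2 <- global_metrics(as_scn_graph(a2))
    expect_gte(m2$eglob, m1$eglob)
    expect_lte(m2$lp, m1$lp)
  }
})

test_that("transitivity equals Cp on vertex-transitive graphs but not stars", {
  ring <- as_scn_graph(ring_lattice(12, 4))
  gr <- global_metrics(ring)
  expect_equal(gr$transitivity, gr$cp, tolerance = 1e-12)
  k6 <- global_metrics(as_scn_graph(complete_graph(6)))
  expect_equal(k6$transitivity, k6$cp)
  # a star with one closed triangle separates the two measures
  br <- star_graph(5)
  br[2, 3] <- br[3, 2] <- 1L
  gb <- global_metrics(as_scn_graph(br))
  expect_false(isTRUE(all.equal(gb$transitivity, gb$cp)))
})

test_that("nodal metrics are equivariant under node relabeling", {
  set.seed(25)
  a <- rand_adjacency(9, 0.4)
  perm <- sample(9)
  ap <- a[perm, perm]
  nm <- nodal_metrics(as_scn_graph(a))
  nmp <- nodal_metrics(as_scn_graph(ap))
  expect_equal(nmp$degree, nm$degree[perm])
  expect_equal(nmp$betweenness, nm$betweenness[perm], tolerance = 1e-12)
  expect_equal(nmp$clustering, nm$clustering[perm], tolerance = 1e-12)
})

test_that("metrics cross-check against igraph on random graphs", {
  set.seed(26)
  for (rep in 1:10) {
    a <- rand_adjacency(15, 0.3)
    if (sum(a) < 4) next
    g <- as_scn_graph(a)
    ig <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
    gm <- global_metrics(g)
    expect_equal(gm$transitivity, igraph::transitivity(ig, type = "global"),
                 tolerance = 1e-12)
    expect_equal(gm$cp, mean(igraph::transitivity(ig, type = "localundirected",
                                                  isolates = "zero")),
                 tolerance = 1e-12)
    if (!is.na(gm$assortativity))
      expect_equal(gm$assortativity, igraph::assortativity_degree(ig),
                   tolerance = 1e-10)
  }
})

test_that("null ensembles preserve the degree sequence exactly", {
  set.seed(27)
  a <- rand_adjacency(20, 0.3)
  g <- as_scn_graph(a)
  nulls <- random_reference(g, m = 8, seed = 42)
  for (k in 1:8)
    expect_equal(sort(nulls$degree_sequences[, k]), sort(unname(rowSums(a))))
})

test_that("rigid graphs yield identical null copies with a warning", {
  k5 <- as_scn_graph(complete_graph(5))
  expect_warning(nulls <- random_reference(k5, m = 5, seed = 1), "no degree-preserving")
  expect_equal(nulls$c_rand, 1)
  expect_equal(nulls$l_rand, 1)
})

test_that("rewiring a lattice destroys clustering", {
  ring <- as_scn_graph(ring_lattice(30, 4))
  # lattice closed form: 3(k-2)/(4(k-1)) = 0.5 for k = 4
  expect_equal(global_metrics(ring)$cp, 0.5)
  nulls <- random_reference(ring, m = 10, seed = 7)
  expect_lt(nulls$c_rand, 0.5)
})

test_that("small-world parameters behave as the normalization dictates", {
  # complete graph vs its identical nulls: gamma = lambda = sigma = 1
  k6 <- as_scn_graph(complete_graph(6))
  suppressWarnings(nulls <- random_reference(k6, m = 3, seed = 1))
  sw <- small_world(k6, nulls)
  expect_equal(sw$gamma, 1)
  expect_equal(sw$lambda, 1)
  expect_equal(sw$sigma, 1)

  # ring lattice: clustered far above its rewired nulls
  ring <- as_scn_graph(ring_lattice(30, 4))
  nulls_r <- random_reference(ring, m = 10, seed = 3)
  swr <- small_world(ring, nulls_r)
  expect_gt(swr$gamma, 1)
  expect_gt(swr$sigma, 1)
  # algebraic identity sigma * lambda = gamma
  expect_equal(swr$sigma * swr$lambda, swr$gamma, tolerance = 1e-12)
})

test_that("modularity is reproducible across repeated calls", {
  set.seed(28)
  a <- rand_adjacency(25, 0.2)
  g <- as_scn_graph(a)
  q1 <- global_metrics(g)$modularity
  q2 <- global_metrics(g)$modularity
  expect_identical(q1, q2)
})

test_that("metric curves carry one value per group, metric, and density", {
  set.seed(29)
  X <- matrix(rnorm(40 * 20), 40, 20)
  res <- fake_residuals(X, rep(c("A", "B"), each = 20))
  grid <- density_grid(0.3, 0.4, 0.05)
  cv <- metric_curves(res, grid)
  expect_equal(nrow(cv), 2 * 7 * 3)
  expect_setequal(unique(cv$metric),
                  c("cp", "lp", "eglob", "eloc", "transitivity", "assortativity",
                    "modularity"))
  aucs <- glance(cv)
  # AUC recomputable from the pairs by the trapezoid rule, exactly
  one <- cv[cv$group == "A" & cv$metric == "cp", ]
  expect_identical(aucs$auc[aucs$group == "A" & aucs$metric == "cp"],
                   sum((one$value[-1] + one$value[-3]) / 2 * diff(one$density)))
})
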