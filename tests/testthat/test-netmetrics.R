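# Graph construction, weighted metrics, random references, normalization,
# sparsity range, AUC.

test_that("thresholding keeps absolute values and zeroes the rest", {
  b <- edge_matrix(c(-0.5, 0.1, 0.25), 3)
  g <- threshold_graph(b, 0.3)
  expect_equal(g$weights[1, 2], 0.5)     # negative edge keeps |value|
  expect_equal(g$weights[1, 3], 0)
  expect_equal(g$weights[2, 3], 0)
  expect_true(all(diag(g$weights) == 0))
  # tau -> 0 limit keeps everything
  g0 <- threshold_graph(b, 1e-6)
  expect_equal(g0$weights, abs(b))
  # uniform sub-threshold matrix -> empty graph
  gall <- threshold_graph(edge_matrix(rep(0.1, 3), 3), 0.17)
  expect_true(all(gall$weights == 0))
  expect_false(weighted_metrics(gall)$valid)
})

test_that("degree check flags isolated nodes", {
  w4 <- matrix(1, 4, 4); diag(w4) <- 0
  dc <- degree_check(threshold_graph(w4, 0.5))
  expect_equal(dc$min_degree, 3)
  expect_true(dc$fully_connected)
  # path graph P5: min degree 1, passes
  p5 <- matrix(0, 5, 5)
  for (i in 1:4) p5[i, i + 1] <- p5[i + 1, i] <- 1
  expect_true(degree_check(threshold_graph(p5, 0.5))$fully_connected)
  # isolated node fails
  iso <- p5; iso[4, 5] <- iso[5, 4] <- 0
  expect_false(degree_check(threshold_graph(iso, 0.5))$fully_connected)
})

test_that("metrics match closed forms on canonical graphs", {
  w4 <- matrix(1, 4, 4); diag(w4) <- 0
  m <- weighted_metrics(threshold_graph(w4, 0.5))
  expect_equal(m$gamma, 1)
  expect_equal(m$lambda, 1)
  expect_equal(m$eglob, 1)
  # path P3, unit weights: E_glob = (1 + 1 + 0.5)/3
  p3 <- matrix(0, 3, 3)
  p3[1, 2] <- p3[2, 1] <- p3[2, 3] <- p3[3, 2] <- 1
  m3 <- weighted_metrics(threshold_graph(p3, 0.5))
  expect_equal(m3$eglob, 5 / 6)
  expect_equal(m3$lambda, 4 / 3)
})

test_that("metrics equal brute-force enumeration on random small graphs", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(4:8, 1)
    w <- random_connected_graph(n)
    g <- threshold_graph(w, 1e-6)
    m <- weighted_metrics(g)
    expect_equal(m$gamma_nodal, oracle_gamma_nodal(w), tolerance = 1e-12)
    expect_equal(m$lambda, oracle_lambda(w), tolerance = 1e-12)
    expect_equal(m$eglob, oracle_eglob(w), tolerance = 1e-12)
    expect_equal(as.numeric(m$eloc_nodal), oracle_eloc_nodal(w),
                 tolerance = 1e-12)
  }
  # cross-check path lengths against an independent library implementation
  w <- random_connected_graph(10)
  ig <- igraph::graph_from_adjacency_matrix(w, weighted = TRUE,
                                            mode = "undirected")
  expect_equal(nirsnet:::shortest_path_lengths(w),
               unname(igraph::distances(ig, weights = 1 / igraph::E(ig)$weight)),
               tolerance = 1e-12)
})

test_that("raising the threshold never adds edges and never raises E_glob", {
  set.seed(9)
  b <- random_edge_matrix(20, 0, 0.2)
  taus <- seq(0.01, 0.3, by = 0.05)
  prev_edges <- Inf; prev_eglob <- Inf
  for (tau in taus) {
    g <- threshold_graph(b, tau)
    ne <- sum(g$weights[upper.tri(g$weights)] > 0)
    expect_lte(ne, prev_edges)
    m <- weighted_metrics(g)
    if (isTRUE(m$valid)) {
      expect_lte(m$eglob, prev_eglob + 1e-12)
      prev_eglob <- m$eglob
    }
    prev_edges <- ne
  }
})

test_that("random references preserve degrees and weights, deterministically", {
  set.seed(10)
  w <- random_connected_graph(16, density = 0.3)
  g <- threshold_graph(w, 1e-6)
  rr <- random_reference(g, n = 8, seed = 6, keep_graphs = TRUE)
  for (wr in attr(rr, "graphs")) {
    expect_equal(rowSums(wr > 0), rowSums(w > 0))
    expect_equal(sort(wr[upper.tri(wr) & wr > 0]),
                 sort(w[upper.tri(w) & w > 0]))
  }
  rr2 <- random_reference(g, n = 8, seed = 6)
  attr(rr, "graphs") <- NULL
  expect_equal(rr, rr2)
  # ring lattice: rewiring lowers clustering on average
  n <- 20
  ring <- matrix(0, n, n)
  for (i in seq_len(n)) for (s in 1:2) {
    j <- ((i + s - 1) %% n) + 1
    ring[i, j] <- ring[j, i] <- 1
  }
  gr <- threshold_graph(ring, 0.5)
  m_ring <- weighted_metrics(gr)
  rrr <- random_reference(gr, n = 20, seed = 3)
  expect_lt(mean(rrr[, "gamma"]), m_ring$gamma)
})

test_that("normalization and small-world identity", {
  raw <- c(gamma = 0.4, eloc = 0.3, lambda = 2, eglob = 0.5)
  m_rand <- c(gamma = 0.2, eloc = 0.3, lambda = 2, eglob = 0.5)
  nm <- normalize_and_smallworld(raw, m_rand)
  expect_equal(unname(nm["gamma"]), 2)
  expect_equal(unname(nm["sigma"]), 2)   # gamma_norm 2 / lambda_norm 1
  # raw equal to reference -> everything 1
  nm1 <- normalize_and_smallworld(m_rand, m_rand)
  expect_true(all(abs(nm1 - 1) < 1e-12))
  # zero reference invalidates the metric
  m0 <- m_rand; m0["gamma"] <- 0
  expect_true(is.na(normalize_and_smallworld(raw, m0)["gamma"]))
})

test_that("AUC matches closed forms and a quadrature oracle", {
  grid <- threshold_grid()
  expect_equal(metric_auc(grid, rep(1, length(grid))), 0.16)
  ramp <- seq(0, 1, length.out = length(grid))
  expect_equal(metric_auc(grid, ramp), 0.08)
  set.seed(11)
  y <- runif(length(grid))
  # independent oracle: sum of trapezoid areas computed pairwise
  oracle <- 0
  for (i in seq_len(length(grid) - 1))
    oracle <- oracle + (grid[i + 1] - grid[i]) * (y[i] + y[i + 1]) / 2
  expect_equal(metric_auc(grid, y), oracle, tolerance = 1e-12)
  expect_true(is.na(metric_auc(grid, c(1, rep(NA, length(grid) - 1)))))
})

test_that("sparsity range validation truncates at failing thresholds", {
  set.seed(12)
  mats <- lapply(1:2, function(i) modular_matrix(n = 30, seed = i))
  hemi <- rep(c("L", "R"), each = 15)
  np <- network_profiles(mats, hemi, grid = threshold_grid(0.01, 0.09, 0.02),
                         n_rand = 10, seed = 13)
  sr <- sparsity_range(np$profiles)
  expect_true(all(sr$pass))
  expect_equal(sr$range, c(0.01, 0.09))
  # force a failure mid-grid and check truncation
  prof <- np$profiles
  prof$min_degree[prof$tau == 0.05] <- 0
  sr2 <- sparsity_range(prof)
  expect_equal(sr2$range[2], 0.03)
  # all-empty profiles error
  prof$min_degree <- 0
  expect_error(sparsity_range(prof), "threshold")
})
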