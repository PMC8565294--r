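test_that("closed-form metric values on canonical graphs", {
  k4 <- complete_graph(4)
  expect_equal(clustering_coefficients(k4)$Cp, 1)
  expect_equal(characteristic_path_length(k4)$Lp, 1)
  expect_equal(global_efficiency(k4)$Eglob, 1)
  expect_equal(unname(global_efficiency(k4)$per_node), rep(1, 4))
  expect_equal(local_efficiency(k4)$Eloc, 1)
  expect_equal(betweenness(k4), rep(0, 4))

  star <- star_graph(3)
  expect_equal(clustering_coefficients(star)$Cp, 0)
  expect_equal(characteristic_path_length(star)$Lp, 1.5)
  expect_equal(global_efficiency(star)$Eglob, 0.75)
  expect_equal(global_efficiency(star)$per_node[1], 1)
  expect_equal(global_efficiency(star)$per_node[2], 2 / 3)
  expect_equal(betweenness(star), c(3, 0, 0, 0))
  expect_equal(local_efficiency(star)$Eloc, 0)

  pg <- path_graph(4)
  D <- shortest_path_lengths(pg)
  expect_equal(D[1, 4], 3)
  expect_equal(D[1, 3], 2)
  expect_equal(D[2, 4], 2)
  expect_equal(characteristic_path_length(pg)$Lp, 10 / 6)
  expect_equal(betweenness(pg), c(0, 2, 2, 0))

  # ring lattice N=20, k=4: closed form Cp = 3(k-2)/(4(k-1)) = 0.5
  rl <- ring_lattice(20, 4)
  expect_equal(clustering_coefficients(rl)$Cp, 0.5)
  expect_equal(unname(nodal_degree(rl)), rep(4L, 20))
})

test_that("disconnected graphs are handled: Inf distances, flags, efficiency", {
  two_triangles <- graph_from_edges(6, list(c(1, 2), c(2, 3), c(1, 3),
                                            c(4, 5), c(5, 6), c(4, 6)))
  D <- shortest_path_lengths(two_triangles)
  expect_true(all(is.infinite(D[1:3, 4:6])))
  lp <- characteristic_path_length(two_triangles)
  expect_true(lp$disconnected)
  expect_equal(lp$Lp, 1)  # mean over finite pairs only
  # efficiency treats unreachable pairs as zero contribution
  expect_equal(global_efficiency(two_triangles)$Eglob, 12 / 30)

  empty <- binary_graph(matrix(0L, 4, 4))
  expect_equal(global_efficiency(empty)$Eglob, 0)
  expect_error(characteristic_path_length(empty), "no edges")
  # isolated node has NEg = 0
  pend <- graph_from_edges(4, list(c(1, 2), c(2, 3), c(1, 3)))
  expect_equal(global_efficiency(pend)$per_node[4], 0)
})

test_that("local efficiency matches brute force on a triangle with pendant", {
  g <- graph_from_edges(4, list(c(1, 2), c(2, 3), c(1, 3), c(3, 4)))
  expect_equal(local_efficiency(g)$per_node, oracle_local_efficiency(g$adjacency))
  expect_equal(local_efficiency(g)$per_node[4], 0)  # pendant, degree 1
})

test_that("all eight metrics match brute-force oracles on random graphs", {
  set.seed(101)
  for (rep in 1:60) {
    n <- sample(4:12, 1)
    g <- random_graph(n, p = runif(1, 0.15, 0.7))
    adj <- g$adjacency
    expect_equal(unname(nodal_degree(g)), unname(colSums(adj)))
    expect_equal(clustering_coefficients(g)$per_node, oracle_clustering(adj))
    D <- shortest_path_lengths(g)
    expect_equal(D, oracle_distances(adj))
    off <- D[row(D) != col(D)]
    if (any(is.finite(off)))
      expect_equal(characteristic_path_length(g)$Lp,
                   mean(off[is.finite(off)]))
    eff <- global_efficiency(g)
    oeff <- oracle_global_efficiency(adj)
    expect_equal(eff$Eglob, oeff$Eglob)
    expect_equal(unname(eff$per_node), unname(oeff$per_node))
    expect_equal(local_efficiency(g)$per_node, oracle_local_efficiency(adj))
    expect_equal(betweenness(g), oracle_betweenness(adj), tolerance = 1e-9)
  }
})

test_that("metrics agree with igraph on a larger random graph", {
  skip_if_not_installed("igraph")
  set.seed(77)
  g <- random_graph(40, 0.15)
  ig <- igraph::graph_from_adjacency_matrix(g$adjacency, mode = "undirected")
  expect_equal(betweenness(g), unname(igraph::betweenness(ig)),
               tolerance = 1e-9)
  tr <- igraph::transitivity(ig, type = "localundirected", isolates = "zero")
  expect_equal(clustering_coefficients(g)$per_node, tr, tolerance = 1e-12)
  expect_equal(global_efficiency(g)$Eglob,
               igraph::global_efficiency(ig), tolerance = 1e-12)
  # neighbor-induced-subgraph local efficiency via igraph primitives
  ig_neloc <- sapply(seq_len(40), function(i) {
    nb <- which(g$adjacency[i, ] == 1)
    if (length(nb) < 2) return(0)
    igraph::global_efficiency(igraph::induced_subgraph(ig, nb))
  })
  expect_equal(local_efficiency(g)$per_node, ig_neloc, tolerance = 1e-12)
  expect_equal(shortest_path_lengths(g),
               unname(igraph::distances(ig)), tolerance = 1e-12)
})

test_that("conservation and bound invariants hold on random graphs", {
  set.seed(202)
  for (rep in 1:20) {
    n <- sample(5:12, 1)
    g <- random_graph(n, 0.4)
    expect_identical(sum(nodal_degree(g)), 2L * g$n_edges)
    expect_true(all(clustering_coefficients(g)$per_node >= 0 &
                      clustering_coefficients(g)$per_node <= 1))
    expect_true(all(global_efficiency(g)$per_node >= 0 &
                      global_efficiency(g)$per_node <= 1))
    expect_true(all(local_efficiency(g)$per_node >= 0 &
                      local_efficiency(g)$per_node <= 1))
    expect_true(all(betweenness(g) <= (n - 1) * (n - 2) / 2 + 1e-9))
  }
  # BC attains its bound only at a star center
  st <- star_graph(5)
  expect_equal(betweenness(st)[1], (6 - 1) * (6 - 2) / 2)
})

test_that("Eglob and nodal degree are non-decreasing in sparsity", {
  set.seed(55)
  fc <- compute_fc_matrix(matrix(rnorm(100 * 20), 100, 20))
  grid <- threshold_grid()
  eg <- numeric(0)
  prev_dc <- NULL
  for (s in grid) {
    g <- binarize_at_sparsity(fc, s)
    eg <- c(eg, global_efficiency(g)$Eglob)
    dc <- nodal_degree(g)
    if (!is.null(prev_dc)) expect_true(all(dc >= prev_dc))
    prev_dc <- dc
  }
  expect_true(all(diff(eg) >= 0))
})

test_that("null ensembles preserve the degree sequence exactly", {
  set.seed(31)
  g <- random_graph(20, 0.3)
  ens <- generate_null_ensemble(g, n_nulls = 25, seed = 5)
  deg <- nodal_degree(g)
  for (h in ens$graphs) {
    expect_identical(unname(nodal_degree(h)), unname(deg))
    expect_true(all(diag(h$adjacency) == 0))
  }
  # rewiring actually changed something
  expect_true(any(vapply(ens$graphs, function(h)
    !identical(h$adjacency, g$adjacency), logical(1))))
  # reproducible under the same seed
  ens2 <- generate_null_ensemble(g, n_nulls = 25, seed = 5)
  expect_identical(lapply(ens$graphs, `[[`, "adjacency"),
                   lapply(ens2$graphs, `[[`, "adjacency"))
  # graphs with no two independent edges cannot be rewired
  expect_error(generate_null_ensemble(star_graph(3), n_nulls = 2),
               "independent edges")
})

test_that("small-world normalization behaves as expected", {
  # identity ensemble: gamma = lambda = sigma = 1
  set.seed(61)
  g <- random_graph(15, 0.3)
  ens <- structure(list(graphs = replicate(10, g, simplify = FALSE),
                        n_nulls = 10, n_swap_attempts = 0, seed = 1),
                   class = "null_ensemble")
  sw <- small_world_metrics(g, ens)
  expect_equal(sw$gamma, 1)
  expect_equal(sw$lambda, 1)
  expect_equal(sw$sigma, 1)

  # lattice clustering exceeds its randomized nulls
  rl <- ring_lattice(20, 4)
  ens_rl <- generate_null_ensemble(rl, n_nulls = 100, seed = 9)
  null_cp <- vapply(ens_rl$graphs, function(h)
    clustering_coefficients(h)$Cp, numeric(1))
  expect_lt(mean(null_cp), 0.5)
  sw_rl <- small_world_metrics(rl, ens_rl)
  expect_gt(sw_rl$gamma, 1)
  expect_equal(sw_rl$sigma, sw_rl$gamma / sw_rl$lambda)

  # an ER-like graph is its own null: gamma near 1
  er <- random_graph(60, 0.15, seed = 71)
  sw_er <- small_world_metrics(er, generate_null_ensemble(er, 100, seed = 3))
  expect_lt(abs(sw_er$gamma - 1), 0.3)
})

test_that("AUC summarization uses the trapezoidal rule", {
  grid <- threshold_grid()
  expect_equal(auc_over_grid(rep(2, 8), grid), 0.70)
  expect_equal(auc_over_grid(as.numeric(grid), grid), (0.40^2 - 0.05^2) / 2)
  expect_equal(auc_over_grid(c(1, 3), c(0.1, 0.2)), 0.2)
  expect_error(auc_over_grid(1, 0.1), "at least 2")
  expect_error(auc_over_grid(c(1, 2), c(0.2, 0.1)), "increasing")
})

test_that("subject profiles assemble all metrics with correct AUCs", {
  set.seed(91)
  # denser band: at very sparse thresholds on a tiny graph the rewired
  # nulls can be triangle-free, which (correctly) errors the gamma
  # normalization; profile assembly is tested away from that degeneracy
  grid <- threshold_grid(0.15, 0.40, 0.05)
  fc <- compute_fc_matrix(matrix(rnorm(120 * 12), 120, 12))
  p <- profile_subject(fc, grid, n_nulls = 10, seed = 2)
  expect_named(p$auc$global, c("Cp", "Lp", "Eglob", "Eloc",
                               "gamma", "lambda", "sigma"))
  expect_identical(dim(p$auc$nodal), c(12L, 4L))
  expect_identical(colnames(p$auc$nodal), c("DC", "BC", "NEg", "NEloc"))
  # AUC consistency with the per-grid values
  expect_equal(p$auc$global[["Cp"]],
               auc_over_grid(p$global$Cp, grid))
  expect_equal(unname(p$auc$nodal[3, "DC"]),
               auc_over_grid(p$nodal$DC[3, ], grid))
  # sigma = gamma / lambda at every grid point
  expect_equal(p$global$sigma, p$global$gamma / p$global$lambda)
  # per-grid values match direct metric calls
  g3 <- binarize_at_sparsity(fc, as.numeric(grid)[3])
  expect_equal(p$global$Cp[3], clustering_coefficients(g3)$Cp)
  expect_equal(p$nodal$NEloc[, 3], local_efficiency(g3)$per_node)
  # deterministic under the same seed
  p2 <- profile_subject(fc, grid, n_nulls = 10, seed = 2)
  expect_identical(p$auc, p2$auc)
  # Eglob non-decreasing across the grid (nested edge sets)
  expect_true(all(diff(p$global$Eglob) >= 0))
})
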