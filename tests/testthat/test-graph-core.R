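test_that("threshold_sparsity keeps exactly round(s * n(n-1)/2) strongest edges", {
  # printed edge count at the reference scale: 140 nodes, 20% sparsity
  w <- random_weight_matrix(140, seed = 7)
  g <- threshold_sparsity(w, 0.20)
  expect_identical(g$n_edges, 1946L)
  expect_equal(g$sparsity, 1946 / 9730)

  # 4 nodes, distinct weights: the top-weighted pairs form the edge set
  w4 <- matrix(0, 4, 4)
  w4[upper.tri(w4)] <- c(6, 5, 4, 3, 2, 1) # pairs (1,2),(1,3),(2,3),(1,4),(2,4),(3,4)
  w4 <- w4 + t(w4)
  diag(w4) <- 1
  g4 <- threshold_sparsity(connectivity_matrix(w4), 0.5)
  ed <- graph_edges(g4)
  expect_identical(g4$n_edges, 3L)
  expect_setequal(paste(ed$i, ed$j), c("1 2", "1 3", "2 3"))

  # sparsity invariant holds exactly, and matched sparsity means matched counts
  for (s in c(0.06, 0.17, 0.33)) {
    ga <- threshold_sparsity(random_weight_matrix(30, seed = 1), s)
    gb <- threshold_sparsity(random_weight_matrix(30, seed = 2), s)
    expect_identical(ga$n_edges, gb$n_edges)
    expect_equal(ga$sparsity, ga$n_edges / (30 * 29 / 2))
  }
  expect_error(threshold_sparsity(w, 1e-6), "no edges")
  expect_error(threshold_sparsity(w, 0.999999), "all pairs")
})

test_that("weight ties at the threshold break by lexicographic pair order", {
  w <- matrix(0.5, 4, 4)
  diag(w) <- 1
  g <- threshold_sparsity(connectivity_matrix(w), 0.5) # 3 of 6 equal weights
  ed <- graph_edges(g)
  expect_identical(paste(ed$i, ed$j), c("1 2", "1 3", "1 4"))
})

test_that("closed-form metric values are exact", {
  complete5 <- binary_graph(matrix(1, 5, 5) - diag(5))
  expect_identical(global_efficiency(complete5), 1)
  expect_identical(mean_clustering(complete5), 1)

  edgeless <- binary_graph(matrix(0, 4, 4))
  expect_identical(global_efficiency(edgeless), 0)
  expect_identical(node_degree(edgeless), setNames(rep(0L, 4), paste0("roi_", 1:4)))

  path3 <- binary_graph(matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3))
  expect_equal(global_efficiency(path3), 5 / 6)

  triangle <- binary_graph(matrix(1, 3, 3) - diag(3))
  expect_identical(unname(clustering_coef(triangle)), rep(1, 3))

  c4 <- binary_graph(rbind(c(0, 1, 0, 1), c(1, 0, 1, 0), c(0, 1, 0, 1), c(1, 0, 1, 0)))
  expect_identical(unname(clustering_coef(c4)), rep(0, 4))

  star <- binary_graph(rbind(c(0, 1, 1, 1), c(1, 0, 0, 0), c(1, 0, 0, 0), c(1, 0, 0, 0)))
  expect_identical(unname(node_degree(star)), c(3L, 1L, 1L, 1L))

  # modularity: single module gives 0; two disconnected triangles give 1/2
  two_tri <- matrix(0, 6, 6)
  two_tri[1:3, 1:3] <- 1
  two_tri[4:6, 4:6] <- 1
  diag(two_tri) <- 0
  g2t <- binary_graph(two_tri)
  expect_equal(modularity_q(g2t, rep(1L, 6)), 0)
  expect_equal(modularity_q(g2t, c(1L, 1L, 1L, 2L, 2L, 2L)), 0.5)
  # invariant under module relabeling
  expect_equal(modularity_q(g2t, c(9L, 9L, 9L, 4L, 4L, 4L)), 0.5)
})

test_that("metrics match brute-force oracles on random small graphs", {
  for (seed in 1:25) {
    n <- withr::with_seed(seed, sample(4:8, 1))
    g <- random_graph(n, p = 0.45, seed = seed)
    expect_equal(global_efficiency(g), bf_efficiency(g$adj))
    expect_equal(unname(clustering_coef(g)), bf_clustering(g$adj))
    expect_identical(unname(node_degree(g)), as.integer(rowSums(g$adj)))
    if (g$n_edges >= 1) {
      mem <- withr::with_seed(seed + 100, sample(1:3, n, replace = TRUE))
      expect_equal(modularity_q(g, mem), unname(bf_modularity(g$adj, mem)))
    }
  }
})

test_that("metrics agree with igraph on larger random graphs", {
  skip_if_not_installed("igraph")
  for (seed in c(3, 11)) {
    g <- random_graph(30, p = 0.2, seed = seed)
    ig <- igraph::graph_from_adjacency_matrix(g$adj, mode = "undirected")
    expect_equal(global_efficiency(g), igraph::global_efficiency(ig))
    expect_equal(
      unname(clustering_coef(g)),
      unname(ifelse(is.nan(igraph::transitivity(ig, type = "local")), 0,
                    igraph::transitivity(ig, type = "local")))
    )
    mem <- withr::with_seed(seed, sample(1:4, 30, replace = TRUE))
    expect_equal(modularity_q(g, mem), igraph::modularity(ig, mem))
  }
})

test_that("louvain recovers planted structure and reports exact Q", {
  # two disconnected 5-cliques: exactly the two components, Q = 1/2
  adj <- matrix(0, 10, 10)
  adj[1:5, 1:5] <- 1
  adj[6:10, 6:10] <- 1
  diag(adj) <- 0
  part <- louvain(binary_graph(adj), seed = 1)
  expect_identical(part$n_modules, 2L)
  expect_equal(part$q, 0.5)
  expect_equal(adjusted_rand(part$membership, rep(1:2, each = 5)), 1)
  expect_identical(part$q, modularity_q(binary_graph(adj), part$membership))

  # complete graph collapses to one module with Q = 0
  k6 <- binary_graph(matrix(1, 6, 6) - diag(6))
  p6 <- louvain(k6, seed = 1)
  expect_identical(p6$n_modules, 1L)
  expect_equal(p6$q, 0)

  # planted 4-block stochastic graph: exact block recovery
  blocks <- rep(1:4, each = 15)
  adj <- withr::with_seed(42, {
    p <- ifelse(outer(blocks, blocks, `==`), 0.9, 0.05)
    a <- matrix(0L, 60, 60)
    up <- upper.tri(a)
    a[up] <- as.integer(runif(sum(up)) < p[up])
    a[lower.tri(a)] <- t(a)[lower.tri(a)]
    a
  })
  part4 <- louvain(binary_graph(adj), seed = 3, restarts = 10)
  expect_equal(adjusted_rand(part4$membership, blocks), 1)

  # determinism: same seed, same partition
  part4b <- louvain(binary_graph(adj), seed = 3, restarts = 10)
  expect_identical(part4, part4b)
})

test_that("louvain finds partitions at least as good as igraph's", {
  skip_if_not_installed("igraph")
  for (seed in c(5, 9)) {
    g <- random_graph(40, p = 0.15, seed = seed)
    ig <- igraph::graph_from_adjacency_matrix(g$adj, mode = "undirected")
    q_ig <- withr::with_seed(1, igraph::modularity(igraph::cluster_louvain(ig)))
    q_own <- louvain(g, seed = 1, restarts = 10)$q
    expect_gte(q_own, q_ig - 0.02)
  }
})

test_that("random references reproduce Erdos-Renyi expectations", {
  ref <- random_reference(50, 245, reps = 60, seed = 11)
  # G(n, m) clustering concentrates on the density m / (n(n-1)/2) = 0.2
  p <- 245 / (50 * 49 / 2)
  expect_lt(abs(ref$clustering - p), 3 * 0.02)
  expect_gt(ref$efficiency, 0.5)

  # complete-graph edge count forces efficiency and clustering of 1
  ref_full <- random_reference(6, 15, reps = 3, seed = 1)
  expect_identical(ref_full$efficiency, 1)
  expect_identical(ref_full$clustering, 1)

  # reproducible under a fixed seed
  expect_identical(random_reference(20, 40, reps = 5, seed = 9),
                   random_reference(20, 40, reps = 5, seed = 9))
  expect_error(random_reference(5, 11), "infeasible")
})

test_that("degree-preserving rewiring keeps the degree sequence", {
  g <- random_graph(25, p = 0.25, seed = 4)
  r <- netshift:::rewire_graph(g, seed = 2)
  expect_identical(sort(node_degree(r)), sort(node_degree(g)))
  expect_identical(r$n_edges, g$n_edges)
  expect_false(identical(r$adj, g$adj))
})

test_that("sparsity_sweep matches pointwise calls and efficiency grows with sparsity", {
  w <- random_weight_matrix(40, seed = 21)
  grid <- seq(0.06, 0.40, by = 0.01)
  expect_identical(nrow(sparsity_sweep(w, metrics = "efficiency", grid = grid)), 35L)

  sub_grid <- c(0.10, 0.20, 0.30)
  sw <- sparsity_sweep(w, metrics = c("efficiency", "clustering"), grid = sub_grid)
  for (i in seq_along(sub_grid)) {
    g <- threshold_sparsity(w, sub_grid[i])
    expect_equal(sw$value[sw$metric == "efficiency"][i], global_efficiency(g))
    expect_equal(sw$value[sw$metric == "clustering"][i], mean_clustering(g))
  }
  eff <- sw$value[sw$metric == "efficiency"]
  expect_true(all(diff(eff) > 0))
})

test_that("a planted modular graph is small-world relative to its random reference", {
  w <- gen_modular_matrix(modular_spec(60, rep(15, 4), 0.6, 0.2, 0.05, seed = 5))
  g <- threshold_sparsity(w, 0.2)
  ref <- random_reference(g$n_nodes, g$n_edges, reps = 30, seed = 8)
  expect_gt(mean_clustering(g), ref$clustering)
  expect_lt(global_efficiency(g), ref$efficiency)
})

test_that("noiseless fully-modular matrices yield the planted partition and closed-form Q", {
  # mu_out = 0, sigma = 0: within-block weights 1, between 0; threshold at a
  # sparsity keeping exactly the within-block pairs -> k disconnected cliques
  k <- 4
  size <- 6
  w <- gen_modular_matrix(modular_spec(k * size, rep(size, k), 1, 0, 0, seed = 1))
  n_pairs <- (k * size) * (k * size - 1) / 2
  m_within <- k * size * (size - 1) / 2
  g <- threshold_sparsity(w, m_within / n_pairs)
  expect_identical(g$n_edges, as.integer(m_within))
  part <- louvain(g, seed = 1)
  expect_equal(adjusted_rand(part$membership, attr(w, "modules")), 1)
  # Q for k equal disconnected cliques: 1 - 1/k
  expect_equal(part$q, 1 - 1 / k)
})
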