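test_that("clustering and transitivity on canonical graphs", {
  k4 <- complete_graph(4)
  expect_equal(unname(clustering_coefficient(k4)), rep(1, 4))
  expect_equal(graph_transitivity(k4), 1)

  star <- adj_from_edges(4, list(c(1, 2), c(1, 3), c(1, 4)))
  expect_equal(unname(clustering_coefficient(star)), rep(0, 4))
  expect_equal(graph_transitivity(star), 0) # tree

  tri_pendant <- adj_from_edges(4, list(c(1, 2), c(2, 3), c(1, 3), c(3, 4)))
  expect_equal(
    unname(clustering_coefficient(tri_pendant)),
    oracle_clustering(unclass(tri_pendant))
  )
})

test_that("path length and efficiency on canonical graphs", {
  expect_equal(characteristic_path_length(complete_graph(5)), 1)
  expect_equal(global_efficiency(complete_graph(5)), 1)

  p3 <- path_graph(3)
  expect_equal(characteristic_path_length(p3), 4 / 3)
  expect_equal(global_efficiency(p3), 5 / 6)

  two_edges <- adj_from_edges(4, list(c(1, 2), c(3, 4)))
  expect_equal(characteristic_path_length(two_edges), 1) # reachable pairs only

  empty <- adj_from_edges(4, list())
  expect_equal(global_efficiency(empty), 0)
  expect_equal(characteristic_path_length(empty), 0)
  expect_equal(unname(local_efficiency(empty)), rep(0, 4))
})

test_that("betweenness on canonical graphs", {
  expect_equal(unname(betweenness_centrality(complete_graph(6))), rep(0, 6))
  p3 <- path_graph(3)
  expect_equal(unname(betweenness_centrality(p3)), c(0, 1, 0))
})

test_that("eigenvector centrality: regular graphs are uniform, star ratio
           is sqrt(leaves), minor components score zero", {
  ring <- adj_from_edges(5, list(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(5, 1)))
  ec <- eigenvector_centrality(ring)
  expect_equal(unname(ec), rep(1, 5), tolerance = 1e-8)

  star <- adj_from_edges(5, list(c(1, 2), c(1, 3), c(1, 4), c(1, 5)))
  ec <- eigenvector_centrality(star)
  expect_equal(ec[["R1"]] / ec[["R2"]], 2, tolerance = 1e-8) # sqrt(4)
  expect_equal(max(ec), 1)

  # triangle plus a detached edge: minor component gets zeros
  g <- adj_from_edges(5, list(c(1, 2), c(2, 3), c(1, 3), c(4, 5)))
  ec <- eigenvector_centrality(g)
  expect_equal(unname(ec[4:5]), c(0, 0))
  expect_equal(eigenvector_centrality(adj_from_edges(3, list())),
    c(R1 = 0, R2 = 0, R3 = 0)
  )
})

test_that("module detection recovers planted cliques with Q = 0.5 and is
           deterministic under a fixed seed", {
  two_k5 <- adj_from_edges(10, c(
    combn(1:5, 2, simplify = FALSE),
    combn(6:10, 2, simplify = FALSE)
  ))
  m <- detect_modules(two_k5, seed = 3)
  expect_equal(length(unique(m)), 2)
  expect_equal(length(unique(m[1:5])), 1)
  expect_equal(length(unique(m[6:10])), 1)
  expect_equal(attr(m, "modularity"), 0.5)
  expect_equal(graph_modularity(two_k5, m), 0.5)

  m2 <- detect_modules(two_k5, seed = 3)
  expect_identical(m, m2)

  # complete graph: one module, Q = 0
  expect_equal(graph_modularity(complete_graph(6), rep(1, 6)), 0)
})

test_that("participation coefficient and within-module z-score follow their
           defining formulas", {
  # node 1 with degree 4 split 2/2 across two modules
  g <- adj_from_edges(5, list(c(1, 2), c(1, 3), c(1, 4), c(1, 5)))
  membership <- c(1, 1, 1, 2, 2)
  p <- participation_coefficient(g, membership)
  expect_equal(p[["R1"]], 0.5) # 1 - (0.5^2 + 0.5^2)

  # all edges inside own module -> P = 0; isolated node -> P = 0
  clique <- adj_from_edges(4, combn(1:3, 2, simplify = FALSE))
  expect_equal(unname(participation_coefficient(clique, c(1, 1, 1, 2))),
    rep(0, 4)
  )

  z <- within_module_zscore(g, membership)
  for (mod in unique(membership)) {
    expect_equal(mean(z[membership == mod]), 0, tolerance = 1e-12)
  }
  # singleton-SD module: all zeros rather than NaN
  expect_true(all(is.finite(z)))
  expect_equal(unname(within_module_zscore(clique, c(1, 1, 1, 2))[4]), 0)
})

test_that("metrics agree with brute-force oracles on random graphs", {
  for (seed in 1:6) {
    g <- random_adj(10, p = 0.35, seed = seed)
    a <- unclass(g)
    expect_equal(unname(clustering_coefficient(g)), oracle_clustering(a),
      tolerance = 1e-12
    )
    expect_equal(graph_transitivity(g), oracle_transitivity(a),
      tolerance = 1e-12
    )
    expect_equal(characteristic_path_length(g), oracle_charpath(a),
      tolerance = 1e-12
    )
    expect_equal(global_efficiency(g), oracle_global_efficiency(a),
      tolerance = 1e-12
    )
    expect_equal(unname(local_efficiency(g)), oracle_local_efficiency(a),
      tolerance = 1e-12
    )
    expect_equal(unname(betweenness_centrality(g)), oracle_betweenness(a),
      tolerance = 1e-9
    )
  }
})

test_that("every metric is equivariant under node relabelling", {
  withr::with_seed(31, {
    g <- random_adj(9, p = 0.4, seed = 32)
    perm <- sample(9)
    gp <- unclass(g)[perm, perm]
    class(gp) <- class(g)
    expect_equal(unname(clustering_coefficient(gp)),
      unname(clustering_coefficient(g))[perm]
    )
    expect_equal(unname(betweenness_centrality(gp)),
      unname(betweenness_centrality(g))[perm],
      tolerance = 1e-12
    )
    expect_equal(unname(local_efficiency(gp)),
      unname(local_efficiency(g))[perm]
    )
    expect_equal(unname(eigenvector_centrality(gp)),
      unname(eigenvector_centrality(g))[perm],
      tolerance = 1e-6
    )
    expect_equal(graph_transitivity(gp), graph_transitivity(g))
    expect_equal(characteristic_path_length(gp), characteristic_path_length(g))
  })
})

test_that("adding an edge never decreases global efficiency or any degree", {
  withr::with_seed(33, {
    g <- unclass(random_adj(8, p = 0.3, seed = 34))
    absent <- which(upper.tri(g) & g == 0, arr.ind = TRUE)
    e0 <- global_efficiency(structure(g, class = class(complete_graph(2))))
    d0 <- rowSums(g)
    for (row in sample(nrow(absent), min(5, nrow(absent)))) {
      g2 <- g
      g2[absent[row, 1], absent[row, 2]] <- 1L
      g2[absent[row, 2], absent[row, 1]] <- 1L
      g2 <- structure(g2, class = class(complete_graph(2)))
      expect_gte(global_efficiency(g2), e0)
      expect_true(all(rowSums(unclass(g2)) >= d0))
    }
  })
})

test_that("nodal and global metric tables have the documented shape", {
  g <- random_adj(7, p = 0.5, seed = 35)
  nm <- nodal_metrics(g, seed = 1)
  expect_equal(dim(nm), c(7, 8))
  expect_true(all(nm$clustering >= 0 & nm$clustering <= 1))
  expect_true(all(nm$local_efficiency >= 0 & nm$local_efficiency <= 1))
  expect_true(all(nm$participation >= 0 & nm$participation <= 1))
  expect_true(all(nm$betweenness >= 0))
  expect_true(all(nm$eigenvector >= 0 & nm$eigenvector <= 1))
  gm <- global_metrics(g, seed = 1)
  expect_equal(dim(gm), c(1, 5))
  expect_true(gm$transitivity >= 0 && gm$transitivity <= 1)
  expect_true(gm$global_efficiency >= 0 && gm$global_efficiency <= 1)
  expect_true(gm$modularity >= -0.5 && gm$modularity <= 1)
})
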