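test_that("generators satisfy their edge-count and structural identities", {
  # BA with m = 1 is a tree: n - 1 edges, connected, triangle-free
  tree <- generate_ba(50, 1, seed = 3)
  expect_equal(igraph::ecount(tree), 49)
  expect_true(igraph::is_connected(tree))
  expect_equal(network_stats(tree)$interconnectedness, 0)

  # BA with n = m + 1 is forced to the complete graph
  expect_setequal(edge_set(generate_ba(3, 2, seed = 1)),
                  edge_set(graph_from_pairs(3, c(1, 2, 1, 3, 2, 3))))

  # BA edge count is deterministic: choose(m,2) + (n-m)m
  for (s in 1:10) {
    expect_equal(igraph::ecount(generate_ba(50, 2, seed = s)), 1 + 48 * 2)
  }
  # so mean degree 2*97/50 = 3.88 ~ 2m(1 - m/n)
  expect_equal(mean(igraph::degree(generate_ba(50, 2, seed = 1))), 3.88)

  # Watts preserves the lattice edge count under any rewiring rate
  for (beta in c(0, 0.3, 1)) {
    expect_equal(igraph::ecount(generate_watts(50, 4, beta, seed = 2)), 100)
  }

  # ER extremes
  full <- generate_er(50, 1)
  expect_equal(igraph::ecount(full), choose(50, 2))
  expect_true(all(node_clustering(full) == 1))
  expect_true(all(node_triplets(full) == choose(49, 2)))
  expect_equal(igraph::ecount(generate_er(50, 0)), 0)

  # handshake and simplicity across all three generators
  for (g in list(tree, generate_watts(30, 6, 0.5, seed = 4),
                 generate_er(30, 0.2, seed = 5))) {
    expect_equal(sum(igraph::degree(g)), 2 * igraph::ecount(g))
    expect_false(igraph::any_loop(g))
    expect_false(igraph::any_multiple(g))
  }
})

test_that("generator parameter validation rejects bad input", {
  expect_error(generate_ba(5, 0), "m >= 1")
  expect_error(generate_ba(3, 3), "n >= m")
  expect_error(generate_watts(50, 3, 0.1), "even k")
  expect_error(generate_watts(50, 4, 1.5), "probability")
  expect_error(generate_er(50, -0.1), "probability")
})

test_that("seeded generators are bit-reproducible", {
  expect_identical(edge_set(generate_ba(40, 3, seed = 11)),
                   edge_set(generate_ba(40, 3, seed = 11)))
  expect_identical(edge_set(generate_watts(40, 6, 0.4, seed = 11)),
                   edge_set(generate_watts(40, 6, 0.4, seed = 11)))
  expect_identical(edge_set(generate_er(40, 0.15, seed = 11)),
                   edge_set(generate_er(40, 0.15, seed = 11)))
  expect_false(identical(edge_set(generate_er(40, 0.15, seed = 11)),
                         edge_set(generate_er(40, 0.15, seed = 12))))
})

test_that("ER edge counts match the binomial expectation over seeds", {
  counts <- vapply(1:200, function(s) {
    igraph::ecount(generate_er(50, 0.1, seed = s))
  }, numeric(1))
  # mean of 200 Bin(1225, 0.1) draws; 4 sigma of the sample mean
  se <- sqrt(1225 * 0.1 * 0.9 / 200)
  expect_lt(abs(mean(counts) - 122.5), 4 * se)
})

test_that("watts beta = 0 reproduces the regular-lattice clustering", {
  ring4 <- generate_watts(50, 4, 0)
  # on the k = 4 ring each node's neighbourhood has 3 of 6 pairs linked
  expect_true(all(node_clustering(ring4) == 0.5))
  # k = 2 is the cycle: triangle-free
  expect_equal(network_stats(generate_watts(50, 2, 0))$interconnectedness, 0)
})

test_that("full rewiring approaches random-graph clustering", {
  # beta = 1 destroys the lattice structure; mean clustering should fall
  # to the random-graph level k/n rather than stay near 0.5
  cl <- vapply(1:30, function(s) {
    network_stats(generate_watts(50, 4, 1, seed = s))$mean_clustering
  }, numeric(1))
  er <- vapply(1:30, function(s) {
    network_stats(generate_er(50, 4 / 49, seed = s))$mean_clustering
  }, numeric(1))
  expect_lt(mean(cl), 0.25)
  expect_lt(abs(mean(cl) - mean(er)), 0.1)
})

test_that("radius-2 closure links exactly the distance <= 2 pairs", {
  # C5 -> K5, star -> complete
  expect_setequal(edge_set(radius2_closure(generate_watts(5, 2, 0))),
                  edge_set(generate_er(5, 1)))
  star <- graph_from_pairs(6, c(1, 2, 1, 3, 1, 4, 1, 5, 1, 6))
  expect_setequal(edge_set(radius2_closure(star)), edge_set(generate_er(6, 1)))
  # path a-b-c-d: ad stays absent
  p4 <- graph_from_pairs(4, c(1, 2, 2, 3, 3, 4))
  expect_setequal(edge_set(radius2_closure(p4)),
                  c("1 2", "1 3", "2 3", "2 4", "3 4"))
  # general BFS oracle + idempotence at diameter <= 2
  g <- generate_er(30, 0.1, seed = 9)
  r2 <- radius2_closure(g)
  d <- igraph::distances(g)
  want <- sort(apply(which(d <= 2 & upper.tri(d), arr.ind = TRUE), 1,
                     function(rc) paste(min(rc), max(rc))))
  expect_setequal(edge_set(r2), want)
  if (max(igraph::distances(r2)) <= 2) {
    expect_setequal(edge_set(radius2_closure(r2)), edge_set(r2))
  }
})

test_that("triplet counts match exhaustive enumeration", {
  k4 <- generate_er(4, 1)
  expect_equal(node_triplets(k4), rep(3L, 4))
  star <- graph_from_pairs(5, c(1, 2, 1, 3, 1, 4, 1, 5))
  expect_equal(node_triplets(star, 1), 0L)
  g <- generate_er(10, 0.4, seed = 21)
  expect_equal(node_triplets(g),
               vapply(1:10, function(i) ref_node_triplets(g, i), integer(1)))
  expect_error(node_triplets(g, 11), "out of range")
})

test_that("clustering is triplets over neighbour pairs with guarded domain", {
  expect_equal(node_clustering(generate_er(4, 1)), rep(1, 4))
  star <- graph_from_pairs(5, c(1, 2, 1, 3, 1, 4, 1, 5))
  expect_equal(node_clustering(star, 1), 0)
  expect_error(node_clustering(star, 2), "fewer than two")
  g <- generate_er(20, 0.3, seed = 8)
  ok <- igraph::degree(g) >= 2
  cl <- node_clustering(g, which(ok))
  expect_true(all(cl >= 0 & cl <= 1))
})

test_that("network_stats aggregates are consistent with first principles", {
  k50 <- generate_er(50, 1)
  ns <- network_stats(k50)
  expect_equal(ns$avg_degree, 49)
  expect_equal(ns$interconnectedness, 1176)
  expect_equal(unname(ns$clustering_by_degree["49"]), 1)
  expect_equal(sum(ns$degree_dist), 1)

  g <- generate_er(30, 0.2, seed = 31)
  ns <- network_stats(g)
  # interconnectedness = 3 * (#triangles) / n
  tri <- sum(igraph::count_triangles(g)) / 3
  expect_equal(ns$interconnectedness, 3 * tri / 30)
  expect_true(all(ns$clustering_by_degree >= 0 & ns$clustering_by_degree <= 1))
  expect_equal(sum(ns$degree_dist), 1)
})
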