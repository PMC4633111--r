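# Binarization, graph metrics, null models, hubs, profile scores.

test_that("binarize_by_sparsity keeps the top-K pairs with a fixed count", {
  # 4-node toy: AB .9, AC .8, AD .7, BC .6, BD .5, CD .4 at S = 0.5
  m <- sim_from_upper(c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4), 4,
                      c("A", "B", "C", "D"))
  adj <- binarize_by_sparsity(m, 0.5)
  expect_equal(attr(adj, "n_edges"), 3)
  expect_equal(adj["A", "B"], 1)
  expect_equal(adj["A", "C"], 1)
  expect_equal(adj["A", "D"], 1)
  expect_equal(sum(adj) / 2, 3)
  expect_true(all(adj == t(adj)))
  expect_true(all(diag(adj) == 0))
  # R = 90 at the spotlight threshold: round(0.23 * 4005) = 921 edges
  set.seed(21)
  m90 <- sim_from_upper(runif(4005), 90)
  expect_equal(attr(binarize_by_sparsity(m90, 0.23), "n_edges"), 921)
  # identical edge count across "subjects" with different value scales
  m90b <- sim_from_upper(runif(4005) * 0.3, 90)
  expect_equal(attr(binarize_by_sparsity(m90b, 0.23), "n_edges"), 921)
  # degenerate thresholds
  expect_error(binarize_by_sparsity(m, 0.01), "0 edges")
  expect_error(binarize_by_sparsity(m, 0.99), "complete graph")
  # deterministic lexicographic tie-break
  mt <- sim_from_upper(rep(0.5, 6), 4)
  a1 <- binarize_by_sparsity(mt, 0.5)
  expect_equal(which(a1[upper.tri(a1)] == 1), c(1, 2, 4))  # (1,2),(1,3),(1,4)
})

test_that("clustering coefficient matches hand-enumerated cases", {
  k3 <- adj_from_edges(3, list(c(1, 2), c(2, 3), c(1, 3)))
  expect_equal(clustering_coefficient(k3)$Cp, 1)
  star <- adj_from_edges(4, list(c(1, 2), c(1, 3), c(1, 4)))
  expect_equal(clustering_coefficient(star)$Cp, 0)
  # 4-cycle plus one diagonal: per-node 2/3, 1, 2/3, 1
  cyc <- adj_from_edges(4, list(c(1, 2), c(2, 3), c(3, 4), c(4, 1), c(1, 3)))
  cc <- clustering_coefficient(cyc)
  expect_equal(cc$per_node, c(2 / 3, 1, 2 / 3, 1))
  expect_equal(cc$Cp, 5 / 6)
})

test_that("characteristic path length and disconnection handling", {
  path3 <- adj_from_edges(3, list(c(1, 2), c(2, 3)))
  expect_equal(characteristic_path_length(path3), 4 / 3)
  k4 <- matrix(1, 4, 4) - diag(4)
  expect_equal(characteristic_path_length(k4), 1)
  two_edges <- adj_from_edges(4, list(c(1, 2), c(3, 4)))
  expect_warning(lp <- characteristic_path_length(two_edges),
                 class = "morphnet_disconnected")
  expect_equal(lp, 1)
  expect_error(characteristic_path_length(matrix(0, 3, 3)), "no edges")
})

test_that("betweenness raw and normalized match hand enumeration", {
  star <- adj_from_edges(4, list(c(1, 2), c(1, 3), c(1, 4)))
  b <- betweenness_normalized(star)
  expect_equal(b$B, c(3, 0, 0, 0))
  expect_equal(b$meanBet, 0.75)
  expect_equal(b$b, c(4, 0, 0, 0))
  path3 <- adj_from_edges(3, list(c(1, 2), c(2, 3)))
  b3 <- betweenness_normalized(path3)
  expect_equal(b3$B, c(0, 1, 0))
  expect_equal(b3$b, c(0, 3, 0))
  k4 <- matrix(1, 4, 4) - diag(4)
  bk <- betweenness_normalized(k4)
  expect_equal(bk$B, rep(0, 4))
  expect_true(all(is.na(bk$b)))
})

test_that("global and local efficiency match hand enumeration", {
  k4 <- matrix(1, 4, 4) - diag(4)
  expect_equal(global_efficiency(k4), 1)
  path3 <- adj_from_edges(3, list(c(1, 2), c(2, 3)))
  expect_equal(global_efficiency(path3), 5 / 6)
  expect_equal(global_efficiency(matrix(0, 3, 3)), 0)
  k3 <- adj_from_edges(3, list(c(1, 2), c(2, 3), c(1, 3)))
  expect_equal(local_efficiency(k3)$Eloc, 1)
  expect_equal(local_efficiency(path3)$Eloc, 0)
  # 4-cycle plus diagonal 1-3: induced neighbor subgraphs give
  # (5/6 + 1 + 5/6 + 1)/4 = 11/12 (checked against brute_eloc)
  cyc <- adj_from_edges(4, list(c(1, 2), c(2, 3), c(3, 4), c(4, 1), c(1, 3)))
  expect_equal(local_efficiency(cyc)$Eloc, 11 / 12)
  expect_equal(local_efficiency(cyc)$Eloc, brute_eloc(cyc)$Eloc)
})

test_that("all metrics match brute-force oracles on enumerated small graphs", {
  # every graph on 4 nodes (64), plus random 5- and 6-node graphs
  check_graph <- function(a) {
    expect_equal(clustering_coefficient(a)$per_node,
                 brute_clustering(a)$per_node)
    expect_equal(global_efficiency(a), brute_eg(a))
    expect_equal(local_efficiency(a)$per_node, brute_eloc(a)$per_node)
    if (sum(a) > 0) {
      suppressWarnings(
        expect_equal(characteristic_path_length(a), brute_lp(a)))
      expect_equal(betweenness_normalized(a)$B, brute_betweenness(a),
                   tolerance = 1e-12)
    }
  }
  ut <- which(upper.tri(matrix(0, 4, 4)))
  for (code in 0:63) {
    a <- matrix(0, 4, 4)
    a[ut] <- as.numeric(bitwAnd(code, 2^(0:5)) > 0)
    a[lower.tri(a)] <- t(a)[lower.tri(a)]
    check_graph(a)
  }
  set.seed(22)
  for (k in 1:30) check_graph(random_graph(5))
  for (k in 1:30) check_graph(random_graph(6))
})

test_that("Maslov rewiring preserves degrees, edges, and is seeded", {
  set.seed(23)
  a <- random_graph(12, 0.35)
  r1 <- maslov_random_reference(a, seed = 99)
  r2 <- maslov_random_reference(a, seed = 99)
  expect_identical(unclass(r1), unclass(r2))
  expect_equal(sort(rowSums(r1)), sort(rowSums(a)))
  expect_equal(rowSums(r1), rowSums(a))  # per-node, not just sorted
  expect_equal(sum(r1), sum(a))
  expect_true(all(diag(r1) == 0))
  expect_true(all(r1 %in% c(0, 1)))
  # ensemble: degree sequence deviation 0 across 100 references; the
  # rewired graph is not stuck at the original for non-rigid graphs
  shared <- vapply(1:100, function(k) {
    r <- maslov_random_reference(a, seed = 1000 + k)
    expect_equal(rowSums(r), rowSums(a))
    sum(r * a) / sum(a)
  }, numeric(1))
  expect_lt(mean(shared), 1)
  expect_error(maslov_random_reference(adj_from_edges(3, list(c(1, 2)))),
               "at least 2 edges")
})

test_that("small_world_metrics: rigid complete graph gives gamma=lambda=sigma=1", {
  k5 <- matrix(1, 5, 5) - diag(5)
  gm <- suppressWarnings(small_world_metrics(k5, n_random = 5, seed = 1))
  expect_equal(gm$gamma, 1)
  expect_equal(gm$lambda, 1)
  expect_equal(gm$sigma, 1)
  expect_equal(gm$sigma, gm$gamma / gm$lambda, tolerance = 1e-12)
})

test_that("Watts-Strogatz graphs are detected as small-world", {
  # 90 nodes, degree 20, rewiring 0.1: gamma >= 1, lambda in [0.9, 1.5],
  # sigma > 1 for every seed (reduced 20-reference ensembles here; the
  # acceptance test runs the full 100)
  for (seed in 0:2) {
    set.seed(seed)
    a <- ws_graph(90, 20, 0.1)
    gm <- small_world_metrics(a, n_random = 20, seed = seed)
    expect_gt(gm$sigma, 1)
    expect_gte(gm$gamma, 1)
    expect_gt(gm$lambda, 0.9)
    expect_lt(gm$lambda, 1.5)
    expect_equal(gm$sigma, gm$gamma / gm$lambda, tolerance = 1e-12)
  }
})

test_that("hub rule: mean + 1 sample SD across nodes", {
  # cross-subject mean b = (1, 1, 1, 5): mean 2, sample SD 2, threshold 4
  bm <- rbind(c(1, 1, 1, 5), c(1, 1, 1, 5))
  colnames(bm) <- c("n1", "n2", "n3", "n4")
  h <- identify_hubs(bm)
  expect_equal(h$threshold, 4)
  expect_equal(h$hubs, "n4")
  # all equal: no hubs
  expect_length(identify_hubs(rbind(rep(2, 5)))$hubs, 0)
  # single subject reduces to its own profile
  h1 <- identify_hubs(c(n1 = 1, n2 = 1, n3 = 1, n4 = 5))
  expect_equal(h1$hubs, "n4")
})

test_that("profile similarity and uniqueness scores", {
  p <- rbind(1:10, 1:10, 1:10)
  sc <- profile_similarity_uniqueness(p)
  expect_equal(sc$similarity_raw, rep(1, 3))
  expect_equal(sc$uniqueness_raw, rep(0, 3))
  expect_equal(sc$similarity, rep(1, 3))
  expect_equal(sc$uniqueness, rep(0, 3))
  # subject 1 anticorrelated with identical subjects 2 and 3:
  # raw uniqueness 2, rescaled 1
  base <- c(1, 4, 2, 8, 5, 7, 3, 6, 9, 10)
  anti <- 2 * mean(base) - base
  sc2 <- profile_similarity_uniqueness(rbind(anti, base, base))
  expect_equal(sc2$uniqueness_raw[1], 2)
  expect_equal(sc2$uniqueness[1], 1)
  expect_equal(sc2$similarity_raw[1], -1)
  # N = 2: uniqueness = 1 - similarity for both subjects
  set.seed(24)
  two <- rbind(rnorm(10), rnorm(10))
  sc3 <- profile_similarity_uniqueness(two)
  expect_equal(sc3$uniqueness_raw, 1 - sc3$similarity_raw)
  expect_error(profile_similarity_uniqueness(rbind(rep(1, 5), rnorm(5))),
               "zero-variance")
})
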