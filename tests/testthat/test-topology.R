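triangle_net <- function(w_ab, w_bc, w_ac) {
  W <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  W["A", "B"] <- W["B", "A"] <- w_ab
  W["B", "C"] <- W["C", "B"] <- w_bc
  W["A", "C"] <- W["C", "A"] <- w_ac
  parenclitic_network(W)
}

test_that("weighted degrees sum incident edge weights", {
  tri <- triangle_net(1, 3, 2)     # A: 1+2, B: 1+3, C: 3+2
  expect_equal(weighted_degrees(tri), c(A = 3, B = 4, C = 5))
  st <- star_net(6)
  expect_equal(unname(weighted_degrees(st)), c(5, rep(1, 5)))
  z <- parenclitic_network(matrix(0, 3, 3),
                           present = matrix(FALSE, 3, 3))
  expect_equal(unname(weighted_degrees(z)), rep(0, 3))
})

test_that("shortest paths take detours when the direct edge is heavy", {
  tri <- triangle_net(w_ab = 5, w_bc = 1, w_ac = 1)
  D <- shortest_paths_matrix(tri)
  expect_equal(D["A", "B"], 2)          # via C, not the direct edge of 5
  expect_equal(D["A", "C"], 1)
  expect_equal(network_diameter(tri), 2)
  Dc <- shortest_paths_matrix(complete_net(5))
  expect_true(all(Dc[upper.tri(Dc)] == 1))
})

test_that("diameter matches hand computation and errors on disconnection", {
  # path A-B-C with weights 2, 3
  W <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  W["A", "B"] <- W["B", "A"] <- 2
  W["B", "C"] <- W["C", "B"] <- 3
  expect_equal(network_diameter(parenclitic_network(W)), 5)
  # single edge
  W2 <- matrix(0, 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  W2["A", "B"] <- W2["B", "A"] <- 0.7
  expect_equal(network_diameter(parenclitic_network(W2)), 0.7)
  # two isolated nodes
  z <- parenclitic_network(matrix(0, 2, 2), present = matrix(FALSE, 2, 2))
  expect_error(network_diameter(z), "components")
})

test_that("degree centralization follows the normalized star formula", {
  expect_equal(degree_centralization(complete_net(6)), 0)
  for (n in c(4, 5, 9))
    expect_equal(degree_centralization(star_net(n)), 1 / n, tolerance = 1e-12)
  expect_error(degree_centralization(complete_net(2)), "3 nodes")
  set.seed(51)
  g <- rand_weighted_graph(6)
  expect_equal(degree_centralization(g), oracle_degree_centralization(g),
               tolerance = 1e-12)
})

test_that("efficiency is exact on closed forms and matches oracle distances", {
  expect_equal(graph_efficiency(complete_net(7)), 1)
  z <- parenclitic_network(matrix(0, 2, 2), present = matrix(FALSE, 2, 2))
  expect_equal(graph_efficiency(z), 0)
  set.seed(52)
  g <- rand_weighted_graph(7)
  expect_equal(graph_efficiency(g),
               oracle_efficiency(oracle_graph_metrics(g)$D),
               tolerance = 1e-9)
})

test_that("betweenness matches closed forms for stars and complete graphs", {
  for (n in c(4, 6, 8)) {
    bw <- betweenness_scores(star_net(n))
    expect_equal(unname(bw[1]), (n - 1) * (n - 2) / 2)
    expect_equal(unname(bw[-1]), rep(0, n - 1))
  }
  expect_equal(unname(betweenness_scores(complete_net(6))), rep(0, 6))
})

test_that("all metric families agree with exhaustive-path oracles on random graphs", {
  set.seed(53)
  n_graphs <- 200
  for (rep in seq_len(n_graphs)) {
    n <- sample(4:8, 1)
    g <- rand_weighted_graph(n, p_extra = runif(1, 0.3, 0.9))
    ora <- oracle_graph_metrics(g)
    D <- unname(shortest_paths_matrix(g))
    dimnames(D) <- NULL
    expect_equal(D, ora$D, tolerance = 1e-9,
                 info = sprintf("distances, graph %d", rep))
    expect_equal(unname(betweenness_scores(g)), ora$betweenness,
                 tolerance = 1e-9, info = sprintf("betweenness, graph %d", rep))
    expect_equal(degree_centralization(g), oracle_degree_centralization(g),
                 tolerance = 1e-9, info = sprintf("centralization, graph %d", rep))
    expect_equal(graph_efficiency(g), oracle_efficiency(ora$D),
                 tolerance = 1e-9, info = sprintf("efficiency, graph %d", rep))
  }
})

test_that("homogeneous complete graphs give the expected degenerate features", {
  cn <- complete_net(5, w = 0.3)
  f <- extract_features(cn)
  expect_equal(unname(f["mean_edge_weight"]), 0.3)
  expect_equal(unname(f["var_edge_weight"]), 0)
  expect_equal(unname(f["max_edge_weight"]), 0.3)
  expect_equal(unname(f["var_degree"]), 0)
  expect_equal(unname(f["degree_centrality"]), 0)
  expect_equal(unname(f["diameter"]), 0.3)
  expect_equal(unname(f["efficiency"]), 1 / 0.3, tolerance = 1e-12)
})

test_that("the feature vector has 12 named entries matching per-metric oracles", {
  set.seed(54)
  g <- rand_weighted_graph(7)
  f <- extract_features(g)
  expect_length(f, 12)
  expect_identical(names(f),
                   c("mean_edge_weight", "var_edge_weight", "max_edge_weight",
                     "mean_degree", "var_degree", "max_degree",
                     "mean_shortest_path", "var_shortest_path",
                     "diameter", "degree_centrality", "efficiency",
                     "betweenness_centrality"))
  w <- g$weights[upper.tri(g$weights) & g$present]
  deg <- weighted_degrees(g)
  ora <- oracle_graph_metrics(g)
  dp <- ora$D[upper.tri(ora$D)]
  expect_equal(unname(f["mean_edge_weight"]), mean(w), tolerance = 1e-12)
  expect_equal(unname(f["var_edge_weight"]), var(w), tolerance = 1e-12)
  expect_equal(unname(f["max_edge_weight"]), max(w), tolerance = 1e-12)
  expect_equal(unname(f["mean_degree"]), mean(deg), tolerance = 1e-12)
  expect_equal(unname(f["var_degree"]), var(deg), tolerance = 1e-12)
  expect_equal(unname(f["max_degree"]), max(deg), tolerance = 1e-12)
  expect_equal(unname(f["mean_shortest_path"]), mean(dp), tolerance = 1e-9)
  expect_equal(unname(f["var_shortest_path"]), var(dp), tolerance = 1e-9)
  expect_equal(unname(f["diameter"]), max(ora$D), tolerance = 1e-9)
  expect_equal(unname(f["degree_centrality"]),
               oracle_degree_centralization(g), tolerance = 1e-9)
  expect_equal(unname(f["efficiency"]), oracle_efficiency(ora$D),
               tolerance = 1e-9)
  expect_equal(unname(f["betweenness_centrality"]), mean(ora$betweenness),
               tolerance = 1e-9)
})

test_that("features transform as the formulas dictate under uniform weight scaling", {
  set.seed(55)
  g <- rand_weighted_graph(7)
  f1 <- extract_features(g)
  for (c in c(0.25, 3)) {
    gc <- parenclitic_network(g$weights * c, present = g$present)
    f2 <- extract_features(gc)
    expect_equal(unname(f2["mean_edge_weight"]), unname(c * f1["mean_edge_weight"]), tolerance = 1e-9)
    expect_equal(unname(f2["max_edge_weight"]), unname(c * f1["max_edge_weight"]), tolerance = 1e-9)
    expect_equal(unname(f2["var_edge_weight"]), unname(c^2 * f1["var_edge_weight"]), tolerance = 1e-9)
    expect_equal(unname(f2["mean_shortest_path"]), unname(c * f1["mean_shortest_path"]), tolerance = 1e-9)
    expect_equal(unname(f2["diameter"]), unname(c * f1["diameter"]), tolerance = 1e-9)
    expect_equal(unname(f2["efficiency"]), unname(f1["efficiency"] / c), tolerance = 1e-9)
    # weighted degrees scale linearly, so the printed centralization does too
    expect_equal(unname(f2["degree_centrality"]), unname(c * f1["degree_centrality"]), tolerance = 1e-9)
    # path membership is unchanged: betweenness is scale-invariant
    expect_equal(unname(f2["betweenness_centrality"]), unname(f1["betweenness_centrality"]), tolerance = 1e-9)
  }
})

test_that("metrics are invariant under node relabeling", {
  set.seed(56)
  g <- rand_weighted_graph(6)
  perm <- sample(6)
  gp <- parenclitic_network(g$weights[perm, perm], present = g$present[perm, perm])
  f1 <- extract_features(g); f2 <- extract_features(gp)
  expect_equal(as.numeric(f1), as.numeric(f2), tolerance = 1e-10)
  expect_equal(sort(unname(betweenness_scores(g))),
               sort(unname(betweenness_scores(gp))), tolerance = 1e-10)
})

test_that("inverse edge-to-length mode shortens heavy edges", {
  tri <- triangle_net(4, 2, 2)
  Dd <- shortest_paths_matrix(tri, "direct")
  Di <- shortest_paths_matrix(tri, "inverse")
  expect_equal(Dd["A", "B"], 4)          # direct: heavy edge is long
  expect_equal(Di["A", "B"], 1 / 4)      # inverse: heavy edge is short
  f <- extract_features(tri, edge_to_length = "inverse")
  expect_identical(attr(f, "edge_to_length"), "inverse")
})

test_that("disconnected graphs error unless restricted to the largest component", {
  W <- matrix(0, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  W["a", "b"] <- W["b", "a"] <- 1
  W["b", "c"] <- W["c", "b"] <- 2
  W["d", "e"] <- W["e", "d"] <- 1
  g <- parenclitic_network(W)
  expect_error(extract_features(g), "disconnected")
  f <- extract_features(g, on_disconnected = "largest_component")
  expect_equal(attr(f, "component"), 3L)
  expect_equal(unname(f["diameter"]), 3)
})
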