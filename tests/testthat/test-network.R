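test_that("regression kernel matches hand arithmetic", {
  p <- list(alpha = 0.1, beta = 0.5, sigma = 0.2)
  # point exactly on the line
  expect_equal(edge_weight_regression(0.4, 0.3, p), 0)
  # one-sigma deviation
  expect_equal(edge_weight_regression(0.4, 0.3 + 0.2, p), 1)
  # worked case |0.7 - 0.3| / 0.2
  expect_equal(edge_weight_regression(0.4, 0.7, p), 2.0, tolerance = 1e-12)
  expect_error(edge_weight_regression(0.4, 0.7,
                                      list(alpha = 0, beta = 1, sigma = 0)),
               "sigma")
})

test_that("mahalanobis kernel matches the explicit 2x2 inverse", {
  mu <- c(0.3, 0.6)
  # at the center
  expect_equal(edge_weight_mahalanobis(mu, list(mu = mu, S = diag(2))), 0)
  # unit deviation under identity covariance
  expect_equal(edge_weight_mahalanobis(mu + c(1, 0), list(mu = mu, S = diag(2))), 1)
  # S = [[2,1],[1,2]], delta = (1,1): (1,1) (1/3)[[2,-1],[-1,2]] (1,1)' = 2/3
  S <- matrix(c(2, 1, 1, 2), 2, 2)
  expect_equal(edge_weight_mahalanobis(mu + c(1, 1), list(mu = mu, S = S)),
               2 / 3, tolerance = 1e-12)
  # square-root variant
  expect_equal(edge_weight_mahalanobis(mu + c(1, 1), list(mu = mu, S = S),
                                       squared = FALSE),
               sqrt(2 / 3), tolerance = 1e-12)
  expect_error(edge_weight_mahalanobis(c(1, 1),
                                       list(mu = c(0, 0),
                                            S = matrix(1, 2, 2))),
               "singular")
})

toy_cohort <- function(seed = 31, G = 4, n = 25) {
  set.seed(seed)
  X <- matrix(runif(G * n, 0.1, 0.9), G, n,
              dimnames = list(sprintf("g%02d", 1:G), sprintf("c%02d", 1:n)))
  X
}

test_that("network weights equal per-pair kernel evaluation (both kernels)", {
  X <- toy_cohort()
  x <- setNames(runif(4, 0.1, 0.9), rownames(X))
  for (fit in list(fit_regression(X), fit_mahalanobis(X))) {
    net <- build_network(x, fit, sample_id = "s1")
    expect_identical(net$weights, t(net$weights))
    expect_equal(diag(net$weights), setNames(rep(0, 4), rownames(X)))
    for (k in seq_along(fit$pair_i)) {
      gi <- fit$gene_ids[fit$pair_i[k]]; gj <- fit$gene_ids[fit$pair_j[k]]
      p <- pair_params(fit, gi, gj)
      w_hand <- if (fit$kernel == "regression")
        abs(x[gj] - (p$alpha + p$beta * x[gi])) / p$sigma
      else {
        d <- c(x[gi], x[gj]) - p$mu
        Sinv <- solve(p$S)
        drop(t(d) %*% Sinv %*% d)
      }
      expect_equal(unname(net$weights[gi, gj]), unname(w_hand),
                   tolerance = 1e-12)
    }
  }
})

test_that("a sample at the control mean yields an all-zero network", {
  X <- toy_cohort(32)
  x <- rowMeans(X)
  for (fit in list(fit_regression(X), fit_mahalanobis(X))) {
    net <- build_network(x, fit, sample_id = "mean")
    expect_lt(max(net$weights), 1e-10)
  }
})

test_that("regression weights are homogeneous in the deviation from the line", {
  X <- toy_cohort(33)
  fit <- fit_regression(X)
  p <- pair_params(fit, "g01", "g02")
  xi <- 0.5
  on_line <- p$alpha + p$beta * xi
  dev <- 0.07
  w1 <- edge_weight_regression(xi, on_line + dev, p)
  for (c in c(0.5, 2, 3.7))
    expect_equal(edge_weight_regression(xi, on_line + c * dev, p),
                 abs(c) * w1, tolerance = 1e-10)
})

test_that("mahalanobis weights are invariant under a shared affine transform", {
  set.seed(34)
  X <- toy_cohort(34, G = 2, n = 40)
  x <- c(g01 = 0.8, g02 = 0.15)
  A <- matrix(c(0.4, 0.1, -0.05, 0.3), 2, 2)   # invertible
  b <- c(0.3, 0.35)
  Xt <- A %*% X + b
  rownames(Xt) <- rownames(X)
  xt <- setNames(drop(A %*% x + b), names(x))
  w0 <- build_network(x, fit_mahalanobis(X), sample_id = "s")$weights[1, 2]
  wt <- build_network(xt, fit_mahalanobis(Xt), sample_id = "s")$weights[1, 2]
  expect_equal(wt, w0, tolerance = 1e-8)
})

test_that("degenerate pairs are excluded from the edge set (or error in strict mode)", {
  X <- toy_cohort(35)
  X["g03", ] <- 0.4                       # constant gene
  fit <- suppressWarnings(fit_regression(X))
  expect_true(any(fit$degenerate))
  x <- setNames(runif(4, 0.1, 0.9), rownames(X))
  net <- build_network(x, fit, sample_id = "s")
  degen <- which(fit$degenerate)
  for (k in degen) {
    gi <- fit$gene_ids[fit$pair_i[k]]; gj <- fit$gene_ids[fit$pair_j[k]]
    expect_false(net$present[gi, gj])
    expect_equal(unname(net$weights[gi, gj]), 0)
  }
  expect_error(build_network(x, fit, sample_id = "s", strict = TRUE),
               "degenerate")
})

test_that("building a network for a control sample requires explicit opt-in", {
  X <- toy_cohort(36)
  m <- methylation_matrix(X)
  fit <- fit_mahalanobis(X)
  expect_error(build_network(m, fit, "c01"), "control group")
  expect_warning(net <- build_network(m, fit, "c01", allow_control = TRUE),
                 "control")
  expect_s3_class(net, "parenclitic_network")
  expect_error(build_network(setNames(runif(3), c("g01", "g02", "zzz")),
                             fit, sample_id = "s"),
               "lacks genes")
})

test_that("top-edge subgraphs select the k strongest edges with the documented tie rule", {
  X <- toy_cohort(37, G = 6)
  fit <- fit_mahalanobis(X)
  x <- setNames(runif(6, 0.1, 0.9), rownames(X))
  net <- build_network(x, fit, sample_id = "s")
  ne <- nrow(parenclitic:::net_edges(net))

  whole <- top_edges_subgraph(net, ne)
  expect_equal(nrow(whole$edges), ne)
  expect_setequal(whole$nodes, rownames(X))

  # k = 1: the single maximal edge, verified by full scan
  best <- top_edges_subgraph(net, 1)
  up <- which(upper.tri(net$weights), arr.ind = TRUE)
  wmax <- max(net$weights[up])
  expect_equal(best$edges$weight, wmax)
  expect_error(top_edges_subgraph(net, 0), "between 1")
  expect_error(top_edges_subgraph(net, ne + 1), "between 1")

  # tie at the boundary: lexicographically smaller pair wins
  W <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  W["a", "b"] <- W["b", "a"] <- 1
  W["a", "c"] <- W["c", "a"] <- 1
  W["b", "c"] <- W["c", "b"] <- 2
  tie <- parenclitic_network(W)
  top2 <- top_edges_subgraph(tie, 2)
  expect_equal(top2$edges$gene_i, c("b", "a"))
  expect_equal(top2$edges$gene_j, c("c", "b"))
})

test_that("edge lists and graphml round-trip through disk", {
  X <- toy_cohort(38, G = 5)
  fit <- fit_mahalanobis(X)
  x <- setNames(runif(5, 0.1, 0.9), rownames(X))
  net <- build_network(x, fit, sample_id = "s9")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(net, path)
  back <- read_edge_list(path, gene_ids = net$gene_ids, sample_id = "s9")
  expect_equal(back$weights, net$weights, tolerance = 1e-11)
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(net, gml)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::gorder(g), 5)
  expect_equal(igraph::gsize(g), 10)
  expect_equal(sort(igraph::E(g)$weight),
               sort(net$weights[upper.tri(net$weights)]), tolerance = 1e-11)
})
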