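## Weighted-graph topology metrics.  Edge weights are used directly as path
## lengths by default ("direct"): the distance between two nodes is the
## minimal sum of edge weights along a path.  An alternative "inverse" mode
## (length = 1/weight) treats heavy, abnormal edges as short; both modes are
## first-class and stamped into outputs.

EPS_PATH <- 1e-9    # relative tolerance for shortest-path length ties
EPS_DIST <- 1e-12   # distances below this contribute 1/EPS_DIST to efficiency

length_matrix <- function(net, edge_to_length = c("direct", "inverse")) {
  edge_to_length <- match.arg(edge_to_length)
  W <- net$weights
  L <- matrix(Inf, nrow(W), ncol(W), dimnames = dimnames(W))
  if (edge_to_length == "direct") L[net$present] <- W[net$present]
  else L[net$present] <- 1 / pmax(W[net$present], EPS_DIST)
  diag(L) <- 0
  if (any(L < 0, na.rm = TRUE)) stop_pn("negative edge weights are not allowed")
  L
}

floyd_warshall <- function(L) {
  D <- L
  n <- nrow(L)
  for (k in seq_len(n)) {
    Dk <- outer(D[, k], D[k, ], `+`)   # Inf-safe
    upd <- Dk < D
    if (any(upd)) D[upd] <- Dk[upd]
  }
  D
}

#' Weighted node degrees
#'
#' The degree of a node is the sum of the weights of its incident edges.
#'
#' @param net a `parenclitic_network`.
#' @return named numeric vector, one entry per gene.
#' @export
weighted_degrees <- function(net) {
  rowSums(net$weights * net$present)
}

#' All-pairs shortest-path distance matrix
#'
#' Distances are minimal total weight over paths (Floyd-Warshall);
#' `d(v, v) = 0` and unreachable pairs carry the sentinel `Inf`.
#'
#' @param net a `parenclitic_network`.
#' @param edge_to_length `"direct"` (weight is the length, the default) or
#'   `"inverse"` (length = 1/weight).
#' @return symmetric numeric matrix with gene dimnames.
#' @export
shortest_paths_matrix <- function(net, edge_to_length = "direct") {
  floyd_warshall(length_matrix(net, edge_to_length))
}

components_from_D <- function(D) {
  n <- nrow(D)
  comp <- integer(n); cur <- 0L
  for (v in seq_len(n)) if (comp[v] == 0L) {
    cur <- cur + 1L
    comp[is.finite(D[v, ])] <- cur
  }
  comp
}

require_connected <- function(D, what) {
  comp <- components_from_D(D)
  if (max(comp) > 1L)
    stop_pn(what, " requires a connected graph; found ", max(comp),
            " components of sizes ",
            paste(sort(tabulate(comp), decreasing = TRUE), collapse = ", "))
  invisible(comp)
}

#' Graph diameter
#'
#' The maximal shortest-path distance between any pair of vertices; an error
#' on disconnected graphs (the components are named).
#'
#' @inheritParams shortest_paths_matrix
#' @return scalar.
#' @export
network_diameter <- function(net, edge_to_length = "direct") {
  D <- shortest_paths_matrix(net, edge_to_length)
  require_connected(D, "diameter")
  max(D)
}

#' Freeman-style degree centralization of the graph
#'
#' Node degree centrality is `deg(v) / |V|` with weighted degrees; the graph
#' score sums the gaps to the most central node,
#' `H(G) = sum_i |C_D(v*) - C_D(v_i)|`, and is normalized by the star-graph
#' maximum `H_max = (|V| - 1)(|V| - 2)`.  With this normalization a
#' unit-weight star on n nodes scores `1/n`, and uniform weight scaling by c
#' scales the score by c.
#'
#' @param net a `parenclitic_network` with at least 3 nodes.
#' @return scalar in `[0, Inf)`.
#' @export
degree_centralization <- function(net) {
  n <- length(net$gene_ids)
  if (n < 3) stop_pn("degree centralization needs at least 3 nodes (H_max = 0 otherwise)")
  cd <- weighted_degrees(net) / n
  sum(max(cd) - cd) / ((n - 1) * (n - 2))
}

#' Graph efficiency
#'
#' Mean inverse shortest-path distance over ordered node pairs:
#' `E_C(G) = sum_{i != j} 1/d(v_i, v_j) / (|V| (|V| - 1))`.  Unreachable
#' pairs contribute 0; distances below `1e-12` (possible only for samples
#' identical to the control mean) contribute the capped value `1e12`.
#'
#' @inheritParams shortest_paths_matrix
#' @return scalar; 1 for a unit-weight complete graph.
#' @export
graph_efficiency <- function(net, edge_to_length = "direct") {
  D <- shortest_paths_matrix(net, edge_to_length)
  n <- nrow(D)
  off <- D[row(D) != col(D)]
  fin <- is.finite(off)
  sum(1 / pmax(off[fin], EPS_DIST)) / (n * (n - 1))
}

## Count minimal-weight paths between every ordered pair.  Nodes are
## processed outward from each source in (distance, index) order; a
## predecessor must be tight (d(s,u) + w(u,j) equals d(s,j) within the
## relative tolerance) and already processed, which breaks zero-weight
## distance ties by node index.
path_counts <- function(L, D, tol = EPS_PATH) {
  n <- nrow(L)
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    ds <- D[s, ]
    sig <- numeric(n)
    sig[s] <- 1
    ord <- order(ds, seq_len(n))
    for (j in ord) {
      if (j == s || !is.finite(ds[j])) next
      tolj <- tol * max(1, abs(ds[j]))
      tight <- is.finite(L[, j]) & abs(ds + L[, j] - ds[j]) <= tolj
      tight[j] <- FALSE
      sig[j] <- sum(sig[tight])
    }
    sigma[s, ] <- sig
  }
  sigma
}

betweenness_from <- function(D, sigma, tol = EPS_PATH) {
  n <- nrow(D)
  bw <- numeric(n)
  tolm <- tol * pmax(1, abs(D))
  for (k in seq_len(n)) {
    through <- outer(D[, k], D[k, ], `+`)
    ok <- is.finite(D) & is.finite(through) & abs(through - D) <= tolm
    ok[k, ] <- FALSE; ok[, k] <- FALSE; diag(ok) <- FALSE
    ok <- ok & sigma > 0
    if (any(ok)) {
      num <- outer(sigma[, k], sigma[k, ])
      bw[k] <- sum(num[ok] / sigma[ok]) / 2
    }
  }
  bw
}

#' Betweenness centrality of every node
#'
#' For node v_k, the sum over unordered pairs (i, j), i != k != j, of the
#' fraction of minimal-weight i-j paths that pass through v_k as an interior
#' node.  Path-length ties are resolved with a relative tolerance of `1e-9`.
#'
#' @inheritParams shortest_paths_matrix
#' @return named numeric vector of per-node scores; the center of a
#'   unit-weight star on n nodes scores `(n-1)(n-2)/2`.
#' @export
betweenness_scores <- function(net, edge_to_length = "direct") {
  L <- length_matrix(net, edge_to_length)
  D <- floyd_warshall(L)
  sigma <- path_counts(L, D)
  setNames(betweenness_from(D, sigma), net$gene_ids)
}

FEATURE_NAMES <- c("mean_edge_weight", "var_edge_weight", "max_edge_weight",
                   "mean_degree", "var_degree", "max_degree",
                   "mean_shortest_path", "var_shortest_path",
                   "diameter", "degree_centrality", "efficiency",
                   "betweenness_centrality")

var0 <- function(x) if (length(x) < 2) 0 else var(x)

#' The 12-index topology feature vector
#'
#' Summarizes one parenclitic network by, in fixed order: mean, sample
#' variance (divisor n - 1) and maximum of the edge weights; mean, variance
#' and maximum of the weighted node degrees; mean and variance of the
#' shortest-path lengths over unordered node pairs; the diameter; the
#' normalized degree centralization; the graph efficiency; and the mean
#' per-node betweenness centrality.
#'
#' @inheritParams shortest_paths_matrix
#' @param on_disconnected `"error"` (default) or `"largest_component"`,
#'   which restricts the whole computation to the largest connected
#'   component (recorded in the `component` attribute).
#' @return a named numeric vector of class `topology_features`, length 12,
#'   with attributes `sample_id`, `kernel`, `edge_to_length`.
#' @export
extract_features <- function(net, edge_to_length = "direct",
                             on_disconnected = c("error", "largest_component")) {
  on_disconnected <- match.arg(on_disconnected)
  L <- length_matrix(net, edge_to_length)
  D <- floyd_warshall(L)
  comp <- components_from_D(D)
  used_component <- FALSE
  if (max(comp) > 1L) {
    if (on_disconnected == "error")
      stop_pn("network is disconnected (", max(comp), " components of sizes ",
              paste(sort(tabulate(comp), decreasing = TRUE), collapse = ", "),
              "); use on_disconnected = \"largest_component\" to proceed")
    keep <- comp == which.max(tabulate(comp))
    net <- new_parenclitic_network(net$sample_id, net$gene_ids[keep],
                                   net$weights[keep, keep, drop = FALSE],
                                   net$present[keep, keep, drop = FALSE],
                                   net$kernel)
    L <- L[keep, keep, drop = FALSE]
    D <- D[keep, keep, drop = FALSE]
    used_component <- TRUE
  }
  n <- nrow(D)
  if (n < 3) stop_pn("need at least 3 connected nodes for the feature vector")
  w <- net$weights[upper.tri(net$weights) & net$present]
  deg <- weighted_degrees(net)
  dpath <- D[upper.tri(D)]
  sigma <- path_counts(L, D)
  bw <- betweenness_from(D, sigma)
  cd <- deg / n
  feats <- c(mean(w), var0(w), max(w),
             mean(deg), var0(deg), max(deg),
             mean(dpath), var0(dpath),
             max(D),
             sum(max(cd) - cd) / ((n - 1) * (n - 2)),
             sum(1 / pmax(D[row(D) != col(D)], EPS_DIST)) / (n * (n - 1)),
             mean(bw))
  structure(setNames(feats, FEATURE_NAMES), class = "topology_features",
            sample_id = net$sample_id, kernel = net$kernel,
            edge_to_length = edge_to_length,
            component = if (used_component) n else NA_integer_)
}

#' @export
print.topology_features <- function(x, ...) {
  cat(sprintf("<topology_features> sample=%s kernel=%s lengths=%s\n",
              attr(x, "sample_id"), attr(x, "kernel"),
              attr(x, "edge_to_length")))
  print(setNames(as.numeric(x), names(x)))
  invisible(x)
}

#' Feature table for many samples
#'
#' Builds each sample's network and extracts the 12-index vector, returning
#' one row per sample.
#'
#' @param m a [methylation_matrix()].
#' @param model a `control_model`.
#' @param sample_ids default: all samples outside the control group.
#' @param edge_to_length passed to [extract_features()].
#' @param ... passed to [build_network()].
#' @return data.frame with `sample_id`, `kernel`, `edge_to_length` and the
#'   12 feature columns.
#' @export
topology_feature_table <- function(m, model, sample_ids = NULL,
                                   edge_to_length = "direct", ...) {
  stopifnot(inherits(m, "methylation_matrix"))
  if (is.null(sample_ids))
    sample_ids <- setdiff(colnames(m$values), model$control_ids)
  rows <- lapply(sample_ids, function(s) {
    f <- extract_features(build_network(m, model, s, ...), edge_to_length)
    as.data.frame(as.list(f))
  })
  out <- do.call(rbind, rows)
  cbind(data.frame(sample_id = sample_ids, kernel = model$kernel,
                   edge_to_length = edge_to_length,
                   stringsAsFactors = FALSE),
        out)
}

#' Write a feature table
#'
#' @param features data.frame from [topology_feature_table()].
#' @param path output TSV.
#' @export
write_features <- function(features, path) {
  out <- features
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], fmt_num)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
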