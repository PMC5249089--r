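#' Regression-kernel edge weight
#'
#' The absolute residual of the sample's point from the control regression
#' line, in units of the control residual standard deviation:
#' `|x_j - (alpha + beta * x_i)| / sigma`.
#'
#' @param x_i,x_j methylation levels of the predictor and response gene.
#' @param params list with `alpha`, `beta`, `sigma` (e.g. from
#'   [pair_params()]).
#' @return nonnegative edge weight (vectorized over inputs).
#' @export
edge_weight_regression <- function(x_i, x_j, params) {
  if (any(!is.finite(params$sigma)) || any(params$sigma <= 0))
    stop_pn("regression kernel undefined: sigma must be positive ",
            "(degenerate pair; drop it upstream)")
  abs(x_j - (params$alpha + params$beta * x_i)) / params$sigma
}

#' Mahalanobis-kernel edge weight
#'
#' The squared Mahalanobis distance of the sample's pair of methylation
#' levels from the control-group cloud:
#' `(x - mu)' S^{-1} (x - mu)`.  The squared form (no square root) is the
#' default edge weight; set `squared = FALSE` for the square-root variant.
#'
#' @param x numeric 2-vector `(x_i, x_j)`.
#' @param params list with `mu` (2-vector) and `S` (2x2 covariance).
#' @param squared return the squared distance (default) or its square root.
#' @return nonnegative edge weight.
#' @export
edge_weight_mahalanobis <- function(x, params, squared = TRUE) {
  S <- params$S
  det <- S[1, 1] * S[2, 2] - S[1, 2] * S[2, 1]
  if (!is.finite(det) || det <= 0)
    stop_pn("mahalanobis kernel undefined: singular covariance ",
            "(degenerate pair; refit with ridge > 0)")
  d <- c(x[1] - params$mu[1], x[2] - params$mu[2])
  w <- (S[2, 2] * d[1]^2 - 2 * S[1, 2] * d[1] * d[2] + S[1, 1] * d[2]^2) / det
  if (squared) w else sqrt(w)
}

#' Assemble a parenclitic network from explicit matrices
#'
#' [build_network()] is the usual constructor; this one builds a network
#' object directly from a symmetric nonnegative weight matrix, which is
#' handy for toy graphs and for restoring exported networks.
#'
#' @param weights symmetric numeric matrix, zero diagonal; dimnames are the
#'   gene ids (defaults are generated when absent).
#' @param present symmetric logical matrix marking which pairs carry an
#'   edge; default: every off-diagonal pair with `weights > 0` — pass an
#'   explicit mask to keep zero-weight edges.
#' @param sample_id,kernel metadata carried on the object.
#' @return a `parenclitic_network`.
#' @export
parenclitic_network <- function(weights, present = NULL,
                                sample_id = "sample", kernel = "custom") {
  if (!is.matrix(weights) || nrow(weights) != ncol(weights))
    stop_pn("`weights` must be a square matrix")
  if (max(abs(weights - t(weights))) > 0)
    stop_pn("`weights` must be symmetric")
  if (any(weights < 0) || any(!is.finite(weights)))
    stop_pn("weights must be finite and nonnegative")
  if (any(diag(weights) != 0)) stop_pn("diagonal must be zero")
  ids <- rownames(weights) %||% sprintf("v%03d", seq_len(nrow(weights)))
  if (is.null(present)) {
    present <- weights > 0
  } else {
    if (!identical(dim(present), dim(weights)) ||
        !identical(present, t(present)))
      stop_pn("`present` must be a symmetric logical matrix matching `weights`")
    diag(present) <- FALSE
  }
  new_parenclitic_network(sample_id, ids, weights, present, kernel)
}

new_parenclitic_network <- function(sample_id, gene_ids, weights, present,
                                    kernel) {
  dimnames(weights) <- list(gene_ids, gene_ids)
  dimnames(present) <- list(gene_ids, gene_ids)
  structure(list(sample_id = sample_id, gene_ids = gene_ids,
                 weights = weights, present = present, kernel = kernel),
            class = "parenclitic_network")
}

#' @export
print.parenclitic_network <- function(x, ...) {
  ne <- sum(x$present[upper.tri(x$present)])
  cat(sprintf("<parenclitic_network> sample=%s, %d genes, %d edges, kernel=%s\n",
              x$sample_id, length(x$gene_ids), ne, x$kernel))
  invisible(x)
}

#' Build one sample's parenclitic network
#'
#' Evaluates the control model's edge kernel at the sample's methylation
#' levels for every non-degenerate gene pair, producing a complete weighted
#' graph (symmetric nonnegative weight matrix, zero diagonal).  Degenerate
#' pairs are absent from the edge set (weight 0, `present = FALSE`); with
#' `strict = TRUE` their presence is an error instead.
#'
#' @param x either a named numeric vector of methylation levels covering the
#'   model's gene panel, or a [methylation_matrix()] together with
#'   `sample_id`.
#' @param model a `control_model` from [fit_regression()] or
#'   [fit_mahalanobis()].
#' @param sample_id sample column to use when `x` is a matrix; also stamps
#'   the returned network.
#' @param strict error on degenerate pairs instead of dropping them.
#' @param allow_control building a network for one of the model's own
#'   control samples is an error unless this is `TRUE` (then a warning).
#' @param squared use the squared Mahalanobis distance (default, as the
#'   kernel is defined) or its square root.
#' @return a `parenclitic_network`.
#' @export
build_network <- function(x, model, sample_id = NULL, strict = FALSE,
                          allow_control = FALSE, squared = TRUE) {
  stopifnot(inherits(model, "control_model"))
  if (inherits(x, "methylation_matrix")) {
    if (is.null(sample_id)) stop_pn("`sample_id` required with a matrix input")
    if (!sample_id %in% colnames(x$values))
      stop_pn("sample not found: ", sample_id)
    x <- x$values[, sample_id]
  } else {
    if (is.null(sample_id)) sample_id <- "sample"
  }
  if (is.null(names(x))) {
    if (length(x) != length(model$gene_ids))
      stop_pn("unnamed sample vector must match the model panel length")
    names(x) <- model$gene_ids
  }
  missing <- setdiff(model$gene_ids, names(x))
  if (length(missing))
    stop_pn("sample lacks genes in the model panel: ",
            paste(head(missing, 5), collapse = ", "),
            if (length(missing) > 5) ", ...")
  if (sample_id %in% model$control_ids) {
    if (allow_control)
      warning("building a network for control sample ", sample_id, call. = FALSE)
    else
      stop_pn("sample ", sample_id, " is in the model's control group ",
              "(use allow_control = TRUE to proceed)")
  }
  x <- x[model$gene_ids]
  G <- length(model$gene_ids)
  pi <- model$pair_i; pj <- model$pair_j
  degen <- model$degenerate
  if (strict && any(degen))
    stop_pn(sum(degen), " degenerate pair(s) in model, e.g. ",
            model$gene_ids[pi[which(degen)[1]]], "-",
            model$gene_ids[pj[which(degen)[1]]])

  w <- numeric(length(pi))
  ok <- !degen
  if (model$kernel == "regression") {
    a <- model$params$alpha; b <- model$params$beta; s <- model$params$sigma
    w[ok] <- abs(x[pj[ok]] - (a[ok] + b[ok] * x[pi[ok]])) / s[ok]
  } else {
    mu <- model$params$mu
    dx <- x[pi] - mu[pi]; dy <- x[pj] - mu[pj]
    s11 <- model$params$s11; s12 <- model$params$s12; s22 <- model$params$s22
    det <- s11 * s22 - s12^2
    w[ok] <- (s22[ok] * dx[ok]^2 - 2 * s12[ok] * dx[ok] * dy[ok] +
                s11[ok] * dy[ok]^2) / det[ok]
    if (!squared) w[ok] <- sqrt(w[ok])
  }
  W <- matrix(0, G, G)
  W[cbind(pi, pj)] <- w
  W <- W + t(W)
  P <- matrix(FALSE, G, G)
  P[cbind(pi, pj)] <- ok
  P <- P | t(P)
  new_parenclitic_network(sample_id, model$gene_ids, W, P, model$kernel)
}

#' Networks for many samples
#'
#' @param m a [methylation_matrix()].
#' @param model a `control_model`.
#' @param sample_ids samples to build; default all samples not in the
#'   model's control group.
#' @param ... passed to [build_network()].
#' @return named list of `parenclitic_network` objects.
#' @export
build_networks <- function(m, model, sample_ids = NULL, ...) {
  stopifnot(inherits(m, "methylation_matrix"))
  if (is.null(sample_ids))
    sample_ids <- setdiff(colnames(m$values), model$control_ids)
  setNames(lapply(sample_ids, function(s) build_network(m, model, s, ...)),
           sample_ids)
}

net_edges <- function(net) {
  up <- which(upper.tri(net$weights) & net$present, arr.ind = TRUE)
  data.frame(gene_i = net$gene_ids[up[, 1]],
             gene_j = net$gene_ids[up[, 2]],
             weight = net$weights[up],
             stringsAsFactors = FALSE)
}

#' Strongest-edge subgraph
#'
#' The `k` largest-weight edges of a network and the node set they touch;
#' ties at the boundary are broken by lexicographic gene-pair order
#' (smaller pair included first).
#'
#' @param net a `parenclitic_network`.
#' @param k number of edges to keep, between 1 and the edge count.
#' @return list with `edges` (data.frame `gene_i`, `gene_j`, `weight`,
#'   sorted by decreasing weight) and `nodes` (sorted incident gene ids).
#' @export
top_edges_subgraph <- function(net, k) {
  ed <- net_edges(net)
  if (!(k >= 1 && k <= nrow(ed)))
    stop_pn("`k` must lie between 1 and the number of edges (", nrow(ed), ")")
  ord <- order(-ed$weight, ed$gene_i, ed$gene_j)
  top <- ed[ord[seq_len(k)], , drop = FALSE]
  rownames(top) <- NULL
  list(edges = top, nodes = sort(unique(c(top$gene_i, top$gene_j))))
}

#' Export a network (or subgraph) to disk
#'
#' `write_edge_list` writes the three-column weighted edge list
#' (`gene_i`, `gene_j`, `weight`, tab-separated); `write_graphml` writes
#' GraphML via igraph.  `read_edge_list` restores a network from an edge
#' list; nodes default to the genes observed in the file.
#'
#' @param net a `parenclitic_network` or the `edges`/`nodes` list returned
#'   by [top_edges_subgraph()].
#' @param path output file.
#' @export
write_edge_list <- function(net, path) {
  ed <- if (inherits(net, "parenclitic_network")) net_edges(net) else net$edges
  ed$weight <- fmt_num(ed$weight)
  write.table(ed, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
write_graphml <- function(net, path) {
  if (inherits(net, "parenclitic_network")) {
    ed <- net_edges(net); nodes <- net$gene_ids
  } else {
    ed <- net$edges; nodes <- net$nodes
  }
  g <- igraph::graph_from_data_frame(ed, directed = FALSE,
                                     vertices = data.frame(name = nodes))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @param gene_ids optional full gene panel (nodes may be isolated).
#' @param sample_id,kernel metadata stamped on the restored network.
#' @rdname write_edge_list
#' @export
read_edge_list <- function(path, gene_ids = NULL, sample_id = NULL,
                           kernel = "unknown") {
  ed <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_i", "gene_j", "weight") %in% colnames(ed)))
    stop_pn("edge list needs columns gene_i, gene_j, weight: ", path)
  nodes <- gene_ids %||% sort(unique(c(ed$gene_i, ed$gene_j)))
  G <- length(nodes)
  W <- matrix(0, G, G, dimnames = list(nodes, nodes))
  P <- matrix(FALSE, G, G, dimnames = list(nodes, nodes))
  i <- match(ed$gene_i, nodes); j <- match(ed$gene_j, nodes)
  if (anyNA(i) || anyNA(j)) stop_pn("edge list refers to genes outside the panel")
  W[cbind(i, j)] <- ed$weight; W[cbind(j, i)] <- ed$weight
  P[cbind(i, j)] <- TRUE; P[cbind(j, i)] <- TRUE
  new_parenclitic_network(sample_id %||% sub("\\.[^.]*$", "", basename(path)),
                          nodes, W, P, kernel)
}
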