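# Brute-force graph oracles, independent of the package's algorithms:
# distances, shortest-path counts and betweenness come from exhaustive
# enumeration of all simple paths; the scalar indices from direct
# transcription of their defining formulas.

# Random connected weighted graph (random spanning tree + extra edges).
rand_weighted_graph <- function(n, p_extra = 0.6, wmin = 0.1, wmax = 2) {
  W <- matrix(0, n, n)
  P <- matrix(FALSE, n, n)
  ord <- sample(n)
  for (k in 2:n) {
    a <- ord[k]; b <- ord[sample(k - 1, 1)]
    P[a, b] <- P[b, a] <- TRUE
  }
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    if (!P[i, j] && runif(1) < p_extra) P[i, j] <- P[j, i] <- TRUE
  w <- runif(sum(P[upper.tri(P)]), wmin, wmax)
  W[upper.tri(W)][P[upper.tri(P)]] <- w
  W <- W + t(W)
  parenclitic_network(W, present = P)
}

# Exhaustive simple-path enumeration from every source.  Returns all-pairs
# distances D, minimal-path counts SIG, and per-node betweenness per the
# definition: sum over unordered pairs of the fraction of minimal paths
# with the node interior.
oracle_graph_metrics <- function(net, tol = 1e-9) {
  W <- net$weights; P <- net$present
  n <- nrow(W)
  D <- matrix(Inf, n, n); diag(D) <- 0
  SIG <- matrix(0, n, n); diag(SIG) <- 1
  INT <- array(0, dim = c(n, n, n))
  for (s in seq_len(n)) {
    lens <- vector("list", n)
    ints <- vector("list", n)
    dfs <- function(v, visited, len) {
      for (u in which(P[v, ])) {
        if (u %in% visited) next
        l2 <- len + W[v, u]
        lens[[u]][[length(lens[[u]]) + 1]] <<- l2
        ints[[u]][[length(ints[[u]]) + 1]] <<- setdiff(visited, s)
        dfs(u, c(visited, u), l2)
      }
    }
    dfs(s, s, 0)
    for (t in seq_len(n)) {
      if (t == s || length(lens[[t]]) == 0) next
      ls <- unlist(lens[[t]])
      dmin <- min(ls)
      D[s, t] <- dmin
      minimal <- which(abs(ls - dmin) <= tol * max(1, abs(dmin)))
      SIG[s, t] <- length(minimal)
      for (m in minimal) for (k in ints[[t]][[m]]) INT[s, t, k] <- INT[s, t, k] + 1
    }
  }
  bw <- numeric(n)
  for (k in seq_len(n)) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (i == k || j == k || !is.finite(D[i, j]) || SIG[i, j] == 0) next
      bw[k] <- bw[k] + INT[i, j, k] / SIG[i, j]
    }
  }
  list(D = D, SIG = SIG, betweenness = bw)
}

# Direct formula transcriptions for the scalar indices.
oracle_degree_centralization <- function(net) {
  n <- nrow(net$weights)
  deg <- sapply(seq_len(n), function(v) sum(net$weights[v, net$present[v, ]]))
  cd <- deg / n
  H <- sum(abs(max(cd) - cd))
  H / ((n - 1) * (n - 2))
}

oracle_efficiency <- function(D) {
  n <- nrow(D)
  tot <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j && is.finite(D[i, j])) tot <- tot + 1 / D[i, j]
  tot / (n * (n - 1))
}

# Toy fixtures
star_net <- function(n, w = 1) {
  W <- matrix(0, n, n)
  W[1, 2:n] <- w; W[2:n, 1] <- w
  P <- W > 0
  parenclitic_network(W, present = P)
}

complete_net <- function(n, w = 1) {
  W <- matrix(w, n, n); diag(W) <- 0
  parenclitic_network(W, present = W > 0)
}
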