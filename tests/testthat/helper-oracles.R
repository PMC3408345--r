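# Shared independent oracles and small fixture builders.

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# Exhaustive maximum-weight connected subgraph by bitmask enumeration (n <= 20).
brute_mwcs <- function(graph, scores) {
  ids <- igraph::as_ids(igraph::V(graph))
  n <- length(ids)
  best <- 0
  best_set <- character(0)
  for (m in seq_len(2^n - 1)) {
    sel <- ids[bitwAnd(m, 2^(0:(n - 1))) > 0]
    if (!igraph::is_connected(igraph::induced_subgraph(graph, sel))) next
    s <- sum(scores[sel])
    if (s > best + 1e-9) {
      best <- s
      best_set <- sel
    }
  }
  list(score = best, set = sort(best_set))
}

# Literal triangle-by-triangle DPI on the original weights.
brute_dpi <- function(graph, tolerance = 0) {
  w <- igraph::E(graph)$weight
  tri <- matrix(as.integer(igraph::triangles(graph)), nrow = 3)
  drop <- integer(0)
  for (t in seq_len(ncol(tri))) {
    v <- tri[, t]
    eids <- igraph::get_edge_ids(graph, c(v[1], v[2], v[1], v[3], v[2], v[3]))
    ew <- w[eids]
    weakest <- which.min(ew)
    if (ew[weakest] <= (1 - tolerance) * min(ew[-weakest]))
      drop <- c(drop, eids[weakest])
  }
  igraph::delete_edges(graph, unique(drop))
}

# Step-up Benjamini-Hochberg from its definition.
brute_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m))
    q[ord[i]] <- min(vapply(i:m, function(j) p[ord[j]] * m / j, numeric(1)), 1)
  q
}

# Hypergeometric upper tail by direct summation of binomial coefficients.
enum_hypergeom <- function(k, n, K, N) {
  if (k == 0) return(1)
  j <- k:min(n, K)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# Random simple graph with named vertices, for solver equivalence suites.
random_named_graph <- function(n, p) {
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("v%02d", seq_len(n))
  g
}

graph_edges_key <- function(g) {
  el <- igraph::as_edgelist(g)
  sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2])))
}
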