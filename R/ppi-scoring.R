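#' Collapse a multigraph interaction network to a simple graph
#'
#' Parallel edges (interactions with multiple evidence sources) are collapsed
#' to one and self-loops removed; the node set is unchanged.
#'
#' @param graph An igraph, possibly with multi-edges and loops.
#' @return A simple igraph.
#' @export
simplify_network <- function(graph) {
  igraph::simplify(graph, remove.multiple = TRUE, remove.loops = TRUE)
}

bum_density <- function(p, lambda, a) lambda + (1 - lambda) * a * p^(a - 1)

#' Fit a beta-uniform mixture to P-values
#'
#' Models the P-value density as \eqn{f(p) = \lambda + (1-\lambda) a
#' p^{a-1}}: a uniform noise component plus a Beta(a, 1) signal component
#' concentrated near zero. Fitted by maximum likelihood with multi-start
#' bounded (L-BFGS-B) optimization; \eqn{\lambda} is kept inside
#' `[0.01, 0.99]` to avoid the degenerate ridge at pure-uniform data.
#'
#' @param p_values Numeric vector (n >= 100) in (0, 1]; zeros are clamped to
#'   the smallest positive double with a warning.
#' @return A list of class `bum_fit`: `lambda`, `a`, `log_likelihood`.
#' @export
fit_bum <- function(p_values) {
  if (length(p_values) < 100) stop("need >= 100 P-values")
  if (any(p_values < 0 | p_values > 1)) stop("P-values must lie in [0, 1]")
  if (any(p_values == 0)) {
    warning("clamping zero P-values to the smallest positive double",
            call. = FALSE)
    p_values[p_values == 0] <- .Machine$double.xmin
  }
  if (length(unique(p_values)) == 1) stop("all P-values identical; cannot fit")
  nll <- function(par) -sum(log(bum_density(p_values, par[1], par[2])))
  starts <- expand.grid(lambda = c(0.2, 0.5, 0.8), a = c(0.1, 0.3, 0.6))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- try(stats::optim(as.numeric(starts[i, ]), nll, method = "L-BFGS-B",
                            lower = c(0.01, 1e-4), upper = c(0.99, 0.999)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("BUM optimization failed from all starts")
  structure(list(lambda = best$par[1], a = best$par[2],
                 log_likelihood = -best$value),
            class = "bum_fit")
}

#' P-value threshold attaining a target FDR under a BUM fit
#'
#' Using the conservative uniform mass \eqn{\pi = \lambda + (1-\lambda)a},
#' the threshold is \eqn{\tau = \left(\frac{\mathrm{fdr}(1-\lambda)}
#' {\pi - \mathrm{fdr}\,\lambda}\right)^{1/(1-a)}}.
#'
#' @param fit A `bum_fit`.
#' @param fdr Target false discovery rate in (0, 1).
#' @return The P-value threshold `tau`.
#' @export
fdr_threshold <- function(fit, fdr) {
  if (fdr <= 0 || fdr >= 1) stop("`fdr` must be in (0, 1)")
  pi_u <- fit$lambda + (1 - fit$lambda) * fit$a
  denom <- pi_u - fdr * fit$lambda
  if (denom <= 0) stop("requested FDR unattainable under this fit")
  (fdr * (1 - fit$lambda) / denom)^(1 / (1 - fit$a))
}

#' FDR-calibrated node scores from P-values
#'
#' Log-likelihood-ratio-style score \eqn{s(p) = (a - 1)(\ln p - \ln \tau)}:
#' zero exactly at \eqn{p = \tau}, positive for smaller P-values, strictly
#' decreasing in p.
#'
#' @param p_values Named numeric vector of node P-values.
#' @param fit A `bum_fit`.
#' @param fdr Target FDR (default 0.05).
#' @return Named numeric vector of node scores; attribute `"tau"` holds the
#'   threshold.
#' @export
score_nodes <- function(p_values, fit, fdr = 0.05) {
  if (any(p_values <= 0)) {
    warning("clamping non-positive P-values", call. = FALSE)
    p_values[p_values <= 0] <- .Machine$double.xmin
  }
  tau <- fdr_threshold(fit, fdr)
  s <- (fit$a - 1) * (log(p_values) - log(tau))
  attr(s, "tau") <- tau
  s
}

# Score of a set of vertex names under a named score vector.
set_score <- function(nodes, scores) if (length(nodes) == 0) 0 else sum(scores[nodes])

# Is candidate (score/size/ids) better than incumbent under the tie rules:
# higher score, then smaller size, then lexicographically smaller ids.
better_module <- function(score, nodes, best_score, best_nodes, tol = 1e-9) {
  if (score > best_score + tol) return(TRUE)
  if (score < best_score - tol) return(FALSE)
  if (length(nodes) != length(best_nodes))
    return(length(nodes) < length(best_nodes))
  key <- paste(sort(nodes), collapse = ",")
  bkey <- paste(sort(best_nodes), collapse = ",")
  key < bkey
}

#' Exact maximum-weight connected subgraph
#'
#' Branch-and-bound enumeration of connected vertex subsets: the bound adds
#' to the current score every positive score still admissible, and a branch
#' is cut when that bound cannot beat the incumbent. Returns the empty set
#' when no subset has positive total score. Ties are broken by smaller size,
#' then lexicographically smallest sorted ids. Enforced for graphs of at
#' most `max_nodes` (default 30) vertices; use [find_module_heuristic()]
#' beyond that.
#'
#' @param graph Simple undirected igraph with named vertices.
#' @param scores Named numeric vector of vertex scores.
#' @param max_nodes Hard size limit (default 30).
#' @return Character vector of module vertex names (possibly empty), with
#'   attribute `"score"`.
#' @export
find_module_exact <- function(graph, scores, max_nodes = 30) {
  n <- igraph::vcount(graph)
  if (n > max_nodes)
    stop("graph has ", n, " nodes (> ", max_nodes,
         "); use find_module_heuristic()")
  ids <- igraph::as_ids(igraph::V(graph))
  adj <- lapply(seq_len(n), function(i)
    as.integer(igraph::neighbors(graph, i)))
  sc <- unname(scores[ids])
  best <- list(score = 0, nodes = character(0))
  # admissible-positive bound: every vertex not yet in the set and not
  # forbidden could in principle still be added
  pos_left <- function(members, forb) sum(pmax(sc[!(members | forb)], 0))

  rec <- function(members, score, ext, forb) {
    nodes <- ids[members]
    if (better_module(score, nodes, best$score, best$nodes))
      best <<- list(score = score, nodes = nodes)
    for (k in seq_along(ext)) {
      u <- ext[k]
      forb_k <- forb
      if (k > 1) forb_k[ext[seq_len(k - 1)]] <- TRUE
      members_u <- members
      members_u[u] <- TRUE
      if (score + sc[u] + pos_left(members_u, forb_k) < best$score - 1e-9)
        next
      nb <- adj[[u]]
      nb <- nb[!members_u[nb] & !forb_k[nb]]
      ext_u <- c(ext[-seq_len(k)], setdiff(nb, ext))
      rec(members_u, score + sc[u], ext_u, forb_k)
    }
  }

  forb <- logical(n)
  for (v in order(ids)) {
    members <- logical(n)
    members[v] <- TRUE
    if (sc[v] + pos_left(members, forb) >= best$score - 1e-9) {
      nb <- adj[[v]]
      rec(members, sc[v], nb[!forb[nb] & nb != v], forb)
    }
    forb[v] <- TRUE
  }
  structure(sort(best$nodes), score = best$score)
}

#' Heuristic maximum-weight connected subgraph
#'
#' Scalable stand-in for the exact search: positive-score connected
#' components are collapsed into super-nodes; the cheapest connecting paths
#' between them (path cost = total penalty of the negative-score vertices
#' crossed) define a metric closure whose minimum spanning tree is pruned of
#' leaves that cost more to connect than they contribute. The returned set
#' is connected and its total score is never below that of the best single
#' positive component.
#'
#' @param graph Simple undirected igraph with named vertices.
#' @param scores Named numeric vector of vertex scores.
#' @return Character vector of module vertex names (possibly empty), with
#'   attribute `"score"`.
#' @export
find_module_heuristic <- function(graph, scores) {
  comps <- igraph::components(graph)
  if (comps$no > 1) {
    # solve each connected component independently, keep the best
    best <- structure(character(0), score = 0)
    for (ci in seq_len(comps$no)) {
      sub <- igraph::induced_subgraph(graph, which(comps$membership == ci))
      cand <- find_module_heuristic(sub, scores)
      if (better_module(attr(cand, "score"), cand,
                        attr(best, "score"), best))
        best <- cand
    }
    return(best)
  }
  ids <- igraph::as_ids(igraph::V(graph))
  sc <- scores[ids]
  pos <- ids[sc > 0]
  if (length(pos) == 0) return(structure(character(0), score = 0))
  sub <- igraph::induced_subgraph(graph, pos)
  comp <- igraph::components(sub)
  comp_nodes <- split(igraph::V(sub)$name, comp$membership)
  comp_wt <- vapply(comp_nodes, function(x) sum(sc[x]), numeric(1))
  # single component: nothing to connect
  best_single <- comp_nodes[[which.max(comp_wt)]]
  if (length(comp_nodes) == 1)
    return(structure(sort(best_single), score = sum(sc[best_single])))

  # directed cost graph: entering vertex v costs max(-score(v), 0)
  cost <- pmax(-sc, 0)
  dg <- igraph::as_directed(graph, mode = "mutual")
  ew <- cost[igraph::as_edgelist(dg)[, 2]]
  reps <- vapply(comp_nodes, `[`, character(1), 1)
  D <- igraph::distances(dg, v = reps, to = reps, mode = "out", weights = ew)
  k <- length(reps)
  # explicit complete closure graph: zero-cost connections (via zero-score
  # vertices) are legitimate edges and must not be dropped
  closure <- igraph::make_full_graph(k)
  igraph::V(closure)$name <- as.character(seq_len(k))
  cel <- igraph::as_edgelist(closure)
  igraph::E(closure)$weight <- D[cbind(as.integer(cel[, 1]),
                                       as.integer(cel[, 2]))]
  tree <- igraph::mst(closure, weights = igraph::E(closure)$weight)
  # prune leaves whose connection cost exceeds their contribution
  repeat {
    deg <- igraph::degree(tree)
    if (igraph::vcount(tree) <= 1) break
    leaf_ids <- igraph::V(tree)$name[deg == 1]
    cut <- leaf_ids[vapply(leaf_ids, function(l) {
      e <- igraph::incident(tree, l)
      comp_wt[as.integer(l)] - igraph::E(tree)$weight[as.integer(e)] < 0
    }, logical(1))]
    # never prune everything: keep the heaviest component
    cut <- setdiff(cut, as.character(which.max(comp_wt)))
    if (length(cut) == 0) break
    tree <- igraph::delete_vertices(tree, cut)
  }
  keep <- as.integer(igraph::V(tree)$name)
  nodes <- unlist(comp_nodes[keep], use.names = FALSE)
  if (igraph::ecount(tree) > 0) {
    te <- igraph::as_edgelist(tree)
    for (i in seq_len(nrow(te))) {
      a <- reps[as.integer(te[i, 1])]
      b <- reps[as.integer(te[i, 2])]
      sp <- igraph::shortest_paths(dg, from = a, to = b, mode = "out",
                                   weights = ew)$vpath[[1]]
      nodes <- union(nodes, igraph::as_ids(sp))
    }
  }
  total <- sum(sc[nodes])
  single <- sum(sc[best_single])
  if (single > total) {
    nodes <- best_single
    total <- single
  }
  structure(sort(nodes), score = total)
}
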