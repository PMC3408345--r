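#' MCODE vertex weight
#'
#' Weight of a vertex is `k_max` times the density of the highest k-core of
#' its closed neighborhood (the vertex plus its neighbors): dense local
#' neighborhoods score high, a degree-1 vertex's closed neighborhood is a
#' single edge (weight 1), an isolated vertex scores 0. Density is
#' `2m / (n (n - 1))` on the simple core subgraph.
#'
#' @param graph Simple undirected igraph.
#' @param v Vertex name or index.
#' @return The vertex weight (>= 0).
#' @export
vertex_weight <- function(graph, v) {
  nb <- igraph::neighbors(graph, v)
  if (length(nb) == 0) return(0)
  closed <- unique(c(igraph::as_ids(igraph::V(graph)[v]), igraph::as_ids(nb)))
  sub <- igraph::induced_subgraph(graph, closed)
  core <- igraph::coreness(sub)
  kmax <- max(core)
  if (kmax == 0) return(0)
  core_sub <- igraph::induced_subgraph(sub, which(core >= kmax))
  n <- igraph::vcount(core_sub)
  dens <- if (n < 2) 0 else 2 * igraph::ecount(core_sub) / (n * (n - 1))
  kmax * dens
}

vertex_weights <- function(graph) {
  vapply(igraph::as_ids(igraph::V(graph)), function(v) vertex_weight(graph, v),
         numeric(1))
}

#' MCODE dense-complex detection
#'
#' Re-implementation of the MCODE procedure: vertices are weighted by
#' [vertex_weight()]; complexes are grown from seed vertices in decreasing
#' weight order (ties broken by lexicographically smallest id) by
#' breadth-first expansion that admits a neighbor when its weight is at least
#' `seed_weight * (1 - vwp)`; each vertex belongs to at most one complex.
#' Post-processing optionally "fluffs" the complex with boundary vertices
#' whose closed-neighborhood density exceeds `fluff_density`, then the
#' "haircut" reduces the complex to its 2-core (removing tree-like fringe).
#' Complexes that contain no 2-core are discarded. Complexes are ranked by
#' score = density x size, descending, ties by smallest member id.
#'
#' @param graph Simple undirected igraph.
#' @param vwp Vertex weight percentage in `[0, 1]` (default 0.2, the plugin
#'   default).
#' @param haircut Reduce each complex to its 2-core (default TRUE).
#' @param fluff Add dense boundary vertices (default FALSE); fluffed
#'   complexes may overlap.
#' @param fluff_density Closed-neighborhood density threshold for fluff.
#' @param degree_cutoff Minimum degree for seed vertices (default 2).
#' @return A data.frame of class `mcode_result`, one row per complex:
#'   `rank`, `score`, `size`, `members` (comma-joined sorted ids).
#' @export
find_complexes <- function(graph, vwp = 0.2, haircut = TRUE, fluff = FALSE,
                           fluff_density = 0.1, degree_cutoff = 2) {
  if (vwp < 0 || vwp > 1) stop("`vwp` must be in [0, 1]")
  ids <- igraph::as_ids(igraph::V(graph))
  if (is.null(igraph::V(graph)$name)) {
    graph <- igraph::set_vertex_attr(graph, "name",
                                     value = as.character(seq_len(igraph::vcount(graph))))
    ids <- igraph::V(graph)$name
  }
  w <- vertex_weights(graph)
  deg <- igraph::degree(graph)
  visited <- stats::setNames(logical(length(ids)), ids)
  seed_order <- ids[order(-w, ids)]
  complexes <- list()
  for (seed in seed_order) {
    if (visited[seed] || deg[seed] < degree_cutoff) next
    threshold <- w[seed] * (1 - vwp)
    members <- seed
    visited[seed] <- TRUE
    frontier <- seed
    while (length(frontier) > 0) {
      nbrs <- unique(unlist(lapply(frontier, function(v)
        igraph::as_ids(igraph::neighbors(graph, v)))))
      nbrs <- sort(nbrs[!visited[nbrs] & w[nbrs] >= threshold])
      visited[nbrs] <- TRUE
      members <- c(members, nbrs)
      frontier <- nbrs
    }
    if (length(members) < 2) next
    if (fluff) {
      boundary <- setdiff(unique(unlist(lapply(members, function(v)
        igraph::as_ids(igraph::neighbors(graph, v))))), members)
      dens <- vapply(boundary, function(v) {
        closed <- c(v, igraph::as_ids(igraph::neighbors(graph, v)))
        sub <- igraph::induced_subgraph(graph, closed)
        n <- igraph::vcount(sub)
        if (n < 2) 0 else 2 * igraph::ecount(sub) / (n * (n - 1))
      }, numeric(1))
      members <- c(members, boundary[dens > fluff_density])
    }
    sub <- igraph::induced_subgraph(graph, members)
    if (haircut) {
      core <- igraph::coreness(sub)
      sub <- igraph::induced_subgraph(sub, which(core >= 2))
    }
    if (igraph::vcount(sub) < 2 || max(igraph::coreness(sub)) < 2) next
    mem <- sort(igraph::V(sub)$name)
    n <- length(mem)
    dens <- 2 * igraph::ecount(sub) / (n * (n - 1))
    complexes[[length(complexes) + 1]] <- list(members = mem,
                                               score = dens * n, size = n)
  }
  if (length(complexes) == 0) {
    out <- data.frame(rank = integer(), score = numeric(), size = integer(),
                      members = character(), stringsAsFactors = FALSE)
  } else {
    out <- data.frame(
      score = vapply(complexes, `[[`, numeric(1), "score"),
      size = vapply(complexes, `[[`, integer(1), "size"),
      members = vapply(complexes, function(x) paste(x$members, collapse = ","),
                       character(1)),
      stringsAsFactors = FALSE)
    out <- out[order(-out$score, out$members), , drop = FALSE]
    out <- cbind(rank = seq_len(nrow(out)), out)
    rownames(out) <- NULL
  }
  class(out) <- c("mcode_result", "data.frame")
  out
}

#' Member ids of a ranked MCODE complex
#' @param result An `mcode_result`.
#' @param rank Complex rank (default 1).
#' @return Character vector of member ids.
#' @export
complex_members <- function(result, rank = 1) {
  strsplit(result$members[result$rank == rank], ",")[[1]]
}
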