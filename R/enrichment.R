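#' Hypergeometric over-representation P-value
#'
#' Exact upper-tail probability \eqn{P(X \ge k)} for
#' \eqn{X \sim \mathrm{Hypergeom}(N, K, n)}: drawing a list of `n` genes
#' from a universe of `N` of which `K` belong to the set, the chance of
#' observing `k` or more set members.
#'
#' @param k Observed overlap.
#' @param n List size.
#' @param K Set size within the universe.
#' @param N Universe size.
#' @return Upper-tail P-value in (0, 1].
#' @export
hypergeom_test <- function(k, n, K, N) {
  if (k < 0 || n < 0 || K < 0 || N < 0 || k > min(n, K) || n > N || K > N)
    stop("inconsistent hypergeometric counts")
  if (k == 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Over-representation analysis of a gene list
#'
#' One hypergeometric upper-tail test per gene set; genes outside the
#' universe are dropped with a warning and duplicates de-duplicated. The
#' table is sorted by P-value (ties by term id).
#'
#' @param gene_list Character vector of query genes.
#' @param collection A [geneset_collection].
#' @param universe Character vector; defaults to the collection's universe.
#' @return A `data.frame` of class `enrichment_table`: `term`, `k`
#'   (overlap), `n` (list size), `K` (set size), `N` (universe size),
#'   `p_value`, `genes` (comma-joined supporting genes), `category`.
#' @export
ora <- function(gene_list, collection, universe = collection$universe) {
  if (is.null(universe) || length(universe) == 0) stop("empty universe")
  gene_list <- unique(gene_list)
  out <- setdiff(gene_list, universe)
  if (length(out) > 0) {
    warning("dropping query genes outside the universe: ",
            paste(utils::head(out, 5), collapse = ", "), call. = FALSE)
    gene_list <- intersect(gene_list, universe)
  }
  n <- length(gene_list)
  N <- length(unique(universe))
  rows <- lapply(names(collection$sets), function(term) {
    set <- intersect(collection$sets[[term]], universe)
    hits <- sort(intersect(gene_list, set))
    data.frame(term = term, k = length(hits), n = n, K = length(set), N = N,
               p_value = hypergeom_test(length(hits), n, length(set), N),
               genes = paste(hits, collapse = ","),
               category = if (term %in% names(collection$categories))
                 collection$categories[[term]] else NA_character_,
               stringsAsFactors = FALSE)
  })
  tab <- if (length(rows) == 0) {
    data.frame(term = character(), k = integer(), n = integer(),
               K = integer(), N = integer(), p_value = numeric(),
               genes = character(), category = character(),
               stringsAsFactors = FALSE)
  } else do.call(rbind, rows)
  tab <- tab[order(tab$p_value, tab$term), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "collection_id") <- collection_id(collection)
  class(tab) <- c("enrichment_table", "data.frame")
  tab
}

collection_id <- function(collection) {
  paste(names(collection$sets), vapply(collection$sets, length, 1L),
        collapse = ";")
}

#' Ontology-conditional over-representation analysis
#'
#' Terms are tested children before parents; when a term is reached, genes
#' annotated to any of its already-significant (p < `alpha`) descendants are
#' removed both from the term's annotation set and from the query overlap
#' before the hypergeometric test, so a parent is only called significant on
#' evidence not already explained below it.
#'
#' @param gene_list Character vector of query genes.
#' @param dag An [ontology_dag].
#' @param universe Character vector of testable genes.
#' @param alpha Significance level used for conditioning (default 0.05).
#' @return An `enrichment_table` (one row per term), sorted by P-value.
#' @export
conditional_ora <- function(gene_list, dag, universe, alpha = 0.05) {
  if (is.null(universe) || length(universe) == 0) stop("empty universe")
  gene_list <- intersect(unique(gene_list), universe)
  n <- length(gene_list)
  N <- length(unique(universe))
  ord <- topo_sort_terms(dag$terms, dag$parents)  # children before parents
  sig <- character(0)
  rows <- list()
  for (term in ord) {
    ann <- intersect(dag$annotations[[term]], universe)
    sig_desc <- intersect(dag_descendants(dag, term), sig)
    removed <- unique(unlist(dag$annotations[sig_desc], use.names = FALSE))
    ann_c <- setdiff(ann, removed)
    hits <- sort(intersect(gene_list, ann_c))
    p <- hypergeom_test(length(hits), n, length(ann_c), N)
    if (p < alpha) sig <- c(sig, term)
    rows[[term]] <- data.frame(term = term, k = length(hits), n = n,
                               K = length(ann_c), N = N, p_value = p,
                               genes = paste(hits, collapse = ","),
                               category = NA_character_,
                               stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows[dag$terms])
  tab <- tab[order(tab$p_value, tab$term), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "collection_id") <- paste("dag", length(dag$terms))
  class(tab) <- c("enrichment_table", "data.frame")
  tab
}

#' Filter enrichment tables by category and supporting-gene count
#'
#' Applies the reporting filters used before cross-module comparison:
#' terms in excluded categories are dropped unless explicitly excepted (e.g.
#' dropping disease pathways except 'Asthma'); terms supported by fewer than
#' `min_support` genes in the module where they were called are dropped; and
#' modules left without any genes annotated to a surviving term are removed
#' from the result.
#'
#' @param tables Named list of `enrichment_table`s, one per module.
#' @param excluded_categories Character vector of category labels to drop.
#' @param exceptions Term names kept even if their category is excluded.
#' @param min_support Minimum supporting genes per term (default 2).
#' @return A list with `tables` (filtered, same names for retained modules)
#'   and `retained_modules` (character vector).
#' @export
filter_pathways <- function(tables, excluded_categories = character(),
                            exceptions = character(), min_support = 2) {
  filtered <- lapply(tables, function(tab) {
    drop_cat <- !is.na(tab$category) &
      tab$category %in% excluded_categories & !(tab$term %in% exceptions)
    tab <- tab[!drop_cat & tab$k >= min_support, , drop = FALSE]
    rownames(tab) <- NULL
    tab
  })
  retained <- names(filtered)[vapply(filtered, function(tab)
    nrow(tab) > 0 && any(tab$k > 0), logical(1))]
  list(tables = filtered[retained], retained_modules = retained)
}

#' Hierarchical clustering of terms by gene-count profiles
#'
#' Groups terms by the similarity of their per-module gene counts:
#' agglomerative clustering (average linkage) with distance 1 - Pearson
#' correlation across the module profiles, as used to order the rows of a
#' term-by-module heatmap. Constant profiles are assigned the maximal
#' distance (2) to every other term, with a warning.
#'
#' @param count_matrix Numeric matrix, terms x modules.
#' @return A list with `order` (term ids, leaf order), `merge_heights`
#'   (hclust heights) and `hclust` (the full tree).
#' @export
cluster_terms <- function(count_matrix) {
  if (nrow(count_matrix) < 2) stop("need at least 2 terms")
  const <- apply(count_matrix, 1, function(x) stats::sd(x) == 0)
  cm <- suppressWarnings(stats::cor(t(count_matrix)))
  d <- 1 - cm
  if (any(const)) {
    warning("constant term profile(s) assigned maximal distance", call. = FALSE)
    d[const, ] <- 2
    d[, const] <- 2
  }
  diag(d) <- 0
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  list(order = rownames(count_matrix)[hc$order],
       merge_heights = hc$height,
       hclust = hc)
}
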