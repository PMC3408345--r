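#' Pathways significantly enriched in both of two modules
#'
#' @param tableA,tableB `enrichment_table`s computed against the same
#'   collection.
#' @param alpha Significance level (default 0.05).
#' @return Sorted character vector of terms with `p_value < alpha` in both.
#' @export
common_terms <- function(tableA, tableB, alpha = 0.05) {
  ia <- attr(tableA, "collection_id")
  ib <- attr(tableB, "collection_id")
  if (!is.null(ia) && !is.null(ib) && !identical(ia, ib))
    stop("enrichment tables were computed against different collections")
  sort(intersect(tableA$term[tableA$p_value < alpha],
                 tableB$term[tableB$p_value < alpha]))
}

#' Permutation null for pathways common to two modules
#'
#' Draws, `N` times, two independent random gene lists (without replacement
#' within each list) of the observed module sizes from the universe, repeats
#' the observed analysis on each pair — over-representation testing, the
#' supporting-gene and category filters, and the intersection of significant
#' terms — and reports, per target term, the empirical probability
#' `p = n / N` of appearing as common by chance. Zero counts are reported as
#' `p = 0` (the resolution floor is `1/N`); a `(n+1)/(N+1)` corrected
#' estimate is also given.
#'
#' @param universe Character vector the random lists are drawn from.
#' @param size_A,size_B Sizes of the two random lists.
#' @param collection A [geneset_collection].
#' @param target_terms Terms whose chance co-occurrence is being assessed.
#' @param N Number of permutations (default 1000).
#' @param alpha Significance level used inside each iteration (default 0.05).
#' @param min_support Supporting-gene filter applied inside each iteration.
#' @param excluded_categories,exceptions Category filter, as in
#'   [filter_pathways()].
#' @param seed Integer seed.
#' @return A `data.frame` of class `common_pathways_result`: `term`, `n`,
#'   `N`, `p`, `p_corrected`; attributes `size_A`, `size_B`, `seed`.
#' @export
permutation_p <- function(universe, size_A, size_B, collection, target_terms,
                          N = 1000, alpha = 0.05, min_support = 2,
                          excluded_categories = character(),
                          exceptions = character(), seed) {
  if (missing(seed)) stop("`seed` is required")
  if (N < 1) stop("`N` must be >= 1")
  universe <- unique(universe)
  if (size_A > length(universe) || size_B > length(universe))
    stop("list size exceeds the universe")
  set.seed(as.integer(seed))
  # membership matrix: sets x universe, for fast per-iteration overlap counts
  sets <- lapply(collection$sets, intersect, y = universe)
  K <- vapply(sets, length, 1L)
  M <- do.call(rbind, lapply(sets, function(s) universe %in% s))
  Nuni <- length(universe)
  cat_drop <- if (length(names(collection$categories)) > 0) {
    names(collection$sets) %in%
      names(collection$categories)[collection$categories %in% excluded_categories] &
      !(names(collection$sets) %in% exceptions)
  } else rep(FALSE, length(sets))

  sig_terms <- function(idx, size) {
    k <- as.integer(M[, idx, drop = FALSE] %*% rep(1L, size))
    p <- stats::phyper(k - 1, K, Nuni - K, size, lower.tail = FALSE)
    p[k == 0] <- 1
    names(collection$sets)[p < alpha & k >= min_support & !cat_drop]
  }
  counts <- stats::setNames(integer(length(target_terms)), target_terms)
  for (i in seq_len(N)) {
    a <- sample.int(Nuni, size_A)
    b <- sample.int(Nuni, size_B)
    common <- intersect(sig_terms(a, size_A), sig_terms(b, size_B))
    hit <- target_terms %in% common
    counts[hit] <- counts[hit] + 1L
  }
  out <- data.frame(term = target_terms, n = unname(counts), N = N,
                    p = unname(counts) / N,
                    p_corrected = (unname(counts) + 1) / (N + 1),
                    stringsAsFactors = FALSE)
  if (any(out$n == 0))
    message("terms never observed as common; the empirical resolution floor is 1/",
            N)
  attr(out, "size_A") <- size_A
  attr(out, "size_B") <- size_B
  attr(out, "seed") <- seed
  class(out) <- c("common_pathways_result", "data.frame")
  out
}
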