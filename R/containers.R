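#' Expression study container
#'
#' Bundles a log2 expression matrix (genes x samples) with per-sample
#' annotations. Every subject must contribute exactly one `pre` and one
#' `post` sample for baseline correction to be defined; construction only
#' checks basic consistency so partially paired studies can still be filtered.
#'
#' @param matrix Numeric matrix, gene rows (rownames) x sample columns
#'   (colnames matching `samples$sample_id`).
#' @param samples data.frame with columns `sample_id`, `subject_id`,
#'   `timepoint` (`pre`/`post`), `arm` (`treated`/`placebo`), `sex` (`M`/`F`),
#'   `age`.
#' @return An object of class `expression_study`.
#' @export
expression_study <- function(matrix, samples) {
  stopifnot(is.matrix(matrix), is.numeric(matrix))
  if (nrow(matrix) > 0 && is.null(rownames(matrix)))
    stop("expression matrix needs gene rownames")
  if (anyDuplicated(rownames(matrix))) stop("duplicate gene ids")
  req <- c("sample_id", "subject_id", "timepoint", "arm", "sex", "age")
  miss <- setdiff(req, names(samples))
  if (length(miss) > 0)
    stop("sample annotations missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample ids")
  if (!setequal(colnames(matrix), samples$sample_id))
    stop("matrix columns and annotation sample_ids disagree")
  if (!all(samples$timepoint %in% c("pre", "post")))
    stop("timepoint must be 'pre' or 'post'")
  if (!all(is.finite(matrix))) stop("expression values must be finite")
  samples <- samples[match(colnames(matrix), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  structure(list(matrix = matrix, samples = samples),
            class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  cat("expression_study:", nrow(x$matrix), "genes x", ncol(x$matrix),
      "samples (", length(unique(x$samples$subject_id)), "subjects )\n")
  invisible(x)
}

#' Baseline-corrected delta matrix container
#'
#' Genes x subjects matrix of post-minus-pre log2 differences, with
#' per-subject annotations (arm, sex, age).
#'
#' @param matrix Numeric matrix, genes x subjects.
#' @param subjects data.frame with `subject_id`, `arm`, `sex`, `age`.
#' @return An object of class `delta_matrix`.
#' @export
delta_matrix <- function(matrix, subjects) {
  stopifnot(is.matrix(matrix), is.numeric(matrix))
  if (!setequal(colnames(matrix), subjects$subject_id))
    stop("matrix columns and subject annotations disagree")
  subjects <- subjects[match(colnames(matrix), subjects$subject_id), , drop = FALSE]
  rownames(subjects) <- NULL
  structure(list(matrix = matrix, subjects = subjects),
            class = "delta_matrix")
}

#' @export
print.delta_matrix <- function(x, ...) {
  cat("delta_matrix:", nrow(x$matrix), "genes x", ncol(x$matrix), "subjects\n")
  invisible(x)
}

#' Gene-set collection container
#'
#' @param sets Named list of character vectors (gene ids).
#' @param categories Optional named character vector of category labels.
#' @param universe Optional character vector; members outside it are dropped
#'   with a warning, matching the behavior of over-representation testing.
#' @return An object of class `geneset_collection`.
#' @export
geneset_collection <- function(sets, categories = character(), universe = NULL) {
  stopifnot(is.list(sets))
  if (length(sets) > 0 && is.null(names(sets))) stop("sets must be named")
  if (!is.null(universe)) {
    sets <- lapply(sets, function(s) {
      out <- setdiff(s, universe)
      if (length(out) > 0)
        warning("dropping genes outside the universe: ",
                paste(utils::head(out, 5), collapse = ", "), call. = FALSE)
      intersect(s, universe)
    })
  }
  structure(list(sets = sets,
                 categories = categories,
                 universe = universe),
            class = "geneset_collection")
}

#' @export
print.geneset_collection <- function(x, ...) {
  cat("geneset_collection:", length(x$sets), "sets")
  if (!is.null(x$universe)) cat(" over", length(x$universe), "genes")
  cat("\n")
  invisible(x)
}

#' Ontology DAG container
#'
#' Acyclic child-to-parent term graph with per-term gene annotations. When
#' `propagate = TRUE`, annotations are propagated upward so every parent's
#' set contains the union of its children's. Construction fails on cycles.
#'
#' @param terms Character vector of term ids.
#' @param parents Named list mapping each term to its parent term ids (the
#'   root has none).
#' @param annotations Named list of gene vectors (direct annotations).
#' @param propagate Propagate annotations upward (default TRUE).
#' @return An object of class `ontology_dag` with `terms`, `parents`,
#'   `children`, `annotations`, `root`.
#' @export
ontology_dag <- function(terms, parents, annotations, propagate = TRUE) {
  parents <- parents[terms]
  names(parents) <- terms
  dangling <- setdiff(unlist(parents), terms)
  if (length(dangling) > 0)
    stop("parents reference unknown terms: ", paste(dangling, collapse = ", "))
  ord <- topo_sort_terms(terms, parents)  # children before parents; errors on cycles
  roots <- terms[vapply(parents, length, 1L) == 0]
  if (length(roots) != 1)
    stop("DAG must have exactly one root, found: ", length(roots))
  ann <- lapply(terms, function(t) sort(unique(annotations[[t]])))
  names(ann) <- terms
  children <- stats::setNames(vector("list", length(terms)), terms)
  for (child in terms)
    for (p in parents[[child]])
      children[[p]] <- c(children[[p]], child)
  if (propagate) {
    for (t in ord)  # children first, so unions accumulate upward
      for (p in parents[[t]])
        annotations[[p]] <- union(annotations[[p]], annotations[[t]])
    ann <- lapply(annotations[terms], function(x) sort(unique(x)))
    names(ann) <- terms
  }
  structure(list(terms = terms, parents = parents, children = children,
                 annotations = ann, root = roots),
            class = "ontology_dag")
}

# Kahn topological sort in children-before-parents order (edges child -> parent).
topo_sort_terms <- function(terms, parents) {
  indeg <- stats::setNames(integer(length(terms)), terms)  # children count
  for (child in terms)
    for (p in parents[[child]]) indeg[p] <- indeg[p] + 1L
  queue <- terms[indeg == 0]
  out <- character(0)
  while (length(queue) > 0) {
    t <- queue[1]; queue <- queue[-1]
    out <- c(out, t)
    for (p in parents[[t]]) {
      indeg[p] <- indeg[p] - 1L
      if (indeg[p] == 0L) queue <- c(queue, p)
    }
  }
  if (length(out) != length(terms)) stop("cycle detected in ontology DAG")
  out
}

#' Descendants of a term (children-edge closure, excluding the term itself)
#' @param dag An `ontology_dag`.
#' @param term Term id.
#' @return Character vector of descendant term ids.
#' @export
dag_descendants <- function(dag, term) {
  seen <- character(0)
  frontier <- dag$children[[term]]
  while (length(frontier) > 0) {
    frontier <- setdiff(unique(frontier), seen)
    seen <- c(seen, frontier)
    frontier <- unlist(dag$children[frontier], use.names = FALSE)
  }
  sort(seen)
}
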