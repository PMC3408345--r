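#' Read and write the pipeline's tabular formats
#'
#' All files are UTF-8 tab-separated. The expression matrix has a header of
#' sample ids and gene ids in the first column; the annotation table has
#' columns `sample_id`, `subject_id`, `timepoint`, `arm`, `sex`, `age`;
#' edge lists have three columns `node_a`, `node_b`, `weight`; GMT lines are
#' `name<TAB>description<TAB>gene...`; the ontology is a child/parent TSV
#' plus a term/gene annotation TSV. Readers reject malformed rows with
#' line-numbered errors; writers are the exact inverses on valid objects.
#'
#' @param study An [expression_study].
#' @param path File path.
#' @name io
NULL

#' @rdname io
#' @export
write_expression_tsv <- function(study, path) {
  df <- data.frame(gene = rownames(study$matrix), study$matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @param annotation_path Path of the sample annotation TSV.
#' @export
write_study <- function(study, path, annotation_path) {
  write_expression_tsv(study, path)
  utils::write.table(study$samples, annotation_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_study <- function(path, annotation_path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (names(tab)[1] != "gene") stop("expression TSV must start with a 'gene' column")
  if (anyDuplicated(tab$gene))
    stop("duplicate gene ids at lines: ",
         paste(which(duplicated(tab$gene)) + 1, collapse = ", "))
  mat <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- which(apply(tab[, -1, drop = FALSE], 1,
                       function(r) any(is.na(suppressWarnings(as.numeric(r))))))
    stop("non-numeric matrix cells at lines: ",
         paste(utils::head(bad + 1, 5), collapse = ", "))
  }
  rownames(mat) <- tab$gene
  ann <- utils::read.table(annotation_path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  expression_study(mat, ann)
}

#' @rdname io
#' @param graph An igraph; unweighted edges are written with weight 1.
#' @export
write_edgelist_tsv <- function(graph, path) {
  el <- igraph::as_edgelist(graph)
  w <- if ("weight" %in% igraph::edge_attr_names(graph))
    igraph::E(graph)$weight else rep(1, nrow(el))
  df <- data.frame(node_a = el[, 1], node_b = el[, 2], weight = w,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @param simple Reject self-loops (default TRUE); otherwise they are
#'   flagged with a warning and kept.
#' @export
read_edgelist_tsv <- function(path, simple = TRUE) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (!all(c("node_a", "node_b", "weight") %in% names(df)))
    stop("edge list needs columns node_a, node_b, weight")
  loops <- which(df$node_a == df$node_b)
  if (length(loops) > 0) {
    if (simple)
      stop("self-loop(s) at lines: ", paste(loops + 1, collapse = ", "))
    warning("self-loop(s) at lines: ", paste(loops + 1, collapse = ", "),
            call. = FALSE)
  }
  g <- igraph::graph_from_data_frame(df[, c("node_a", "node_b")],
                                     directed = FALSE)
  igraph::E(g)$weight <- df$weight
  g
}

#' @rdname io
#' @param collection A [geneset_collection].
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(nm) {
    desc <- if (nm %in% names(collection$categories))
      collection$categories[[nm]] else "na"
    paste(c(nm, desc, collection$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname io
#' @param universe Optional universe to attach to the read collection.
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  categories <- character()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      stop("GMT line ", i, " has fewer than 3 fields")
    sets[[fields[1]]] <- fields[-(1:2)]
    if (fields[2] != "na") categories[fields[1]] <- fields[2]
  }
  geneset_collection(sets, categories = categories, universe = universe)
}

#' @rdname io
#' @param dag An [ontology_dag].
#' @param annotation_path Path of the term-to-gene annotation TSV.
#' @export
write_dag <- function(dag, path, annotation_path) {
  edges <- do.call(rbind, lapply(names(dag$parents), function(child) {
    if (length(dag$parents[[child]]) == 0) return(NULL)
    data.frame(child = child, parent = dag$parents[[child]],
               stringsAsFactors = FALSE)
  }))
  utils::write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  ann <- do.call(rbind, lapply(names(dag$annotations), function(t) {
    if (length(dag$annotations[[t]]) == 0) return(NULL)
    data.frame(term = t, gene = dag$annotations[[t]], stringsAsFactors = FALSE)
  }))
  utils::write.table(ann, annotation_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_dag <- function(path, annotation_path) {
  edges <- utils::read.table(path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
  ann <- utils::read.table(annotation_path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  terms <- sort(unique(c(edges$child, edges$parent, ann$term)))
  dangling <- setdiff(c(edges$child, edges$parent), terms)
  if (length(dangling) > 0)
    stop("dangling DAG references: ", paste(dangling, collapse = ", "))
  parents <- stats::setNames(vector("list", length(terms)), terms)
  for (i in seq_len(nrow(edges)))
    parents[[edges$child[i]]] <- c(parents[[edges$child[i]]], edges$parent[i])
  annotations <- split(ann$gene, factor(ann$term, levels = terms))
  ontology_dag(terms, parents, annotations, propagate = FALSE)
}

#' @rdname io
#' @param x Any data.frame result (enrichment table, DE table, ...).
#' @export
write_results_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @param provenance Named list of parameters/seeds to record.
#' @export
write_provenance <- function(provenance, path) {
  jsonlite::write_json(provenance, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
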