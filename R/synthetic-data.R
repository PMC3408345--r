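#' Simulate a paired two-arm expression study
#'
#' Generates a log2 expression matrix for a randomized two-arm (treated vs
#' placebo) design with one pre- and one post-treatment array per subject,
#' emulating an airway-epithelium microarray study. Co-expression structure is
#' planted through a per-subject latent factor shared by all genes of a module:
#' for a gene in module \eqn{m} the post-minus-pre difference of subject
#' \eqn{s} is \eqn{\sqrt{r}\,f_{m,s} + \sqrt{1-r}\,\epsilon} (both standard
#' normal, scaled by `noise_sd`), so the expected pairwise correlation of
#' baseline-corrected profiles within a module equals `within_module_corr`.
#' Treatment-responsive genes gain a mean post-minus-pre shift of
#' `effect_size` in the treated arm only. One gene is a sex marker expressed
#' in females only (log2 intensities ~ Normal(10, 1) in females, Normal(5,
#' 0.5) in males), mimicking the bimodal XIST distribution used to set a
#' background threshold.
#'
#' @param n_subjects Even number of subjects; half are randomized to each arm.
#' @param n_genes Total genes including the sex marker.
#' @param module_sizes Integer vector of planted co-expression module sizes.
#' @param within_module_corr Target pairwise correlation of baseline-corrected
#'   profiles within a module, in `[0, 1)`.
#' @param effect_size Mean treated-arm post-minus-pre shift (log2 units) for
#'   the planted differentially expressed genes.
#' @param n_de_genes Number of planted treatment-responsive genes (drawn from
#'   genes outside the modules and the marker when possible).
#' @param noise_sd Standard deviation of measurement noise on the log2 scale.
#' @param seed Integer seed; all draws are reproducible from it.
#'
#' @return A list with components `study` (an [expression_study]) and `truth`
#'   (a `study_truth` list: `de_genes`, `module_assignments`, `marker_gene`,
#'   `effect_size`, `arm_of_subject`).
#' @export
generate_study <- function(n_subjects, n_genes, module_sizes = integer(),
                           within_module_corr = 0, effect_size = 0,
                           n_de_genes = 0, noise_sd = 1, seed) {
  if (missing(seed)) stop("`seed` is required for reproducibility")
  if (n_subjects < 2 || n_subjects %% 2 != 0)
    stop("`n_subjects` must be even and >= 2")
  if (n_genes < 1) stop("`n_genes` must be positive")
  if (any(module_sizes < 2)) stop("every module must have >= 2 genes")
  if (sum(module_sizes) + 1 > n_genes)
    stop("sum(module_sizes) + 1 exceeds `n_genes` (one slot is reserved for the marker gene)")
  if (n_de_genes > n_genes) stop("`n_de_genes` exceeds `n_genes`")
  if (within_module_corr < 0 || within_module_corr >= 1)
    stop("`within_module_corr` must be in [0, 1)")
  if (noise_sd <= 0) stop("`noise_sd` must be positive")

  set.seed(as.integer(seed))
  genes <- sprintf("g%05d", seq_len(n_genes))
  subjects <- sprintf("s%03d", seq_len(n_subjects))
  arm <- sample(rep(c("treated", "placebo"), n_subjects / 2))
  # guarantee both sexes so a marker threshold is always estimable
  sex <- sample(c("M", "F", sample(c("M", "F"), n_subjects - 2, replace = TRUE)))
  age <- round(stats::runif(n_subjects, 18, 65))

  marker <- genes[n_genes]
  module_assignments <- stats::setNames(integer(n_genes), genes)
  idx <- 1L
  for (m in seq_along(module_sizes)) {
    module_assignments[idx:(idx + module_sizes[m] - 1L)] <- m
    idx <- idx + module_sizes[m]
  }
  module_assignments[marker] <- 0L

  free <- genes[module_assignments == 0L & genes != marker]
  de_pool <- if (length(free) >= n_de_genes) free else setdiff(genes, marker)
  de_genes <- if (n_de_genes > 0) sort(sample(de_pool, n_de_genes)) else character()

  mu <- stats::rnorm(n_genes, mean = 7, sd = 1.5)
  pre <- matrix(stats::rnorm(n_genes * n_subjects, mean = mu, sd = noise_sd),
                nrow = n_genes)

  r <- within_module_corr
  eps <- matrix(stats::rnorm(n_genes * n_subjects), nrow = n_genes)
  delta <- sqrt(1 - r * (module_assignments > 0)) * eps
  if (length(module_sizes) > 0 && r > 0) {
    f <- matrix(stats::rnorm(length(module_sizes) * n_subjects),
                nrow = length(module_sizes))
    in_mod <- module_assignments > 0
    delta[in_mod, ] <- delta[in_mod, ] +
      sqrt(r) * f[module_assignments[in_mod], , drop = FALSE]
  }
  delta <- delta * noise_sd
  if (length(de_genes) > 0 && effect_size != 0) {
    treated <- arm == "treated"
    delta[match(de_genes, genes), treated] <-
      delta[match(de_genes, genes), treated] + effect_size
  }
  post <- pre + delta

  # sex marker overrides both arrays of each subject
  mi <- match(marker, genes)
  high <- sex == "F"
  pre[mi, ] <- ifelse(high, stats::rnorm(n_subjects, 10, 1),
                      stats::rnorm(n_subjects, 5, 0.5))
  post[mi, ] <- ifelse(high, stats::rnorm(n_subjects, 10, 1),
                       stats::rnorm(n_subjects, 5, 0.5))

  mat <- cbind(pre, post)
  colnames(mat) <- c(paste0(subjects, "_pre"), paste0(subjects, "_post"))
  rownames(mat) <- genes
  samples <- data.frame(
    sample_id = colnames(mat),
    subject_id = rep(subjects, 2),
    timepoint = rep(c("pre", "post"), each = n_subjects),
    arm = rep(arm, 2),
    sex = rep(sex, 2),
    age = rep(age, 2),
    stringsAsFactors = FALSE
  )
  study <- expression_study(mat, samples)
  truth <- list(
    de_genes = de_genes,
    module_assignments = module_assignments,
    marker_gene = marker,
    effect_size = effect_size,
    arm_of_subject = stats::setNames(arm, subjects)
  )
  class(truth) <- "study_truth"
  list(study = study, truth = truth)
}

#' Simulate an interaction network with a planted high-signal subnetwork
#'
#' Grows a scale-free-style simple undirected graph by preferential attachment
#' and plants a connected signal subgraph chosen by seeded breadth-first
#' growth from a random node. Signal-node P-values are drawn from
#' Beta(`bum_a`, 1) and background P-values from Uniform(0, 1), so the pooled
#' P-value distribution follows the beta-uniform mixture
#' \eqn{\lambda + (1-\lambda) a p^{a-1}} with
#' \eqn{\lambda = 1 - \mathrm{signal\_size}/\mathrm{n\_nodes}}.
#'
#' @param n_nodes Number of nodes.
#' @param edges_per_node Preferential-attachment edges added per node
#'   (default 3, matching the edge density of curated human interactomes,
#'   whose mean degree is around 6-7).
#' @param signal_size Number of planted signal nodes (`< n_nodes`); 0 plants
#'   nothing (all P-values uniform).
#' @param bum_a Beta shape of signal P-values, in (0, 1).
#' @param seed Integer seed.
#'
#' @return A list: `graph` (igraph, nodes named `n0001`, ...), `p_values`
#'   (named numeric), `truth` (`network_truth` list with `signal_nodes`,
#'   `bum_lambda`, `bum_a`).
#' @export
generate_planted_network <- function(n_nodes, edges_per_node = 3, signal_size,
                                     bum_a = 0.1, seed) {
  if (missing(seed)) stop("`seed` is required")
  if (signal_size >= n_nodes) stop("`signal_size` must be < `n_nodes`")
  if (bum_a <= 0 || bum_a >= 1) stop("`bum_a` must be in (0, 1)")
  set.seed(as.integer(seed))
  g <- igraph::sample_pa(n_nodes, m = edges_per_node, directed = FALSE)
  g <- igraph::simplify(g)
  igraph::V(g)$name <- sprintf("n%04d", seq_len(n_nodes))

  signal <- character()
  if (signal_size > 0) {
    start <- sample(igraph::V(g)$name, 1)
    ord <- igraph::bfs(g, root = start, order = TRUE)$order
    reach <- igraph::V(g)$name[as.integer(ord)]
    reach <- reach[!is.na(reach)]
    if (length(reach) < signal_size)
      stop("signal subgraph of the requested size is not reachable as a connected subgraph")
    signal <- sort(reach[seq_len(signal_size)])
  }
  p <- stats::runif(n_nodes)
  names(p) <- igraph::V(g)$name
  if (length(signal) > 0) p[signal] <- stats::rbeta(length(signal), bum_a, 1)

  truth <- list(signal_nodes = signal,
                bum_lambda = 1 - signal_size / n_nodes,
                bum_a = bum_a)
  class(truth) <- "network_truth"
  list(graph = g, p_values = p, truth = truth)
}

#' Simulate a gene-set collection
#'
#' Draws random gene sets (without replacement within each set) from a
#' universe and merges in planted sets verbatim, with optional category
#' labels. The result is GMT-serializable via [write_gmt()].
#'
#' @param universe Character vector of gene ids.
#' @param n_sets Number of random sets to draw.
#' @param size_range Length-2 integer range of random set sizes.
#' @param planted_sets Named list of character vectors included verbatim.
#' @param categories Named character vector of category labels per set name.
#' @param seed Integer seed.
#'
#' @return A `geneset_collection`: list with `sets` (named list), `categories`
#'   (named character), `universe`.
#' @export
generate_genesets <- function(universe, n_sets = 0, size_range = c(5, 20),
                              planted_sets = list(), categories = character(),
                              seed) {
  if (missing(seed)) stop("`seed` is required")
  if (max(size_range) > length(universe))
    stop("`size_range` exceeds the universe size")
  bad <- unlist(lapply(planted_sets, setdiff, y = universe))
  if (length(bad) > 0)
    stop("planted set genes outside the universe: ", paste(bad, collapse = ", "))
  set.seed(as.integer(seed))
  sets <- list()
  if (n_sets > 0) {
    sizes <- sample(seq(size_range[1], size_range[2]), n_sets, replace = TRUE)
    sets <- lapply(sizes, function(k) sort(sample(universe, k)))
    names(sets) <- sprintf("set%03d", seq_len(n_sets))
  }
  sets[names(planted_sets)] <- lapply(planted_sets, function(x) sort(unique(x)))
  geneset_collection(sets, categories = categories, universe = universe)
}

#' Simulate an ontology DAG with upward-propagated annotations
#'
#' Builds a single-rooted acyclic term graph: term 1 is the root and every
#' later term draws 1..`max_parents` parents among earlier terms. Each term
#' receives its own direct gene annotations (sizes uniform in
#' `annotations_per_term`) and annotations propagate upward so that every
#' parent's set contains the union of its children's.
#'
#' @param n_terms Number of terms (>= 1).
#' @param max_parents Maximum parents per non-root term (>= 1).
#' @param annotations_per_term Length-2 range of direct annotations per term.
#' @param universe Character vector of gene ids.
#' @param seed Integer seed.
#'
#' @return An `ontology_dag`: list with `terms`, `parents` (named list,
#'   child -> parent ids), `annotations` (named list of gene vectors,
#'   propagated), `root`.
#' @export
generate_dag <- function(n_terms, max_parents = 2,
                         annotations_per_term = c(2, 5), universe, seed) {
  if (missing(seed)) stop("`seed` is required")
  if (n_terms < 1) stop("`n_terms` must be >= 1")
  if (max_parents < 1) stop("`max_parents` must be >= 1")
  set.seed(as.integer(seed))
  terms <- sprintf("T%03d", seq_len(n_terms))
  parents <- stats::setNames(vector("list", n_terms), terms)
  for (i in seq_len(n_terms)[-1]) {
    k <- sample(seq_len(min(max_parents, i - 1)), 1)
    parents[[terms[i]]] <- sort(sample(terms[seq_len(i - 1)], k))
  }
  direct <- lapply(terms, function(t) {
    k <- sample(seq(annotations_per_term[1], annotations_per_term[2]), 1)
    sort(sample(universe, min(k, length(universe))))
  })
  names(direct) <- terms
  ontology_dag(terms = terms, parents = parents, annotations = direct,
               propagate = TRUE)
}
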