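#' Pipeline configuration
#'
#' Assembles the parameter set of the end-to-end workflow with the standard
#' operating defaults: reporting significance `alpha = 0.05`, node-score FDR
#' `fdr = 0.05`, bootstrap consensus over 100 cycles retained at a
#' Bonferroni-corrected `q < 0.001`, and `N = 1000` common-pathway
#' permutations. `mi_p_cutoff` is the null tail probability converted into
#' the MI edge threshold; its default of `1e-3` pairs with the bootstrap
#' consensus: per-network false edges (a handful among thousands of pairs)
#' do not recur across resamples and the binomial consensus filter removes
#' them, while a stricter cutoff would let sampling noise in the
#' extrapolated threshold thin out genuine modules. Without consensus
#' (`bootstrap_cycles = 0`) choose stricter cutoffs — genome-scale
#' co-expression studies operate down at `1e-8`. The
#' default kernel width of 0.22 is the established operating scale for
#' paired studies of around 30 subjects; set `kernel_width = NULL` to
#' recalibrate via [calibrate_kernel_width()]. DPI pruning is off by
#' default here (unlike in [build_network()]): latent-factor co-expression
#' modules are near-cliques whose within-module edges DPI would classify as
#' indirect and strip, defeating dense-module detection; enable it when the
#' goal is regulatory-topology inference instead.
#'
#' When `simulate = TRUE` (default) the pipeline generates its own inputs:
#' a paired two-arm study with one planted co-expression module and planted
#' treatment-responsive genes, a planted-signal interaction network, and a
#' gene-set collection containing sets matched to the planted structures
#' (including one "shared" set straddling both modules) plus random sets.
#' Otherwise `paths` must name `expression`, `annotations`, `network`
#' (edge-list TSV with node P-values in `network_pvalues`), and `genesets`.
#'
#' @param seed Integer master seed; every random stage derives its own
#'   stream from it.
#' @param out_dir Output directory for TSVs and provenance (NULL = no files).
#' @param ... Overrides for any default listed above (e.g. `alpha`,
#'   `fdr`, `mi_p_cutoff`, `bootstrap_cycles`, `consensus_q`,
#'   `permutation_N`, `simulate`, `paths`, simulation sizes).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, out_dir = NULL, ...) {
  cfg <- list(
    seed = as.integer(seed),
    out_dir = out_dir,
    alpha = 0.05,
    fdr = 0.05,
    mi_p_cutoff = 1e-3,
    kernel_width = 0.22,        # NULL = calibrate at the study's sample size
    bootstrap_cycles = 100,
    consensus_q = 0.001,
    permutation_N = 1000,
    min_support = 2,
    excluded_categories = "disease",
    exceptions = character(),
    apply_dpi = FALSE,
    dpi_tolerance = 0,
    simulate = TRUE,
    paths = list(),
    # synthetic study conditions
    n_subjects = 30, n_genes = 120, module_sizes = 30,
    within_module_corr = 0.8, effect_size = 1, n_de_genes = 15, noise_sd = 1,
    ppi_nodes = 200, ppi_edges_per_node = 3, ppi_signal_size = 15,
    ppi_bum_a = 0.1,
    n_random_sets = 20, set_size_range = c(5, 20)
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0)
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  stopifnot(cfg$alpha > 0, cfg$alpha < 1, cfg$fdr > 0, cfg$fdr < 1,
            cfg$mi_p_cutoff > 0, cfg$mi_p_cutoff <= 1,
            cfg$permutation_N >= 1)
  class(cfg) <- "pipeline_config"
  cfg
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the dual-network workflow end to end
#'
#' Executes preprocess -> differential expression -> (co-expression network
#' -> MCODE) and (interaction-network scoring -> connected-module search) ->
#' enrichment -> common-pathways permutation, emitting intermediate TSVs and
#' a JSON provenance record when `out_dir` is set.
#'
#' @param config A [pipeline_config].
#' @return A list of class `pipeline_report`: the background `threshold`,
#'   the `de_table`, counts of raw/FDR significant genes, the consensus
#'   co-expression network and `mcode` complexes, the `bionet_module` and
#'   BUM fit, both `enrichment` tables, the `common` terms and their
#'   `permutation` result, plus `truth` when simulated.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed

  inputs <- with_stage("inputs", {
    if (isTRUE(config$simulate)) {
      sim <- generate_study(n_subjects = config$n_subjects,
                            n_genes = config$n_genes,
                            module_sizes = config$module_sizes,
                            within_module_corr = config$within_module_corr,
                            effect_size = config$effect_size,
                            n_de_genes = config$n_de_genes,
                            noise_sd = config$noise_sd, seed = seed)
      ppi <- generate_planted_network(n_nodes = config$ppi_nodes,
                                      edges_per_node = config$ppi_edges_per_node,
                                      signal_size = config$ppi_signal_size,
                                      bum_a = config$ppi_bum_a,
                                      seed = seed + 1)
      list(study = sim$study, study_truth = sim$truth,
           ppi_graph = ppi$graph, ppi_pvalues = ppi$p_values,
           ppi_truth = ppi$truth)
    } else {
      p <- config$paths
      need <- c("expression", "annotations", "network", "network_pvalues",
                "genesets")
      miss <- setdiff(need, names(p))
      if (length(miss) > 0)
        stop("paths missing: ", paste(miss, collapse = ", "))
      pv <- utils::read.table(p$network_pvalues, sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE)
      list(study = read_study(p$expression, p$annotations),
           study_truth = NULL,
           ppi_graph = read_edgelist_tsv(p$network, simple = FALSE),
           ppi_pvalues = stats::setNames(pv$p, pv$node),
           ppi_truth = NULL)
    }
  })

  pre <- with_stage("preprocess", {
    marker <- if (!is.null(inputs$study_truth))
      inputs$study_truth$marker_gene else config$paths$marker_gene
    thr <- if (is.null(marker)) -Inf else
      suppressMessages(estimate_background_threshold(inputs$study, marker, "M"))
    filtered <- filter_unexpressed(inputs$study, thr)
    list(threshold = thr, filtered = filtered,
         delta = baseline_correct(filtered))
  })

  de <- with_stage("diffexpr", {
    fits <- fit_linear_model(pre$delta)
    moderate_and_test(fits)
  })

  coex <- with_stage("coexnet", {
    h <- config$kernel_width
    if (is.null(h))
      h <- as.numeric(calibrate_kernel_width(ncol(pre$delta$matrix),
                                             seed = seed + 2))
    cfg <- mi_config(h)
    nf <- calibrate_mi_threshold(ncol(pre$delta$matrix), n_null_pairs = 300,
                                 config = cfg, seed = seed + 3)
    I0 <- threshold_for_p(nf, config$mi_p_cutoff)
    net <- if (config$bootstrap_cycles >= 2) {
      bootstrap_consensus(pre$delta, cfg, I0, B = config$bootstrap_cycles,
                          q_cutoff = config$consensus_q, seed = seed + 4,
                          apply_dpi = config$apply_dpi,
                          dpi_tolerance = config$dpi_tolerance)
    } else {
      build_network(pre$delta, cfg, I0, apply_dpi = config$apply_dpi,
                    dpi_tolerance = config$dpi_tolerance)
    }
    deg <- igraph::degree(net)
    plaw <- tryCatch(fit_power_law(deg[deg > 0], method = "mle"),
                     error = function(e) NULL)
    list(config = cfg, null_fit = nf, I0 = I0, network = net,
         power_law = plaw)
  })

  mcode <- with_stage("mcode", find_complexes(coex$network))
  mcode_genes <- if (nrow(mcode) > 0) complex_members(mcode, 1) else character()

  bionet <- with_stage("ppi_scoring", {
    g <- simplify_network(inputs$ppi_graph)
    fit <- fit_bum(inputs$ppi_pvalues)
    scores <- score_nodes(inputs$ppi_pvalues, fit, fdr = config$fdr)
    module <- find_module_heuristic(g, scores)
    list(graph = g, bum = fit, scores = scores, module = module)
  })

  gs <- with_stage("genesets", {
    universe <- sort(union(rownames(pre$delta$matrix),
                           igraph::V(bionet$graph)$name))
    if (isTRUE(config$simulate)) {
      mod_genes <- names(inputs$study_truth$module_assignments)[
        inputs$study_truth$module_assignments == 1]
      mod_genes <- intersect(mod_genes, universe)
      signal <- intersect(inputs$ppi_truth$signal_nodes, universe)
      planted <- list(
        coexpression_program = mod_genes,
        interaction_response = signal,
        shared_signaling = c(utils::head(mod_genes, 10), utils::head(signal, 10)),
        disease_like = utils::head(universe, 8))
      generate_genesets(universe, n_sets = config$n_random_sets,
                        size_range = config$set_size_range,
                        planted_sets = planted,
                        categories = c(disease_like = "disease"),
                        seed = seed + 5)
    } else {
      read_gmt(config$paths$genesets, universe = universe)
    }
  })

  enr <- with_stage("enrichment", {
    tabs <- list(
      mcode_m1 = ora(mcode_genes, gs),
      bionet = ora(as.character(bionet$module), gs))
    filt <- filter_pathways(tabs,
                            excluded_categories = config$excluded_categories,
                            exceptions = config$exceptions,
                            min_support = config$min_support)
    list(tables = tabs, filtered = filt)
  })

  common <- with_stage("common_pathways", {
    ft <- enr$filtered$tables
    terms <- if (all(c("mcode_m1", "bionet") %in% names(ft)))
      common_terms(ft$mcode_m1, ft$bionet, alpha = config$alpha)
    else character()
    perm <- if (length(terms) > 0) {
      permutation_p(gs$universe, size_A = length(mcode_genes),
                    size_B = length(bionet$module), collection = gs,
                    target_terms = terms, N = config$permutation_N,
                    alpha = config$alpha, min_support = config$min_support,
                    excluded_categories = config$excluded_categories,
                    exceptions = config$exceptions, seed = seed + 6)
    } else NULL
    list(terms = terms, permutation = perm)
  })

  report <- list(
    threshold = pre$threshold,
    n_genes_filtered = nrow(pre$filtered$matrix),
    n_subjects = ncol(pre$delta$matrix),
    de_table = de,
    n_raw_significant = sum(de$p_value < config$alpha),
    n_fdr_significant = sum(de$q_value < config$alpha),
    kernel_width = coex$config$kernel_width,
    I0 = coex$I0,
    network = coex$network,
    power_law = coex$power_law,
    mcode = mcode,
    mcode_m1_genes = mcode_genes,
    mcode_m1_coherence = if (length(mcode_genes) >= 2)
      module_coherence(mcode_genes, pre$delta)$mean_r else NA_real_,
    bum = bionet$bum,
    bionet_module = as.character(bionet$module),
    enrichment = enr$filtered$tables,
    common_terms = common$terms,
    permutation = common$permutation,
    truth = inputs[c("study_truth", "ppi_truth")],
    config = config
  )
  class(report) <- "pipeline_report"

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    o <- function(f) file.path(config$out_dir, f)
    write_results_tsv(de, o("de_table.tsv"))
    write_edgelist_tsv(coex$network, o("coexpression_network.tsv"))
    write_results_tsv(mcode, o("mcode_complexes.tsv"))
    write_results_tsv(data.frame(node = names(bionet$scores),
                                 p = unname(inputs$ppi_pvalues[names(bionet$scores)]),
                                 score = as.numeric(bionet$scores)),
                      o("node_scores.tsv"))
    writeLines(report$bionet_module, o("bionet_module.txt"))
    for (nm in names(enr$filtered$tables))
      write_results_tsv(enr$filtered$tables[[nm]],
                        o(paste0("enrichment_", nm, ".tsv")))
    if (!is.null(common$permutation))
      write_results_tsv(common$permutation, o("common_pathways.tsv"))
    write_provenance(list(
      seed = seed, alpha = config$alpha, fdr = config$fdr,
      mi_p_cutoff = config$mi_p_cutoff, kernel_width = coex$config$kernel_width,
      I0 = coex$I0, bootstrap_cycles = config$bootstrap_cycles,
      consensus_q = config$consensus_q, permutation_N = config$permutation_N,
      simulate = config$simulate), o("provenance.json"))
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("dual-network pipeline report\n")
  cat("  genes after background filter:", x$n_genes_filtered,
      "| subjects:", x$n_subjects, "\n")
  cat("  DE genes: P<alpha:", x$n_raw_significant,
      "| q<alpha:", x$n_fdr_significant, "\n")
  cat("  co-expression network:", igraph::vcount(x$network), "nodes,",
      igraph::ecount(x$network), "edges (I0 =", signif(x$I0, 3), "nats)\n")
  if (!is.null(x$power_law))
    cat("  degree power-law gamma:", signif(x$power_law$gamma, 3), "\n")
  cat("  MCODE complexes:", nrow(x$mcode), "| M1 size:",
      length(x$mcode_m1_genes), "\n")
  cat("  interaction module:", length(x$bionet_module), "nodes\n")
  cat("  common pathways:", if (length(x$common_terms) > 0)
    paste(x$common_terms, collapse = ", ") else "(none)", "\n")
  invisible(x)
}

#' Hypergeometric enrichment with explicitly supplied population counts
#'
#' Convenience wrapper for testing over-representation against an external
#' catalog whose universe and annotated-gene totals are only known as
#' stated counts (e.g. interferon-regulated gene catalogs): because those
#' totals are estimates, the resulting P-value is approximate in the same
#' degree.
#'
#' @param hits Annotated genes observed in the list.
#' @param list_size Size of the gene list.
#' @param annotated Stated number of annotated genes in the population.
#' @param universe Stated population size.
#' @return Upper-tail hypergeometric P-value.
#' @export
interferome_style_enrichment <- function(hits, list_size, annotated, universe) {
  message("population counts are stated totals; the enrichment P-value is approximate")
  hypergeom_test(hits, list_size, annotated, universe)
}
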