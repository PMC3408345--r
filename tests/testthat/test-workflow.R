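test_that("study TSVs round-trip exactly", {
  sim <- generate_study(6, 20, seed = 2)
  mp <- withr::local_tempfile(fileext = ".tsv")
  ap <- withr::local_tempfile(fileext = ".tsv")
  write_study(sim$study, mp, ap)
  back <- read_study(mp, ap)
  expect_equal(back$matrix, sim$study$matrix, tolerance = 1e-12)
  expect_equal(back$samples, sim$study$samples)
})

test_that("malformed tabular inputs fail with located errors", {
  mp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1\ts2", "g1\t1.0\t2.0", "g1\t3.0\t4.0"), mp)
  ap <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tsubject_id\ttimepoint\tarm\tsex\tage",
               "s1\tA\tpre\ttreated\tM\t30",
               "s2\tA\tpost\ttreated\tM\t30"), ap)
  expect_error(read_study(mp, ap), "duplicate gene ids at lines: 3")

  mp2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1\ts2", "g1\t1.0\toops"), mp2)
  expect_error(read_study(mp2, ap), "non-numeric")

  gmt <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("ok\tna\tg1\tg2", "bad\tna"), gmt)
  expect_error(read_gmt(gmt), "line 2")
})

test_that("edge lists round-trip and police self-loops", {
  g <- igraph::graph_from_literal(a - b, b - c)
  igraph::E(g)$weight <- c(0.5, 1.5)
  ep <- withr::local_tempfile(fileext = ".tsv")
  write_edgelist_tsv(g, ep)
  back <- read_edgelist_tsv(ep)
  expect_setequal(graph_edges_key(back), graph_edges_key(g))
  expect_equal(sort(igraph::E(back)$weight), c(0.5, 1.5))

  loop <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("node_a\tnode_b\tweight", "a\ta\t1", "a\tb\t1"), loop)
  expect_error(read_edgelist_tsv(loop), "lines: 2")
  expect_warning(read_edgelist_tsv(loop, simple = FALSE), "lines: 2")
})

test_that("gene sets and ontologies round-trip through their text formats", {
  uni <- sprintf("g%02d", 1:30)
  gs <- generate_genesets(uni, n_sets = 5, size_range = c(3, 6),
                          planted_sets = list(px = uni[1:4]),
                          categories = c(px = "disease"), seed = 3)
  gp <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(gs, gp)
  back <- read_gmt(gp, universe = uni)
  expect_equal(back$sets, gs$sets)
  expect_equal(back$categories["px"], gs$categories["px"])

  dag <- generate_dag(8, universe = uni, seed = 5)
  dp <- withr::local_tempfile(fileext = ".tsv")
  ap <- withr::local_tempfile(fileext = ".tsv")
  write_dag(dag, dp, ap)
  back_dag <- read_dag(dp, ap)
  expect_equal(back_dag$annotations, dag$annotations)
  expect_equal(back_dag$parents[order(names(back_dag$parents))],
               dag$parents[order(names(dag$parents))])
})

test_that("the end-to-end pipeline finds the planted structures reproducibly", {
  cfg <- pipeline_config(seed = 1, out_dir = withr::local_tempdir(),
                         bootstrap_cycles = 0, permutation_N = 50,
                         n_genes = 80, module_sizes = 25)
  rep1 <- suppressWarnings(suppressMessages(run_pipeline(cfg)))
  mod <- names(rep1$truth$study_truth$module_assignments)[
    rep1$truth$study_truth$module_assignments == 1]
  expect_gte(jaccard(rep1$mcode_m1_genes, mod), 0.6)
  expect_gt(length(rep1$bionet_module), 0)
  expect_true("shared_signaling" %in% rep1$common_terms)
  expect_true(all(c("de_table.tsv", "mcode_complexes.tsv", "provenance.json")
                  %in% list.files(cfg$out_dir)))

  cfg2 <- pipeline_config(seed = 1, out_dir = withr::local_tempdir(),
                          bootstrap_cycles = 0, permutation_N = 50,
                          n_genes = 80, module_sizes = 25)
  rep2 <- suppressWarnings(suppressMessages(run_pipeline(cfg2)))
  for (f in list.files(cfg$out_dir)) {
    expect_identical(readLines(file.path(cfg$out_dir, f)),
                     readLines(file.path(cfg2$out_dir, f)), label = f)
  }

  one <- pipeline_config(seed = 2, bootstrap_cycles = 0, permutation_N = 1,
                         n_genes = 80, module_sizes = 25)
  rep3 <- suppressWarnings(suppressMessages(run_pipeline(one)))
  if (!is.null(rep3$permutation))
    expect_true(all(rep3$permutation$p %in% c(0, 1)))

  expect_error(pipeline_config(alpha = 2), "alpha")
  expect_error(pipeline_config(nonsense = 1), "unknown config")
})

test_that("catalog-count enrichment wraps the hypergeometric tail", {
  expect_equal(suppressMessages(interferome_style_enrichment(0, 114, 2000, 20900)), 1)
  expect_equal(suppressMessages(interferome_style_enrichment(5, 10, 50, 50)), 1)
  p <- suppressMessages(interferome_style_enrichment(20, 114, 2000, 20900))
  expect_equal(p, hypergeom_test(20, 114, 2000, 20900))
  expect_true(p > 0 && p < 1)
})
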