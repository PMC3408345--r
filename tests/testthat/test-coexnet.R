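test_that("copula transform maps to mid-ranked uniforms", {
  m <- rbind(a = c(10, 30, 20))
  expect_equal(unname(copula_transform(m)[1, ]), c(0.25, 0.75, 0.50))
  # rank invariance under monotone transforms
  m2 <- rbind(a = exp(c(10, 30, 20) / 10))
  expect_equal(copula_transform(m)[1, ], copula_transform(m2)[1, ],
               ignore_attr = TRUE)
  expect_warning(u <- copula_transform(rbind(a = c(2, 2, 2, 2))), "constant")
  expect_equal(unname(u[1, ]), rep(0.5, 4))
  expect_error(copula_transform(rbind(a = c(1, 2))), "3 samples")
})

test_that("mutual information is symmetric, non-negative and maximal on self", {
  set.seed(19)
  cfg <- mi_config(0.15)
  u <- copula_transform(matrix(rnorm(5 * 40), nrow = 5,
                               dimnames = list(letters[1:5], NULL)))
  for (i in 1:4) for (j in (i + 1):5) {
    mij <- mutual_information(u[i, ], u[j, ], cfg)
    expect_equal(mij, mutual_information(u[j, ], u[i, ], cfg))
    expect_gte(mij, 0)
    expect_lte(mij, mutual_information(u[i, ], u[i, ], cfg))
  }
  expect_error(mi_config(-0.1), "> 0")
})

test_that("independent profiles score near-zero mutual information", {
  set.seed(3)
  x <- rnorm(1000)
  y <- rnorm(1000)
  u <- copula_transform(rbind(x, y))
  expect_lte(mutual_information(u[1, ], u[2, ], mi_config(0.04)), 0.02)
})

test_that("kernel-width calibration picks the grid minimum and shrinks with n", {
  w <- calibrate_kernel_width(50, width_grid = c(0.1, 0.2, 0.3), n_reps = 3,
                              rho_grid = c(0, 0.5), seed = 2)
  mse <- attr(w, "mse")
  expect_length(mse, 3)
  expect_equal(as.numeric(w), c(0.1, 0.2, 0.3)[which.min(mse)])
  grid <- c(0.05, 0.1, 0.2, 0.3)
  w20 <- as.numeric(calibrate_kernel_width(20, grid, n_reps = 4,
                                           rho_grid = c(0, 0.5), seed = 8))
  w500 <- as.numeric(calibrate_kernel_width(500, grid, n_reps = 4,
                                            rho_grid = c(0, 0.5), seed = 8))
  expect_lte(w500, w20)
  expect_error(calibrate_kernel_width(50, n_reps = 1, seed = 1), "n_reps")
})

test_that("null-MI calibration yields a decreasing survival line", {
  cfg <- mi_config(0.2)
  nf <- calibrate_mi_threshold(30, 200, cfg, seed = 12)
  expect_lt(nf$beta, 0)
  # exact inverse relation
  p_at <- exp(nf$alpha + nf$beta * 0.3)
  expect_equal(threshold_for_p(nf, p_at), 0.3)
  expect_gt(threshold_for_p(nf, 1e-6), threshold_for_p(nf, 1e-3))
  expect_error(threshold_for_p(nf, 0), "0, 1")
  # more samples concentrate the null: thresholds drop
  nf2 <- calibrate_mi_threshold(60, 200, cfg, seed = 12)
  expect_lt(threshold_for_p(nf2, 1e-4), threshold_for_p(nf, 1e-4))
})

test_that("DPI removes the weakest edge of each triangle", {
  g <- igraph::graph_from_literal(A - B, B - C, A - C)
  igraph::E(g)$weight <- c(0.5, 0.1, 0.4)[match(
    apply(igraph::as_edgelist(g), 1, paste, collapse = ""),
    c("AB", "AC", "BC"))]
  out <- apply_dpi(g, 0)
  expect_equal(igraph::ecount(out), 2)
  expect_equal(igraph::get_edge_ids(out, c("A", "C")), 0)  # AC removed
  # a square has no triangles: identity
  sq <- igraph::graph_from_literal(A - B, B - C, C - D, D - A)
  igraph::E(sq)$weight <- 1:4
  expect_equal(igraph::ecount(apply_dpi(sq, 0)), 4)
})

test_that("DPI equals literal triangle pruning and is idempotent", {
  set.seed(55)
  for (i in 1:40) {
    g <- random_named_graph(sample(5:12, 1), 0.5)
    igraph::E(g)$weight <- runif(igraph::ecount(g))
    tol <- sample(c(0, 0.1), 1)
    ours <- apply_dpi(g, tol)
    ref <- brute_dpi(g, tol)
    expect_setequal(graph_edges_key(ours), graph_edges_key(ref))
    expect_true(all(graph_edges_key(ours) %in% graph_edges_key(g)))
    expect_setequal(graph_edges_key(apply_dpi(ours, tol)),
                    graph_edges_key(ours))
  }
})

test_that("network construction thresholds and prunes deterministically", {
  sim <- generate_study(20, 30, module_sizes = c(8), within_module_corr = 0.9,
                        seed = 14)
  delta <- baseline_correct(sim$study)
  cfg <- mi_config(0.22)
  net <- build_network(delta, cfg, I0 = 0.2, apply_dpi = FALSE)
  net2 <- build_network(delta, cfg, I0 = 0.2, apply_dpi = FALSE)
  expect_identical(graph_edges_key(net), graph_edges_key(net2))
  expect_true(all(igraph::E(net)$weight >= 0.2))
  empty <- build_network(delta, cfg, I0 = 10)
  expect_equal(igraph::ecount(empty), 0)
})

test_that("bootstrap consensus keeps reproducible well-supported edges", {
  sim <- generate_study(20, 20, module_sizes = c(6), within_module_corr = 0.9,
                        seed = 18)
  delta <- baseline_correct(sim$study)
  cfg <- mi_config(0.22)
  nf <- calibrate_mi_threshold(20, 150, cfg, seed = 1)
  I0 <- threshold_for_p(nf, 1e-3)
  cons <- bootstrap_consensus(delta, cfg, I0, B = 20, seed = 3,
                              apply_dpi = FALSE)
  cons2 <- bootstrap_consensus(delta, cfg, I0, B = 20, seed = 3,
                               apply_dpi = FALSE)
  expect_identical(graph_edges_key(cons), graph_edges_key(cons2))
  mod <- names(sim$truth$module_assignments)[sim$truth$module_assignments == 1]
  el <- igraph::as_edgelist(cons)
  expect_gt(sum(el[, 1] %in% mod & el[, 2] %in% mod), 0)
  expect_true(all(igraph::E(cons)$support <= 20))
  expect_error(bootstrap_consensus(delta, cfg, I0, B = 1, seed = 3), "B")
  # binomial retention arithmetic: full support at low density passes the
  # Bonferroni bar, single support at high density cannot
  expect_lt(pbinom(99, 100, 0.01, lower.tail = FALSE) * 1000, 0.001)
  expect_gt(pbinom(0, 100, 0.5, lower.tail = FALSE), 0.001)
})

test_that("power-law exponent is recovered by maximum likelihood", {
  set.seed(9)
  k <- 1:100000
  deg <- sample(k, 10000, replace = TRUE, prob = k^(-2))
  fit <- fit_power_law(deg, method = "mle")
  expect_lt(abs(fit$gamma - 2), 0.1)
  reg <- fit_power_law(deg, method = "loglog_regression")
  expect_lt(abs(reg$gamma - 2), 0.4)
  expect_error(fit_power_law(c(rep(1, 9), 50)), "degenerate")
  expect_error(fit_power_law(rep(3, 50)), "degenerate")
})
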