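make_delta <- function(mat, arm, sex = NULL, age = NULL) {
  subj <- sprintf("s%02d", seq_len(ncol(mat)))
  colnames(mat) <- subj
  if (is.null(rownames(mat))) rownames(mat) <- sprintf("g%03d", seq_len(nrow(mat)))
  if (is.null(sex)) sex <- rep(c("M", "F"), length.out = ncol(mat))
  if (is.null(age)) age <- 30 + seq_len(ncol(mat))
  delta_matrix(mat, data.frame(subject_id = subj, arm = arm, sex = sex,
                               age = age))
}

test_that("noiseless treatment effect is recovered exactly", {
  arm <- rep(c("treated", "placebo"), each = 4)
  mat <- matrix(rep(ifelse(arm == "treated", 1, 0), each = 3), nrow = 3,
                byrow = FALSE)
  d <- make_delta(mat, arm)
  fit <- fit_linear_model(d, covariates = character())
  expect_equal(unname(fit$coef), rep(1, 3))
  expect_equal(unname(fit$residual_sd), rep(0, 3))
})

test_that("rank-deficient designs are rejected with the offending column", {
  d <- make_delta(matrix(rnorm(40), nrow = 4),
                  arm = rep(c("treated", "placebo"), 5),
                  age = rep(50, 10))
  expect_error(fit_linear_model(d), "age")
})

test_that("null coefficients center at zero", {
  set.seed(31)
  arm <- rep(c("treated", "placebo"), each = 15)
  d <- make_delta(matrix(rnorm(30 * 500), ncol = 30), arm)
  fit <- fit_linear_model(d)
  se <- mean(fit$residual_sd) * fit$se_unscaled / sqrt(500)
  expect_lt(abs(mean(fit$coef)), 3 * se)
})

test_that("moderated t reduces to its closed-form limits", {
  set.seed(7)
  arm <- rep(c("treated", "placebo"), each = 10)
  d <- make_delta(matrix(rnorm(20 * 50, sd = rep(runif(50, 0.5, 2), 20)),
                         ncol = 20), arm)
  fit <- fit_linear_model(d)

  ord <- moderate_and_test(fit, prior_df = 0)
  t_ord <- fit$coef / (fit$residual_sd * fit$se_unscaled)
  expect_equal(ord$moderated_t[match(names(fit$coef), ord$gene)],
               unname(t_ord), tolerance = 1e-12)

  inf <- moderate_and_test(fit, prior_df = Inf)
  t_inf <- inf$moderated_t[match(names(fit$coef), inf$gene)]
  # with d0 -> Inf all variances equal s0^2, so t is proportional to coef
  expect_equal(stats::cor(t_inf, unname(fit$coef)), 1, tolerance = 1e-12)
})

test_that("moderated test matches the reference empirical-Bayes implementation", {
  set.seed(13)
  arm <- rep(c("treated", "placebo"), each = 12)
  d <- make_delta(matrix(rnorm(24 * 300, sd = rep(sqrt(1 / rgamma(300, 4, 4)), 24)),
                         ncol = 24), arm)
  fit <- fit_linear_model(d)
  ours <- moderate_and_test(fit)
  ref <- limma::eBayes(limma::lmFit(d$matrix, fit$design))
  ord <- match(ours$gene, rownames(d$matrix))
  expect_equal(attr(ours, "d0"), ref$df.prior, tolerance = 1e-4)
  expect_equal(ours$moderated_t, unname(ref$t[ord, "treatment"]),
               tolerance = 1e-6)
  expect_equal(ours$p_value, unname(ref$p.value[ord, "treatment"]),
               tolerance = 1e-6)
})

test_that("step-up adjustment matches its brute-force definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.5)), c(0.04, 0.04, 0.04, 0.5))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(41)
  for (i in 1:1000) {
    p <- runif(sample(1:20, 1))
    expect_equal(bh_adjust(p), brute_bh(p))
  }
})

test_that("profile correlation uses the t-transform", {
  x <- 1:10
  res <- correlate_profiles(x, x)
  expect_equal(res$r, 1)
  expect_equal(res$p_two_sided, 0)

  # r = 0.5 at n = 20 via constructed vectors
  t_stat <- 0.5 * sqrt(18 / (1 - 0.25))
  expected_p <- 2 * pt(-t_stat, 18)
  set.seed(2)
  repeat {   # rotate until empirical r is exactly 0.5 by construction
    a <- rnorm(20)
    b <- rnorm(20)
    b <- residuals(lm(b ~ a))
    a <- scale(a)[, 1]; b <- scale(b)[, 1]
    y <- 0.5 * a + sqrt(0.75) * b
    break
  }
  res2 <- correlate_profiles(a, y)
  expect_equal(res2$r, 0.5, tolerance = 1e-12)
  expect_equal(res2$p_two_sided, expected_p, tolerance = 1e-10)
  expect_equal(round(res2$p_two_sided, 3), 0.025)

  expect_error(correlate_profiles(rep(1, 5), rnorm(5)), "constant")
  expect_error(correlate_profiles(1:2, 2:3), "at least 3")

  # spearman is invariant to monotone transforms
  s1 <- correlate_profiles(exp(x), x, method = "spearman")
  expect_equal(s1$r, 1)
})

test_that("module coherence averages pairwise correlations", {
  arm <- rep(c("treated", "placebo"), each = 5)
  base <- sin(1:10)
  d <- make_delta(rbind(a = base, b = base, c = -base), arm)
  same <- module_coherence(c("a", "b"), d, method = "pearson")
  expect_equal(same$mean_r, 1)
  anti <- module_coherence(c("a", "c"), d, method = "pearson")
  expect_equal(anti$mean_r, -1)
  expect_equal(anti$mean_abs_r, 1)
  expect_error(module_coherence(c("a", "zz"), d), "zz")
})

test_that("whole testing pipeline keeps nominal type-I error on null data", {
  sim <- generate_study(30, 1000, effect_size = 0, within_module_corr = 0,
                        seed = 29)
  thr <- suppressMessages(estimate_background_threshold(
    sim$study, sim$truth$marker_gene, "M"))
  filt <- filter_unexpressed(sim$study, thr)
  de <- suppressWarnings(moderate_and_test(fit_linear_model(baseline_correct(filt))))
  frac <- mean(de$p_value < 0.05)
  expect_gte(frac, 0.035)
  expect_lte(frac, 0.065)
})
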