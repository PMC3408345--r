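#' Per-gene linear model on baseline-corrected data
#'
#' Fits, by ordinary least squares, the same design to every gene's
#' post-minus-pre profile: intercept, treatment (placebo = 0, treated = 1),
#' sex (M = 0, F = 1) and standardized age. The coefficient of interest is
#' the treatment contrast, i.e. the treated-minus-placebo difference in mean
#' post-minus-pre change.
#'
#' @param delta A [delta_matrix].
#' @param covariates Character vector of adjustment covariates; any of
#'   `"sex"`, `"age"` (treatment is always included).
#' @return A list of class `de_fit`: `coef` (named treatment coefficients),
#'   `residual_sd`, `df_residual` (shared scalar), `se_unscaled` (unscaled
#'   standard error of the treatment coefficient), `design`.
#' @export
fit_linear_model <- function(delta, covariates = c("sex", "age")) {
  subj <- delta$subjects
  X <- cbind(intercept = 1,
             treatment = as.numeric(subj$arm == "treated"))
  if ("sex" %in% covariates)
    X <- cbind(X, sex = as.numeric(subj$sex == "F"))
  if ("age" %in% covariates) {
    age <- subj$age
    X <- cbind(X, age = if (stats::sd(age) > 0) (age - mean(age)) / stats::sd(age) else age)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank-deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  n <- nrow(X)
  if (n < ncol(X) + 1) stop("need more subjects than design columns")
  Y <- t(delta$matrix)                       # subjects x genes
  beta <- qr.coef(qrX, Y)                    # coefficients x genes
  res <- Y - X %*% beta
  df <- n - ncol(X)
  s2 <- colSums(res^2) / df
  xtxi <- chol2inv(chol(crossprod(X)))
  structure(list(coef = beta["treatment", ],
                 residual_sd = sqrt(s2),
                 df_residual = df,
                 se_unscaled = sqrt(xtxi[2, 2]),
                 design = X),
            class = "de_fit")
}

# Invert the trigamma function by Newton iteration (monotone decreasing on
# (0, Inf)); used for moment-matching the prior degrees of freedom.
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif) / y < 1e-8) break
  }
  y
}

#' Empirical-Bayes moderated t-tests
#'
#' Shrinks the per-gene residual variances toward a pooled prior estimated by
#' moment matching on the log variances (digamma/trigamma inversion), then
#' tests the treatment coefficient with a t statistic on augmented degrees of
#' freedom: \eqn{\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)},
#' \eqn{\tilde t_g = \beta_g / (\tilde s_g \cdot se)}, two-sided P from
#' \eqn{t_{d_0 + d_g}}. Benjamini-Hochberg q-values are appended.
#'
#' @param fits A `de_fit` from [fit_linear_model()].
#' @param prior_df Optional forced prior degrees of freedom `d0` (mainly for
#'   testing the limits `d0 = 0` (ordinary t) and `d0 = Inf`).
#' @return A `data.frame` of class `de_table`, sorted by `p_value`: columns
#'   `gene`, `coef`, `residual_sd`, `df_residual`, `moderated_t`, `p_value`,
#'   `q_value`. Attributes `d0` and `s0_sq` record the prior.
#' @export
moderate_and_test <- function(fits, prior_df = NULL) {
  if (length(fits$coef) < 10 && is.null(prior_df))
    stop("need >= 10 genes to pool variances")
  s2 <- fits$residual_sd^2
  dg <- fits$df_residual
  ok <- s2 > 0
  if (!any(ok)) {
    warning("all residual variances are zero; falling back to ordinary t",
            call. = FALSE)
    t_ord <- fits$coef / (fits$residual_sd * fits$se_unscaled)
    p <- 2 * stats::pt(-abs(t_ord), df = dg)
    p[!is.finite(t_ord)] <- ifelse(fits$coef[!is.finite(t_ord)] == 0, 1, 0)
    return(make_de_table(fits, t_ord, p, d0 = 0, s0_sq = 0))
  }
  if (is.null(prior_df)) {
    z <- log(s2[ok])
    e <- z - digamma(dg / 2) + log(dg / 2)
    ebar <- mean(e)
    target <- mean((e - ebar)^2 * length(e) / (length(e) - 1)) - trigamma(dg / 2)
    if (is.na(target) || target <= 0) {
      warning("trigamma inversion failed (near-equal variances); capping d0 at 1e6",
              call. = FALSE)
      d0 <- 1e6
    } else {
      d0 <- 2 * trigamma_inverse(target)
    }
    s0_sq <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
    if (!is.finite(s0_sq)) s0_sq <- exp(ebar)
  } else {
    d0 <- prior_df
    s0_sq <- if (is.finite(d0) && d0 > 0) {
      z <- log(s2[ok]); exp(mean(z) + digamma(d0 / 2) - log(d0 / 2))
    } else mean(s2[ok])
  }
  if (is.infinite(d0)) {
    s2_mod <- rep(s0_sq, length(s2))
    df_total <- Inf
  } else if (d0 == 0) {
    s2_mod <- s2
    df_total <- dg
  } else {
    s2_mod <- (d0 * s0_sq + dg * s2) / (d0 + dg)
    df_total <- d0 + dg
  }
  t_mod <- fits$coef / (sqrt(s2_mod) * fits$se_unscaled)
  p <- 2 * stats::pt(-abs(t_mod), df = df_total)
  zero_var <- !is.finite(t_mod)
  p[zero_var] <- ifelse(fits$coef[zero_var] == 0, 1, 0)
  make_de_table(fits, t_mod, p, d0 = d0, s0_sq = s0_sq)
}

make_de_table <- function(fits, t_stat, p, d0, s0_sq) {
  tab <- data.frame(gene = names(fits$coef),
                    coef = unname(fits$coef),
                    residual_sd = unname(fits$residual_sd),
                    df_residual = fits$df_residual,
                    moderated_t = unname(t_stat),
                    p_value = unname(p),
                    stringsAsFactors = FALSE)
  tab$q_value <- bh_adjust(tab$p_value)
  tab <- tab[order(tab$p_value, tab$gene), ]
  rownames(tab) <- NULL
  attr(tab, "d0") <- d0
  attr(tab, "s0_sq") <- s0_sq
  class(tab) <- c("de_table", "data.frame")
  tab
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p_values Numeric vector of P-values in `[0, 1]`.
#' @return q-values in the input order.
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("P-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Correlation of two expression profiles with a t-based P-value
#'
#' Pearson or Spearman correlation with a two-sided P-value from the
#' t-transform \eqn{t = r\sqrt{(n-2)/(1-r^2)}} on \eqn{n - 2} degrees of
#' freedom (for Spearman, applied to the rank correlation).
#'
#' @param x,y Numeric vectors of equal length `n >= 3`.
#' @param method `"pearson"` or `"spearman"`.
#' @return A list with `r` and `p_two_sided`.
#' @export
correlate_profiles <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("`x` and `y` must have the same length")
  n <- length(x)
  if (n < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for constant input")
  r <- stats::cor(x, y, method = method)
  if (abs(r) >= 1) return(list(r = r, p_two_sided = 0))
  t_stat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p_two_sided = 2 * stats::pt(-abs(t_stat), df = n - 2))
}

#' Mean pairwise correlation of a gene set's profiles
#'
#' @param genes Character vector (>= 2 genes) present in `delta`.
#' @param delta A [delta_matrix].
#' @param method `"pearson"` or `"spearman"`.
#' @return A list with `mean_r` and `mean_abs_r` over all gene pairs.
#' @export
module_coherence <- function(genes, delta, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  genes <- unique(genes)
  if (length(genes) < 2) stop("need at least 2 genes")
  missing <- setdiff(genes, rownames(delta$matrix))
  if (length(missing) > 0)
    stop("genes absent from the delta matrix: ", paste(missing, collapse = ", "))
  cm <- stats::cor(t(delta$matrix[genes, , drop = FALSE]), method = method)
  off <- cm[lower.tri(cm)]
  list(mean_r = mean(off), mean_abs_r = mean(abs(off)))
}
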