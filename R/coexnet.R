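#' Mutual-information estimator configuration
#'
#' @param kernel_width Gaussian kernel width `h > 0` on the rank-uniform
#'   (copula) scale. Mutual information is reported in nats throughout.
#' @return A list of class `mi_config`.
#' @export
mi_config <- function(kernel_width) {
  if (!is.numeric(kernel_width) || kernel_width <= 0)
    stop("`kernel_width` must be > 0")
  structure(list(kernel_width = kernel_width, mi_units = "nats"),
            class = "mi_config")
}

#' Rank-uniform (copula) transform
#'
#' Replaces each gene's values by `rank/(n+1)`, mapping profiles into (0, 1)
#' so the kernel MI estimator is invariant to monotone transforms of the raw
#' data. Ties are mid-ranked; an all-tied profile maps to 0.5 everywhere
#' (with a degeneracy warning).
#'
#' @param delta A [delta_matrix] or a plain genes x samples numeric matrix.
#' @return A numeric matrix of the same shape with values in (0, 1).
#' @export
copula_transform <- function(delta) {
  mat <- if (inherits(delta, "delta_matrix")) delta$matrix else delta
  if (ncol(mat) < 3) stop("need at least 3 samples")
  n <- ncol(mat)
  out <- t(apply(mat, 1, rank, ties.method = "average")) / (n + 1)
  if (any(apply(mat, 1, function(x) all(x == x[1]))))
    warning("constant profile(s): all ranks tied, mapped to 0.5", call. = FALSE)
  dimnames(out) <- dimnames(mat)
  out
}

# Reflected Gaussian kernel matrix for copula-scale data on [0, 1]:
# K[i, j] is the (unnormalized) boundary-corrected kernel of data point j
# evaluated at point i. Reflection at both edges removes the boundary bias
# of the plain kernel density estimate near 0 and 1.
kernel_matrix <- function(u, h) {
  d <- outer(u, u, "-")
  s <- outer(u, u, "+")
  exp(-(d / h)^2 / 2) + exp(-(s / h)^2 / 2) + exp(-((s - 2) / h)^2 / 2)
}

mi_from_kernels <- function(Kx, Ky) {
  mean(log(rowMeans(Kx * Ky)) - log(rowMeans(Kx)) - log(rowMeans(Ky)))
}

# The plain resubstitution estimate at a single width h carries two leading
# bias terms: a variance-driven +a/(n h^2) inflation (self-kernel mass) and
# a smoothing-driven -b h^2 deficit. Evaluating at the three widths
# (0.6, 1, 1.4) * h and solving MI_hat(h_i) = MI + a'/h_i^2 - b h_i^2
# removes both to leading order.
mi_width_ratios <- c(0.6, 1, 1.4)

mi_solve_weights <- function(h) {
  hs <- h * mi_width_ratios
  solve(cbind(1, 1 / hs^2, -hs^2))[1, ]
}

#' Kernel estimate of mutual information (nats)
#'
#' Gaussian-kernel density estimate of \eqn{I(X;Y) =
#' E[\ln f_2(x,y) / (f_1(x) f_1(y))]} on copula-transformed data, with
#' boundary reflection on the unit square and clipping at zero. The estimate
#' is evaluated at three widths around `kernel_width` and the two leading
#' bias terms of the resubstitution estimator (self-kernel inflation
#' \eqn{\propto 1/(n h^2)} and smoothing deficit \eqn{\propto h^2}) are
#' solved out, so for a bivariate Gaussian with correlation \eqn{\rho} the
#' estimate tracks the population value \eqn{-\tfrac12 \ln(1-\rho^2)} nats.
#'
#' @param x,y Copula-transformed numeric vectors of equal length (>= 3).
#' @param config An [mi_config].
#' @return Estimated mutual information in nats (>= 0).
#' @export
mutual_information <- function(x, y, config) {
  if (!inherits(config, "mi_config")) stop("`config` must be an mi_config")
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  h <- config$kernel_width
  wts <- mi_solve_weights(h)
  m <- vapply(h * mi_width_ratios, function(hh)
    mi_from_kernels(kernel_matrix(x, hh), kernel_matrix(y, hh)), numeric(1))
  max(sum(wts * m), 0)
}

# All-pairs MI on a copula-transformed genes x samples matrix, using the
# same three-width bias-corrected evaluation as mutual_information().
mi_all_pairs <- function(u, h) {
  g <- nrow(u)
  hs <- h * mi_width_ratios
  wts <- mi_solve_weights(h)
  K <- lapply(seq_len(g), function(i)
    lapply(hs, function(hh) kernel_matrix(u[i, ], hh)))
  fx <- lapply(K, function(ks) lapply(ks, function(k) log(rowMeans(k))))
  M <- matrix(0, g, g, dimnames = list(rownames(u), rownames(u)))
  for (i in seq_len(g - 1)) {
    for (j in (i + 1):g) {
      m <- vapply(seq_along(hs), function(w)
        mean(log(rowMeans(K[[i]][[w]] * K[[j]][[w]])) -
               fx[[i]][[w]] - fx[[j]][[w]]), numeric(1))
      M[i, j] <- M[j, i] <- max(sum(wts * m), 0)
    }
  }
  M
}

#' Calibrate the MI kernel width against the Gaussian closed form
#'
#' Grid search: for each candidate width, bivariate Gaussian samples are
#' simulated at each correlation in `rho_grid` (sample size `n_samples`,
#' `n_reps` replicates), MI is estimated on the copula scale, and the total
#' mean squared error against the analytic value
#' \eqn{-\tfrac12\ln(1-\rho^2)} is accumulated. The same simulated data are
#' reused across widths so the comparison is exact. Returns the width
#' minimizing total MSE.
#'
#' @param n_samples Sample size the estimator will be used at.
#' @param width_grid Candidate kernel widths.
#' @param n_reps Replicates per correlation (>= 2).
#' @param rho_grid Correlations to simulate at.
#' @param seed Integer seed.
#' @return The optimal width, with the per-width total MSE in attribute
#'   `"mse"`.
#' @export
calibrate_kernel_width <- function(n_samples, width_grid = seq(0.1, 0.4, by = 0.05),
                                   n_reps = 5, rho_grid = c(0, 0.3, 0.6, 0.9),
                                   seed) {
  if (missing(seed)) stop("`seed` is required")
  if (length(width_grid) == 0 || length(rho_grid) == 0) stop("grids must be non-empty")
  if (n_reps < 2) stop("`n_reps` must be >= 2")
  set.seed(as.integer(seed))
  mse <- stats::setNames(numeric(length(width_grid)), width_grid)
  for (rho in rho_grid) {
    target <- -0.5 * log(1 - rho^2)
    for (rep in seq_len(n_reps)) {
      x <- stats::rnorm(n_samples)
      y <- rho * x + sqrt(1 - rho^2) * stats::rnorm(n_samples)
      u <- copula_transform(rbind(x = x, y = y))
      for (w in seq_along(width_grid)) {
        est <- mutual_information(u[1, ], u[2, ], mi_config(width_grid[w]))
        mse[w] <- mse[w] + (est - target)^2
      }
    }
  }
  best <- width_grid[which.min(mse)]
  attr(best, "mse") <- mse
  best
}

#' Calibrate the null distribution of MI for independent profiles
#'
#' Simulates `n_null_pairs` pairs of independent profiles of length
#' `n_samples`, estimates their MI, and fits the log survival function of the
#' null MI as a line, \eqn{\ln P(\mathrm{MI} > I_0) = \alpha + \beta I_0},
#' by least squares over the upper tail (null values above the median, with
#' at least 5 exceedances per point).
#'
#' @param n_samples Profile length.
#' @param n_null_pairs Number of independent pairs (>= 100).
#' @param config An [mi_config].
#' @param seed Integer seed.
#' @return A list of class `null_fit`: `alpha`, `beta` (< 0), `n_samples`,
#'   `kernel_width`, `null_mi` (the simulated values).
#' @export
calibrate_mi_threshold <- function(n_samples, n_null_pairs = 1000, config, seed) {
  if (missing(seed)) stop("`seed` is required")
  if (n_null_pairs < 100) stop("`n_null_pairs` must be >= 100")
  set.seed(as.integer(seed))
  mi <- vapply(seq_len(n_null_pairs), function(i) {
    u <- copula_transform(rbind(stats::rnorm(n_samples), stats::rnorm(n_samples)))
    mutual_information(u[1, ], u[2, ], config)
  }, numeric(1))
  if (stats::sd(mi) == 0) stop("degenerate null: all MI values equal")
  srt <- sort(mi)
  n <- length(srt)
  surv <- (n - seq_len(n) + 1) / n      # P(MI >= srt[i])
  # fit the exponential tail only: the bulk of the null decays more slowly
  # and would flatten the slope, inflating downstream thresholds
  keep <- surv <= 0.2 & surv >= 5 / n
  if (sum(keep) < 3) keep <- surv >= 5 / n
  fit <- stats::lm(log(surv[keep]) ~ srt[keep])
  structure(list(alpha = unname(stats::coef(fit)[1]),
                 beta = unname(stats::coef(fit)[2]),
                 n_samples = n_samples,
                 kernel_width = config$kernel_width,
                 null_mi = mi),
            class = "null_fit")
}

#' MI threshold at a given null P-value
#'
#' Inverts the fitted null survival line: \eqn{I_0 = (\ln p - \alpha)/\beta}.
#'
#' @param fit A `null_fit` from [calibrate_mi_threshold()].
#' @param p Null tail probability in (0, 1].
#' @return The MI threshold `I0` (nats).
#' @export
threshold_for_p <- function(fit, p) {
  if (p <= 0 || p > 1) stop("`p` must be in (0, 1]")
  (log(p) - fit$alpha) / fit$beta
}

#' Data-processing-inequality pruning
#'
#' For every triangle of the weighted graph, the weakest edge is removed when
#' its weight is at most `(1 - tolerance)` times the smaller of the other two
#' weights — the classic interpretation that the weakest of three mutually
#' dependent profiles reflects an indirect interaction. All triangles are
#' examined on the original weights and removals applied simultaneously, so
#' the operation is idempotent.
#'
#' @param graph Weighted undirected igraph (edge attribute `weight`).
#' @param tolerance DPI tolerance in `[0, 1)`; 0 is strictest.
#' @return The pruned graph.
#' @export
apply_dpi <- function(graph, tolerance = 0) {
  if (tolerance < 0 || tolerance >= 1) stop("`tolerance` must be in [0, 1)")
  tri <- matrix(as.integer(igraph::triangles(graph)), nrow = 3)
  if (ncol(tri) == 0) return(graph)
  w <- igraph::E(graph)$weight
  pairs <- rbind(tri[1, ], tri[2, ], tri[1, ], tri[3, ], tri[2, ], tri[3, ])
  eids <- matrix(igraph::get_edge_ids(graph, as.vector(pairs)), nrow = 3)
  W <- matrix(w[eids], nrow = 3)
  wmin <- pmin(W[1, ], W[2, ], W[3, ])
  wmid <- W[1, ] + W[2, ] + W[3, ] - pmax(W[1, ], W[2, ], W[3, ]) - wmin
  weakest_row <- ifelse(W[1, ] == wmin, 1L, ifelse(W[2, ] == wmin, 2L, 3L))
  weak_eid <- eids[cbind(weakest_row, seq_len(ncol(eids)))]
  drop <- unique(weak_eid[wmin <= (1 - tolerance) * wmid])
  igraph::delete_edges(graph, drop)
}

#' Build a mutual-information co-expression network
#'
#' All-pairs kernel MI on copula-transformed baseline-corrected data; edges
#' with MI at or above the calibrated threshold `I0` are kept, and (by
#' default) DPI pruning removes the weakest edge of every triangle.
#'
#' @param delta A [delta_matrix] or genes x samples matrix.
#' @param config An [mi_config].
#' @param I0 MI threshold in nats.
#' @param apply_dpi Apply DPI pruning (default TRUE).
#' @param dpi_tolerance DPI tolerance (default 0).
#' @return An igraph with edge attribute `weight` (MI, nats) and graph
#'   attributes `kernel_width`, `I0`.
#' @export
build_network <- function(delta, config, I0, apply_dpi = TRUE,
                          dpi_tolerance = 0) {
  u <- copula_transform(delta)
  if (nrow(u) < 2) stop("need at least 2 genes")
  M <- mi_all_pairs(u, config$kernel_width)
  M[M < I0] <- 0
  g <- igraph::graph_from_adjacency_matrix(M, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  if (apply_dpi) g <- apply_dpi(g, dpi_tolerance)
  g <- igraph::set_graph_attr(g, "kernel_width", config$kernel_width)
  igraph::set_graph_attr(g, "I0", I0)
}

#' Bootstrap-consensus co-expression network
#'
#' Rebuilds the thresholded MI network on `B` resamples of the subjects
#' (columns, with replacement) and keeps the edges whose support count is
#' improbably high under a binomial null: support `k_e` is compared with
#' `Binomial(B, p_hat)` where `p_hat` is the mean edge density over the
#' bootstrap networks, and an edge is retained when its Bonferroni-corrected
#' upper-tail probability (correction over all edges seen at least once)
#' falls below `q_cutoff`.
#'
#' @param delta A [delta_matrix] or genes x samples matrix.
#' @param config An [mi_config].
#' @param I0 MI threshold (nats).
#' @param B Number of bootstrap cycles (>= 2; default 100).
#' @param q_cutoff Bonferroni-corrected retention cutoff (default 0.001).
#' @param seed Integer seed.
#' @param apply_dpi,dpi_tolerance Passed to [build_network()].
#' @return An igraph with edge attributes `weight` (MI on the full data) and
#'   `support` (bootstrap count), and graph attributes `B`, `p_hat`.
#' @export
bootstrap_consensus <- function(delta, config, I0, B = 100, q_cutoff = 0.001,
                                seed, apply_dpi = TRUE, dpi_tolerance = 0) {
  if (missing(seed)) stop("`seed` is required")
  if (B < 2) stop("consensus undefined for B < 2")
  mat <- if (inherits(delta, "delta_matrix")) delta$matrix else delta
  set.seed(as.integer(seed))
  g <- nrow(mat)
  n_pairs <- g * (g - 1) / 2
  support <- NULL
  dens <- numeric(B)
  for (b in seq_len(B)) {
    idx <- sample(ncol(mat), replace = TRUE)
    net <- build_network(mat[, idx, drop = FALSE], config, I0,
                         apply_dpi = apply_dpi, dpi_tolerance = dpi_tolerance)
    el <- igraph::as_edgelist(net)
    keys <- paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]), sep = "\t")
    dens[b] <- nrow(el) / n_pairs
    support <- if (is.null(support)) table(keys) else {
      tt <- table(keys)
      all_keys <- union(names(support), names(tt))
      s <- stats::setNames(numeric(length(all_keys)), all_keys)
      s[names(support)] <- support
      s[names(tt)] <- s[names(tt)] + tt
      s
    }
  }
  support <- stats::setNames(as.numeric(support), names(support))
  p_hat <- mean(dens)
  n_cand <- length(support)
  pvals <- stats::pbinom(support - 1, B, p_hat, lower.tail = FALSE)
  retained <- names(support)[pvals * n_cand < q_cutoff]
  full <- build_network(mat, config, I0 = 0, apply_dpi = FALSE)
  el <- do.call(rbind, strsplit(retained, "\t"))
  cons <- igraph::make_empty_graph(n = 0, directed = FALSE)
  cons <- igraph::add_vertices(cons, g, name = rownames(mat))
  if (!is.null(el)) {
    w <- vapply(seq_len(nrow(el)), function(i) {
      eid <- igraph::get_edge_ids(full, c(el[i, 1], el[i, 2]))
      if (eid > 0) igraph::E(full)$weight[eid] else 0
    }, numeric(1))
    cons <- igraph::add_edges(cons, t(el))
    igraph::E(cons)$weight <- w
    igraph::E(cons)$support <- unname(support[retained])
  }
  cons <- igraph::set_graph_attr(cons, "B", B)
  cons <- igraph::set_graph_attr(cons, "p_hat", p_hat)
  cons <- igraph::set_graph_attr(cons, "kernel_width", config$kernel_width)
  igraph::set_graph_attr(cons, "I0", I0)
}

# Hurwitz zeta by direct summation plus an Euler-Maclaurin tail.
hurwitz_zeta <- function(gamma, xmin, n_direct = 10000) {
  k <- seq(xmin, xmin + n_direct - 1)
  m <- xmin + n_direct
  sum(k^(-gamma)) + m^(1 - gamma) / (gamma - 1) - 0.5 * m^(-gamma)
}

#' Fit a power-law exponent to a degree distribution
#'
#' Default method regresses log frequency density on log degree over
#' logarithmically binned degrees at or above `xmin`; the `mle` method
#' maximizes the discrete power-law likelihood
#' \eqn{P(k) = k^{-\gamma}/\zeta(\gamma, x_{min})}.
#'
#' @param degrees Integer vector of node degrees (>= 10 positive values).
#' @param method `"loglog_regression"` or `"mle"`.
#' @param xmin Minimum degree included in the fit (default 1).
#' @return A list of class `power_law_fit`: `gamma`, `fit_method`, `xmin`.
#' @export
fit_power_law <- function(degrees, method = c("loglog_regression", "mle"),
                          xmin = 1) {
  method <- match.arg(method)
  degrees <- degrees[degrees >= xmin]
  if (length(degrees) < 10) stop("need >= 10 degrees at or above xmin")
  if (length(unique(degrees)) < 3)
    stop("degree distribution too degenerate for a power-law fit")
  if (method == "mle") {
    nll <- function(g) length(degrees) * log(hurwitz_zeta(g, xmin)) +
      g * sum(log(degrees))
    gamma <- stats::optimize(nll, c(1.05, 6))$minimum
  } else {
    breaks <- xmin * 2^(0:ceiling(log2(max(degrees) / xmin + 1)))
    h <- graphics::hist(degrees, breaks = c(breaks - 0.5, Inf), plot = FALSE)
    dens <- h$counts[seq_along(breaks)] / diff(c(breaks - 0.5, 2 * breaks[length(breaks)]))[seq_along(breaks)]
    mid <- sqrt(breaks * c(breaks[-1], 2 * breaks[length(breaks)]))
    ok <- dens > 0
    if (sum(ok) < 3) stop("too few occupied bins for log-log regression")
    fit <- stats::lm(log(dens[ok]) ~ log(mid[ok]))
    gamma <- -unname(stats::coef(fit)[2])
  }
  if (gamma <= 0) stop("fitted exponent is not positive")
  structure(list(gamma = gamma, fit_method = method, xmin = xmin),
            class = "power_law_fit")
}
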