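# Synthetic diary generator with known ground truth, and the benchmark
# scenario suite used by the acceptance tests.

#' Configuration for the synthetic diary generator
#'
#' Describes a ground-truth data-generating process for diary-like series:
#' stationary VAR(k) cross-lagged dynamics with Gaussian innovations,
#' optional linear time trends, contemporaneous innovation correlation,
#' affine mapping onto the 0-100 VAS scale, completely-at-random missing
#' cells, and an optional random-walk prefix emulating an initial
#' non-stationary adaptation phase.
#'
#' @param n_items Number of items (>= 2).
#' @param A List of K x K lag coefficient matrices (a single matrix is taken
#'   as order 1). Spectral radius of the companion form must be < 1 unless
#'   `nonstationary_prefix > 0` is the point of the scenario.
#' @param Sigma Innovation covariance (symmetric positive definite); its
#'   off-diagonals control same-day correlation.
#' @param trend Per-item linear trend slopes in VAS units per day (recycled).
#' @param T Number of diary days.
#' @param missing_rate Fraction of cells missing completely at random, in
#'   \[0, 0.25\].
#' @param nonstationary_prefix Days of random-walk burn-in prepended (0 =
#'   none); these days are part of the returned series.
#' @param anchor_mean,anchor_sd Target marginal mean and standard deviation
#'   on the VAS scale (defaults 50 and 15, mid-scale with headroom so that
#'   clipping stays rare).
#' @param items Item names; default the first `n_items` of [canonical_items()].
#' @param group Severity group label for the emitted dataset.
#' @param seed Integer seed; identical seeds give identical output.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_items = 2L, A = NULL, Sigma = NULL, trend = 0,
                             T = 120L, missing_rate = 0,
                             nonstationary_prefix = 0L, anchor_mean = 50,
                             anchor_sd = 15, items = NULL,
                             group = c("HSS", "LSS"), seed = 1L) {
  group <- match.arg(group)
  n_items <- as.integer(n_items)
  if (n_items < 2L) dv_stop("need at least 2 items", "diaryvar_config_error")
  if (is.null(A)) A <- diag(0.3, n_items)
  if (is.matrix(A)) A <- list(A)
  if (any(vapply(A, function(a) !all(dim(a) == n_items), logical(1)))) {
    dv_stop("each A matrix must be n_items x n_items", "diaryvar_config_error")
  }
  if (is.null(Sigma)) Sigma <- diag(n_items)
  if (!isSymmetric(unname(Sigma), tol = 1e-10) ||
      any(eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values <= 0)) {
    dv_stop("Sigma must be symmetric positive definite", "diaryvar_config_error")
  }
  if (missing_rate < 0 || missing_rate > 0.25) {
    dv_stop("missing_rate must lie in [0, 0.25]", "diaryvar_config_error")
  }
  stab <- check_stability(A)
  if (!stab$stable && nonstationary_prefix == 0L) {
    dv_stop("unstable coefficients require nonstationary_prefix > 0",
            "diaryvar_config_error")
  }
  if (is.null(items)) items <- canonical_items()[seq_len(n_items)]
  structure(
    list(n_items = n_items, k = length(A), A = A, Sigma = Sigma,
         trend = rep_len(as.numeric(trend), n_items), T = as.integer(T),
         missing_rate = missing_rate,
         nonstationary_prefix = as.integer(nonstationary_prefix),
         anchor_mean = anchor_mean, anchor_sd = anchor_sd, items = items,
         group = group, seed = as.integer(seed), stable = stab$stable),
    class = "synthetic_config")
}

# Stationary covariance Gamma(0) of the VAR via the companion-form discrete
# Lyapunov equation vec(G) = (I - F (x) F)^{-1} vec(Sigma_companion).
.var_gamma0 <- function(A, Sigma) {
  n_vars <- nrow(A[[1]])
  comp <- companion_matrix(A)
  p <- nrow(comp)
  sig_c <- matrix(0, p, p)
  sig_c[seq_len(n_vars), seq_len(n_vars)] <- Sigma
  g <- solve(diag(p^2) - kronecker(comp, comp), as.vector(sig_c))
  matrix(g, p, p)[seq_len(n_vars), seq_len(n_vars), drop = FALSE]
}

#' Generate a synthetic diary dataset
#'
#' Simulates the VAR recursion (after a discarded 200-step burn-in), adds
#' linear trends centred on the midpoint of the stay, affinely maps each item
#' to the VAS anchor (mean `anchor_mean`, marginal SD `anchor_sd` from the
#' theoretical Yule-Walker variance), clips to \[0, 100\], and applies
#' completely-at-random missingness. A warning is raised when clipping
#' affects more than 5% of cells, the regime where the linear-VAR reading of
#' the data starts to break down.
#'
#' @param cfg A [synthetic_config()].
#' @return A list: `data` (a [diary_dataset()]) and `truth` (the config plus
#'   the mapping scale per item, theoretical `gamma0`/`gamma1`, the clipped
#'   fraction, and the index of the first post-prefix day).
#' @export
generate_diary <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  n_vars <- cfg$n_items
  k <- cfg$k
  with_seed(cfg$seed, {
    L <- t(chol(cfg$Sigma))
    n_burn <- 200L
    n_total <- n_burn + cfg$T
    z <- matrix(0, n_total + k, n_vars)
    eps <- matrix(stats::rnorm(n_vars * n_total), n_vars, n_total)
    innov <- t(L %*% eps)
    for (t in (k + 1L):(n_total + k)) {
      acc <- innov[t - k, ]
      for (j in seq_len(k)) acc <- acc + cfg$A[[j]] %*% z[t - j, ]
      z[t, ] <- acc
    }
    z <- z[(n_burn + k + 1L):(n_total + k), , drop = FALSE]

    if (cfg$nonstationary_prefix > 0L) {
      pre_innov <- t(L %*% matrix(stats::rnorm(n_vars * cfg$nonstationary_prefix),
                                  n_vars, cfg$nonstationary_prefix))
      prefix <- apply(pre_innov, 2, cumsum)
      z <- rbind(prefix, z[seq_len(cfg$T - cfg$nonstationary_prefix), , drop = FALSE])
    }

    if (cfg$stable) {
      gamma0 <- .var_gamma0(cfg$A, cfg$Sigma)
      sd_z <- sqrt(diag(gamma0))
    } else {
      gamma0 <- NULL
      sd_z <- rep(1, n_vars)
    }
    scale_f <- cfg$anchor_sd / sd_z
    t_idx <- seq_len(cfg$T)
    trend_part <- outer(t_idx - (cfg$T + 1) / 2, cfg$trend)
    x <- sweep(z, 2, scale_f, `*`) + cfg$anchor_mean + trend_part
    clipped <- mean(x < 0 | x > 100)
    x <- matrix(pmin(100, pmax(0, x)), nrow(x), ncol(x))
    if (clipped > 0.05) {
      dv_warn(sprintf("VAS clipping affects %.1f%% of cells; anchor too close to the bounds",
                      100 * clipped), "diaryvar_clipping_warning")
    }
    if (cfg$missing_rate > 0) {
      miss <- matrix(stats::runif(length(x)) < cfg$missing_rate,
                     nrow(x), ncol(x))
      x[miss] <- NA_real_
    }
    colnames(x) <- cfg$items
    d <- diary_dataset(x, patient_id = sprintf("synthetic_%d", cfg$seed),
                       group = cfg$group)
    gamma1 <- if (cfg$stable) {
      # Gamma(1) = A_1 Gamma(0) + ... via companion form; for reporting keep
      # the order-1 Yule-Walker relation on the top block.
      comp <- companion_matrix(cfg$A)
      g0c <- .var_gamma0_companion(cfg$A, cfg$Sigma)
      (comp %*% g0c)[seq_len(n_vars), seq_len(n_vars), drop = FALSE]
    } else NULL
    truth <- list(config = cfg, scale = scale_f, gamma0 = gamma0,
                  gamma1 = gamma1, clipped_fraction = clipped,
                  stationary_start = cfg$nonstationary_prefix + 1L)
    list(data = d, truth = truth)
  })
}

.var_gamma0_companion <- function(A, Sigma) {
  n_vars <- nrow(A[[1]])
  comp <- companion_matrix(A)
  p <- nrow(comp)
  sig_c <- matrix(0, p, p)
  sig_c[seq_len(n_vars), seq_len(n_vars)] <- Sigma
  matrix(solve(diag(p^2) - kronecker(comp, comp), as.vector(sig_c)), p, p)
}

#' Benchmark scenario suite
#'
#' A named list of [synthetic_config()]s covering the regimes the pipeline
#' must tell apart: no coupling, contemporaneous-only correlation,
#' unidirectional and bidirectional cross-lagged coupling, trend plus
#' coupling, a non-stationary adaptation prefix, and short/long stays
#' matching the observed participation range (39-231 days).
#'
#' @param seed Base seed; per-scenario seeds are derived deterministically.
#' @return Named list of `synthetic_config` objects.
#' @export
make_benchmark_suite <- function(seed = 1L) {
  seed <- as.integer(seed)
  a_null <- diag(0.3, 2)
  a_uni <- matrix(c(0.3, 0.4, 0, 0.3), 2, 2)   # A[2,1] = 0.4: item 1 -> item 2
  a_bi <- matrix(c(0.3, 0.3, 0.3, 0.3), 2, 2)
  sig_corr <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  list(
    null = synthetic_config(A = a_null, T = 120L, seed = seed),
    contemporaneous = synthetic_config(A = a_null, Sigma = sig_corr,
                                       T = 120L, seed = seed + 1L),
    unidirectional = synthetic_config(A = a_uni, T = 200L, seed = seed + 2L),
    bidirectional = synthetic_config(A = a_bi, T = 200L, seed = seed + 3L),
    trend_coupling = synthetic_config(A = a_uni, trend = c(-0.1, -0.1),
                                      T = 200L, seed = seed + 4L),
    nonstationary_prefix = synthetic_config(A = a_uni, T = 160L,
                                            nonstationary_prefix = 40L,
                                            seed = seed + 5L),
    short_series = synthetic_config(A = a_uni, T = 39L, seed = seed + 6L),
    long_series = synthetic_config(A = a_uni, T = 231L, seed = seed + 7L)
  )
}

#' Ground truth of a benchmark scenario, for tests and reports
#'
#' @param name Scenario name from [make_benchmark_suite()].
#' @return List describing the true causal structure: `cause`, `effect` (or
#'   `NULL` when no cross-lagged coupling exists) and `bidirectional`.
#' @export
benchmark_truth <- function(name) {
  switch(name,
    null = ,
    contemporaneous = list(cause = NULL, effect = NULL, bidirectional = FALSE),
    bidirectional = list(cause = canonical_items()[1], effect = canonical_items()[2],
                         bidirectional = TRUE),
    unidirectional = ,
    trend_coupling = ,
    nonstationary_prefix = ,
    short_series = ,
    long_series = list(cause = canonical_items()[1],
                       effect = canonical_items()[2], bidirectional = FALSE),
    dv_stop(sprintf("unknown scenario '%s'", name), "diaryvar_parameter_error"))
}
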