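# Granger causality, impulse responses with Hall bootstrap bands, accumulated
# responses and forecast error variance decomposition.

#' Granger causality test in a bivariate VAR
#'
#' Tests the k zero-restrictions on the lags of `cause` in the equation of
#' `effect` with a Wald statistic; the statistic divided by k is referred to
#' an F distribution with `df1 = k` and `df2 = 2*T_eff - 4*k - 2`, where
#' `T_eff` is the effective sample size (window length minus k). The df2
#' formula is specific to bivariate models, hence `K = 2` is required.
#'
#' @param m A bivariate `var_model`.
#' @param cause,effect Variable names (distinct).
#' @param alpha Significance level (default 0.05).
#' @return A `granger_result`: `cause`, `effect`, `F`, `df1`, `df2`,
#'   `p_value`, `significant`, `wald` (the unscaled chi-square statistic).
#' @export
granger_test <- function(m, cause, effect, alpha = 0.05) {
  stopifnot(inherits(m, "var_model"))
  if (m$K != 2L) {
    dv_stop("the F(k, 2*T_eff - 4k - 2) reference is bivariate-specific (K = 2)",
            "diaryvar_unsupported_dimension")
  }
  if (identical(cause, effect)) {
    dv_stop("cause and effect must differ", "diaryvar_parameter_error")
  }
  ci <- match(cause, m$var_names)
  ei <- match(effect, m$var_names)
  if (anyNA(c(ci, ei))) {
    dv_stop("cause/effect not found among model variables", "diaryvar_parameter_error")
  }
  k <- m$k
  rows <- 1L + (seq_len(k) - 1L) * m$K + ci
  b <- vapply(seq_len(k), function(j) m$A[[j]][ei, ci], numeric(1))
  V <- m$Sigma_u[ei, ei] * m$xtx_inv[rows, rows, drop = FALSE]
  wald <- drop(t(b) %*% solve(V, b))
  f_stat <- wald / k
  df2 <- 2L * m$T_eff - 4L * k - 2L
  p <- stats::pf(f_stat, k, df2, lower.tail = FALSE)
  structure(
    list(cause = cause, effect = effect, F = f_stat, df1 = k, df2 = df2,
         p_value = p, significant = p < alpha, alpha = alpha, wald = wald),
    class = "granger_result")
}

#' @export
print.granger_result <- function(x, ...) {
  cat(sprintf("Granger: %s -> %s, F(%d, %d) = %.2f, p = %.4f%s\n",
              x$cause, x$effect, x$df1, x$df2, x$F, x$p_value,
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Degrees of freedom for the bivariate Granger F test
#'
#' `df2 = 2*(T_w - k) - 4*k - 2` for a bivariate VAR(k) fitted on a window of
#' `T_w` days (effective sample size `T_w - k`).
#'
#' @param window_length Analysis window length in days.
#' @param k VAR order.
#' @return Integer denominator degrees of freedom.
#' @export
granger_df2 <- function(window_length, k) {
  as.integer(2L * (window_length - k) - 4L * k - 2L)
}

# MA coefficient matrices Phi_0..Phi_H from lag matrices (no stability gate).
.ma_coefs <- function(A, H) {
  n_vars <- nrow(A[[1]])
  k <- length(A)
  phi <- vector("list", H + 1L)
  phi[[1]] <- diag(n_vars)
  for (i in seq_len(H)) {
    acc <- matrix(0, n_vars, n_vars)
    for (j in seq_len(min(i, k))) {
      acc <- acc + phi[[i - j + 1L]] %*% A[[j]]
    }
    phi[[i + 1L]] <- acc
  }
  phi
}

# Lower-triangular factor of Sigma under a variable ordering, expressed on the
# original variable positions: P[ord, ord] = chol factor of Sigma[ord, ord].
.chol_under_ordering <- function(Sigma, ord) {
  L <- t(chol(Sigma[ord, ord]))
  P <- matrix(0, nrow(Sigma), ncol(Sigma))
  P[ord, ord] <- L
  dimnames(P) <- dimnames(Sigma)
  P
}

.resolve_ordering <- function(m, ordering) {
  if (is.null(ordering)) return(seq_len(m$K))
  if (is.character(ordering)) ordering <- match(ordering, m$var_names)
  if (anyNA(ordering) || !setequal(ordering, seq_len(m$K))) {
    dv_stop("ordering must be a permutation of the model variables",
            "diaryvar_parameter_error")
  }
  as.integer(ordering)
}

#' Impulse response functions of a stable VAR
#'
#' Computes the moving-average coefficients \eqn{\Phi_0 = I},
#' \eqn{\Phi_i = \sum_{j=1}^{\min(i,k)} \Phi_{i-j} A_j}. With
#' `orthogonalized = TRUE` responses are \eqn{\Theta_i = \Phi_i P}, P the
#' lower Cholesky factor of the residual covariance under the given variable
#' ordering (the first-ordered variable absorbs the contemporaneous
#' correlation). Accumulated paths are running sums over horizons.
#'
#' @param m A stable `var_model`.
#' @param H Horizon in days (>= 1, default 10).
#' @param orthogonalized Orthogonalise via Cholesky? Default `FALSE`.
#' @param ordering Variable ordering (names or indices) for the Cholesky
#'   factor; default the model's column order.
#' @return A `dynamics_result`: `irf` and `accumulated_irf`, arrays of
#'   dimension `(H+1) x K x K` (`[h+1, i, m]` = response of variable i at
#'   horizon h to an impulse in variable m), plus `orthogonalized`,
#'   `ordering`, `horizon` and empty `bands`.
#' @export
compute_irf <- function(m, H = 10L, orthogonalized = FALSE, ordering = NULL) {
  stopifnot(inherits(m, "var_model"))
  H <- as.integer(H)
  if (H < 1L) dv_stop("horizon H must be >= 1", "diaryvar_parameter_error")
  stab <- check_stability(m)
  if (!stab$stable) {
    dv_stop("model violates the eigenvalue stability condition",
            "diaryvar_stability_error")
  }
  ord <- .resolve_ordering(m, ordering)
  irf <- .irf_array(m$A, m$Sigma_u, H, orthogonalized, ord)
  dimnames(irf) <- list(NULL, m$var_names, m$var_names)
  acc <- irf
  for (h in seq_len(H)) acc[h + 1L, , ] <- acc[h, , ] + irf[h + 1L, , ]
  structure(
    list(irf = irf, accumulated_irf = acc, orthogonalized = orthogonalized,
         ordering = m$var_names[ord], horizon = H, bands = NULL),
    class = "dynamics_result")
}

.irf_array <- function(A, Sigma, H, orthogonalized, ord) {
  n_vars <- nrow(A[[1]])
  phi <- .ma_coefs(A, H)
  P <- if (orthogonalized) .chol_under_ordering(Sigma, ord) else diag(n_vars)
  out <- array(0, c(H + 1L, n_vars, n_vars))
  for (i in 0:H) out[i + 1L, , ] <- phi[[i + 1L]] %*% P
  out
}

#' @export
print.dynamics_result <- function(x, ...) {
  cat(sprintf("%s impulse responses, horizon %d, ordering (%s)\n",
              if (x$orthogonalized) "orthogonalised" else "plain",
              x$horizon, paste(x$ordering, collapse = ", ")))
  cat("accumulated responses at the final horizon:\n")
  print(x$accumulated_irf[x$horizon + 1L, , ])
  invisible(x)
}

#' Choose the Cholesky ordering from Granger test outcomes
#'
#' If exactly one direction is significant, the Granger-cause variable is
#' ordered first; if both or neither are, the supplied default (canonical
#' item order) is kept and a warning is raised, since the orthogonalised
#' quantities then rest on an arbitrary choice.
#'
#' @param g_xy,g_yx `granger_result`s for the two directions on one model.
#' @param default Character vector, the fallback ordering.
#' @return Character vector of length 2, first element ordered first.
#' @export
choose_ordering <- function(g_xy, g_yx, default) {
  stopifnot(inherits(g_xy, "granger_result"), inherits(g_yx, "granger_result"))
  if (g_xy$significant && !g_yx$significant) {
    c(g_xy$cause, g_xy$effect)
  } else if (g_yx$significant && !g_xy$significant) {
    c(g_yx$cause, g_yx$effect)
  } else {
    dv_warn(sprintf(
      "%s: falling back to the default ordering (%s)",
      if (g_xy$significant) "both directions Granger-significant"
      else "neither direction Granger-significant",
      paste(default, collapse = ", ")), "diaryvar_ordering_fallback")
    default
  }
}

#' Bootstrap confidence bands for impulse responses
#'
#' Residual-based recursive bootstrap: centred residuals are resampled with
#' replacement, a series is rebuilt from the fitted model using the original
#' first k observations as starting values, the VAR is re-estimated at the
#' same order and its IRF recomputed. Intervals are Hall percentile intervals
#' \eqn{[2\hat\theta - q^*_{1-\alpha/2},\; 2\hat\theta - q^*_{\alpha/2}]} by
#' default (`type = "percentile"` gives the plain percentile interval). A
#' response at a horizon is flagged significant when its band excludes 0.
#'
#' @param m A `var_model` fitted on `y`.
#' @param y The estimation sample (defaults to the data stored on `m`).
#' @param H Horizon.
#' @param B Number of bootstrap replications (>= 100; default 1000).
#' @param alpha Band level is `1 - alpha` (default 0.05).
#' @param seed Integer seed (bands are deterministic given the seed).
#' @param orthogonalized,ordering As in [compute_irf()].
#' @param type `"hall"` (default) or `"percentile"`.
#' @return A list with `lower`, `upper` (arrays `(H+1) x K x K`),
#'   `significant` (band excludes 0), `B`, `dropped` (failed replicates),
#'   `type`, `seed`, and `point` (the point-estimate IRF array).
#' @export
bootstrap_irf_bands <- function(m, y = m$y, H = 10L, B = 1000L, alpha = 0.05,
                                seed = NULL, orthogonalized = FALSE,
                                ordering = NULL, type = c("hall", "percentile")) {
  stopifnot(inherits(m, "var_model"))
  type <- match.arg(type)
  B <- as.integer(B)
  if (B < 100L) dv_stop("need at least B = 100 bootstrap replications",
                        "diaryvar_parameter_error")
  H <- as.integer(H)
  ord <- .resolve_ordering(m, ordering)
  point <- .irf_array(m$A, m$Sigma_u, H, orthogonalized, ord)
  y <- as.matrix(y)
  t_len <- nrow(y)
  k <- m$k
  n_vars <- m$K
  u <- scale(m$residuals, center = TRUE, scale = FALSE)
  t_eff <- nrow(u)
  A <- m$A
  nu <- m$nu
  draws <- array(NA_real_, c(B, H + 1L, n_vars, n_vars))
  dropped <- 0L
  with_seed(seed, {
    for (b in seq_len(B)) {
      u_star <- u[sample.int(t_eff, t_eff, replace = TRUE), , drop = FALSE]
      y_star <- matrix(0, t_len, n_vars)
      y_star[seq_len(k), ] <- y[seq_len(k), , drop = FALSE]
      for (t in (k + 1L):t_len) {
        acc <- nu + u_star[t - k, ]
        for (j in seq_len(k)) acc <- acc + A[[j]] %*% y_star[t - j, ]
        y_star[t, ] <- acc
      }
      fit <- tryCatch(fit_var(y_star, k), diaryvar_error = function(e) NULL)
      if (is.null(fit)) {
        dropped <- dropped + 1L
        next
      }
      draws[b, , , ] <- .irf_array(fit$A, fit$Sigma_u, H, orthogonalized, ord)
    }
  })
  if (dropped > 0.1 * B) {
    dv_stop(sprintf("%d of %d bootstrap replicates failed re-estimation",
                    dropped, B), "diaryvar_bootstrap_error")
  }
  probs <- c(alpha / 2, 1 - alpha / 2)
  lower <- upper <- array(NA_real_, dim(point))
  for (i in seq_len(n_vars)) {
    for (mm in seq_len(n_vars)) {
      q <- apply(draws[, , i, mm, drop = FALSE], 2, stats::quantile,
                 probs = probs, na.rm = TRUE, names = FALSE)
      if (type == "hall") {
        lower[, i, mm] <- 2 * point[, i, mm] - q[2, ]
        upper[, i, mm] <- 2 * point[, i, mm] - q[1, ]
      } else {
        lower[, i, mm] <- q[1, ]
        upper[, i, mm] <- q[2, ]
      }
    }
  }
  dimnames(lower) <- dimnames(upper) <-
    list(NULL, m$var_names, m$var_names)
  list(lower = lower, upper = upper, significant = lower > 0 | upper < 0,
       B = B, dropped = dropped, type = type, seed = seed, alpha = alpha,
       orthogonalized = orthogonalized, ordering = m$var_names[ord],
       point = point)
}

#' Forecast error variance decomposition
#'
#' Shares of the h-step forecast-error variance of each variable attributable
#' to orthogonalised innovations in each variable, for h = 1..H:
#' \deqn{\omega_{jm}(h) = \sum_{i=0}^{h-1} \Theta_i[j,m]^2 \Big/
#'   \sum_{i=0}^{h-1} \sum_{m'} \Theta_i[j,m']^2.}
#'
#' @param m A stable `var_model`.
#' @param H Horizon (default 10).
#' @param ordering Cholesky ordering, as in [compute_irf()].
#' @return A `fevd_result` with `proportions`, an `H x K x K` array
#'   (`[h, j, m]` = share of variable j's h-step variance due to variable m);
#'   rows sum to one.
#' @export
fevd <- function(m, H = 10L, ordering = NULL) {
  stopifnot(inherits(m, "var_model"))
  dyn <- compute_irf(m, H = H, orthogonalized = TRUE, ordering = ordering)
  theta2 <- dyn$irf^2
  props <- array(NA_real_, c(H, m$K, m$K),
                 dimnames = list(NULL, m$var_names, m$var_names))
  csum <- apply(theta2, c(2, 3), cumsum)  # (H+1) x K x K cumulative sums
  for (h in seq_len(H)) {
    num <- csum[h, , ]
    props[h, , ] <- num / rowSums(num)
  }
  structure(list(proportions = props, horizon = H, ordering = dyn$ordering),
            class = "fevd_result")
}

#' @export
print.fevd_result <- function(x, ...) {
  cat(sprintf("FEVD at horizon %d (ordering %s):\n", x$horizon,
              paste(x$ordering, collapse = ", ")))
  print(round(100 * x$proportions[x$horizon, , ], 1))
  invisible(x)
}
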