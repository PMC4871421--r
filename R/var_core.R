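# VAR(k) estimation, information-criterion lag selection, diagnostics and the
# iterative re-estimation loop.

# Build the lagged design for y over rows (k+1)..T: [1, y_{t-1}, ..., y_{t-k}].
.var_design <- function(y, k, rows = (k + 1L):nrow(y)) {
  n_vars <- ncol(y)
  X <- matrix(1, length(rows), 1L + n_vars * k)
  for (j in seq_len(k)) {
    X[, 1L + (j - 1L) * n_vars + seq_len(n_vars)] <- y[rows - j, , drop = FALSE]
  }
  X
}

#' Fit a vector autoregression of order k
#'
#' Multivariate least squares with intercept: each variable is regressed on k
#' lags of all variables. The residual covariance is the residual
#' cross-product divided by `T_eff - K*k - 1` (degrees-of-freedom adjusted);
#' per-coefficient standard errors, t-ratios and two-sided p-values are
#' computed with the same denominator degrees of freedom.
#'
#' @param y Numeric matrix, T x K, no missing values; column names become
#'   variable names.
#' @param k Model order (number of lags), >= 1.
#' @param window Optional [analysis_window()] recorded on the model.
#' @return A `var_model`: `K`, `k`, `nu` (intercepts), `A` (list of K x K lag
#'   coefficient matrices; `A[[j]][i, m]` weights variable m at lag j in
#'   equation i), `Sigma_u`, `residuals` (T_eff x K), `T_eff`, `coef_table`
#'   (estimate/se/t/p per coefficient), `se_nu`, and the data `y`.
#' @export
fit_var <- function(y, k, window = NULL) {
  y <- as.matrix(y)
  storage.mode(y) <- "double"
  if (anyNA(y)) dv_stop("series contains missing values", "diaryvar_parameter_error")
  n_vars <- ncol(y)
  k <- as.integer(k)
  if (k < 1L) dv_stop("order k must be >= 1", "diaryvar_parameter_error")
  t_len <- nrow(y)
  t_eff <- t_len - k
  n_par <- n_vars * k + 1L
  if (t_eff <= n_vars * k + 1L) {
    dv_stop(sprintf("series too short: T_eff = %d <= K*k + 1 = %d",
                    t_eff, n_vars * k + 1L), "diaryvar_length_error")
  }
  if (any(apply(y, 2, stats::var) == 0)) {
    dv_stop("constant series cannot enter a VAR", "diaryvar_rank_error")
  }
  vn <- colnames(y)
  if (is.null(vn)) vn <- paste0("y", seq_len(n_vars))
  colnames(y) <- vn

  X <- .var_design(y, k)
  Y <- y[(k + 1L):t_len, , drop = FALSE]
  fit <- dv_mls(X, Y, "collinear or constant series: VAR design rank deficient")
  df_resid <- t_eff - n_vars * k - 1L
  Sigma_u <- crossprod(fit$resid) / df_resid
  dimnames(Sigma_u) <- list(vn, vn)

  nu <- fit$coef[1L, ]
  A <- lapply(seq_len(k), function(j) {
    Aj <- t(fit$coef[1L + (j - 1L) * n_vars + seq_len(n_vars), , drop = FALSE])
    dimnames(Aj) <- list(vn, vn)
    Aj
  })

  se_mat <- sqrt(outer(diag(fit$xtx_inv), diag(Sigma_u)))  # (n_par) x K
  t_mat <- fit$coef / se_mat
  p_mat <- 2 * stats::pt(-abs(t_mat), df_resid)
  rn <- c("const", unlist(lapply(seq_len(k), function(j) paste0(vn, ".l", j))))
  coef_table <- data.frame(
    equation = rep(vn, each = n_par),
    term = rep(rn, n_vars),
    lag = rep(c(0L, rep(seq_len(k), each = n_vars)), n_vars),
    estimate = as.vector(fit$coef),
    se = as.vector(se_mat),
    t = as.vector(t_mat),
    p = as.vector(p_mat),
    stringsAsFactors = FALSE)

  structure(
    list(K = n_vars, k = k, nu = nu, A = A, Sigma_u = Sigma_u,
         residuals = fit$resid, T_eff = t_eff, df_resid = df_resid,
         coef_table = coef_table, xtx_inv = fit$xtx_inv,
         var_names = vn, y = y, window = window),
    class = "var_model")
}

#' @export
print.var_model <- function(x, ...) {
  cat(sprintf("VAR(%d) in %d variables (%s), T_eff = %d\n", x$k, x$K,
              paste(x$var_names, collapse = ", "), x$T_eff))
  sig <- subset(x$coef_table, x$coef_table$lag > 0 & x$coef_table$p < 0.05)
  if (nrow(sig)) {
    cat("significant lag coefficients (p < 0.05):\n")
    print(sig[, c("equation", "term", "estimate", "p")], row.names = FALSE)
  } else {
    cat("no significant lag coefficients at 0.05\n")
  }
  invisible(x)
}

#' Companion matrix of a VAR
#'
#' @param m A `var_model`, or a list of coefficient matrices.
#' @return The (K*k) x (K*k) companion form.
#' @export
companion_matrix <- function(m) {
  A <- if (inherits(m, "var_model")) m$A else m
  n_vars <- nrow(A[[1]])
  k <- length(A)
  comp <- matrix(0, n_vars * k, n_vars * k)
  comp[seq_len(n_vars), ] <- do.call(cbind, A)
  if (k > 1L) {
    comp[(n_vars + 1L):(n_vars * k), seq_len(n_vars * (k - 1L))] <-
      diag(n_vars * (k - 1L))
  }
  comp
}

#' Check the eigenvalue stability condition
#'
#' @param m A `var_model` or list of lag coefficient matrices.
#' @return List with `moduli` (sorted decreasing) and `stable` (all < 1).
#' @export
check_stability <- function(m) {
  moduli <- sort(Mod(eigen(companion_matrix(m), only.values = TRUE)$values),
                 decreasing = TRUE)
  list(moduli = moduli, stable = all(moduli < 1))
}

#' Select the VAR lag order by information criteria
#'
#' All candidate orders 1..`p_max` are fitted on the same effective sample
#' (the first `p_max` observations are reserved as presample). Criteria use
#' the ML residual covariance `Sigma_ml(p) = U'U / N` with `N = T - p_max`:
#' \itemize{
#'   \item AIC: `log det Sigma_ml + 2 p K^2 / N`
#'   \item HQ:  `log det Sigma_ml + 2 log(log N) p K^2 / N`
#'   \item SC:  `log det Sigma_ml + log(N) p K^2 / N`
#'   \item FPE: `((N + pK + 1) / (N - pK - 1))^K det Sigma_ml`
#' }
#' The consensus order is the one chosen by the majority of the four
#' criteria, ties broken toward the smallest order (parsimony first).
#'
#' @param y Numeric matrix, T x K.
#' @param p_max Largest candidate order; default `min(10, floor(T/10))`.
#' @return A `lag_selection`: per-criterion chosen orders, `consensus`,
#'   `p_max`, and the criterion table.
#' @export
select_lag_order <- function(y, p_max = NULL) {
  y <- as.matrix(y)
  t_len <- nrow(y)
  n_vars <- ncol(y)
  if (is.null(p_max)) p_max <- min(10L, floor(t_len / 10))
  p_max <- as.integer(p_max)
  if (p_max < 1L) dv_stop("p_max must be >= 1", "diaryvar_parameter_error")
  n_common <- t_len - p_max
  if (n_common <= n_vars * p_max + 1L) {
    dv_stop("series too short for the requested p_max", "diaryvar_length_error")
  }
  rows <- (p_max + 1L):t_len
  Y <- y[rows, , drop = FALSE]
  crit <- matrix(NA_real_, p_max, 4L,
                 dimnames = list(NULL, c("AIC", "FPE", "HQ", "SC")))
  for (p in seq_len(p_max)) {
    X <- .var_design(y, p, rows)
    fit <- dv_mls(X, Y)
    sigma_ml <- crossprod(fit$resid) / n_common
    ld <- determinant(sigma_ml, logarithm = TRUE)$modulus[1]
    pen <- p * n_vars^2 / n_common
    crit[p, "AIC"] <- ld + 2 * pen
    crit[p, "HQ"] <- ld + 2 * log(log(n_common)) * pen
    crit[p, "SC"] <- ld + log(n_common) * pen
    crit[p, "FPE"] <- ((n_common + n_vars * p + 1) /
                         (n_common - n_vars * p - 1))^n_vars * exp(ld)
  }
  chosen <- apply(crit, 2, which.min)
  tab <- table(factor(chosen, levels = seq_len(p_max)))
  consensus <- as.integer(names(tab)[tab == max(tab)][1])  # smallest modal order
  structure(
    list(orders = as.list(chosen), consensus = consensus, p_max = p_max,
         criteria = crit),
    class = "lag_selection")
}

#' @export
print.lag_selection <- function(x, ...) {
  cat(sprintf("lag selection (p_max = %d): AIC %d, FPE %d, HQ %d, SC %d -> consensus %d\n",
              x$p_max, x$orders$AIC, x$orders$FPE, x$orders$HQ, x$orders$SC,
              x$consensus))
  invisible(x)
}

#' Residual diagnostics for a fitted VAR
#'
#' Computes the companion eigenvalue moduli (stability requires all < 1) and
#' the small-sample adjusted (Ljung-Box-type) multivariate Portmanteau
#' statistic over residual autocovariances at lags 1..`h`,
#' \deqn{Q_h = T^2 \sum_{j=1}^h (T-j)^{-1}
#'   \mathrm{tr}(C_j' C_0^{-1} C_j C_0^{-1}),}
#' referred to a chi-square with `K^2 (h - k)` degrees of freedom.
#'
#' @param m A `var_model`.
#' @param h Maximum Portmanteau lag; must exceed the model order. Default
#'   `min(16, floor(T_eff / 4))` (at least `k + 1`).
#' @return A `var_diagnostics`: `moduli`, `stable`, `portmanteau`
#'   (statistic, df, p_value, h), `residual_acf`.
#' @export
run_diagnostics <- function(m, h = NULL) {
  stopifnot(inherits(m, "var_model"))
  if (is.null(h)) h <- max(m$k + 1L, min(16L, floor(m$T_eff / 4)))
  h <- as.integer(h)
  if (h <= m$k) dv_stop("Portmanteau lag h must exceed the model order k",
                        "diaryvar_parameter_error")
  stab <- check_stability(m)
  u <- m$residuals
  t_eff <- nrow(u)
  u <- scale(u, center = TRUE, scale = FALSE)
  C0 <- crossprod(u) / t_eff
  C0_inv <- solve(C0)
  q_stat <- 0
  racf <- array(NA_real_, c(h, m$K, m$K))
  d0 <- sqrt(diag(C0))
  for (j in seq_len(h)) {
    Cj <- crossprod(u[(j + 1L):t_eff, , drop = FALSE],
                    u[seq_len(t_eff - j), , drop = FALSE]) / t_eff
    q_stat <- q_stat + sum(diag(t(Cj) %*% C0_inv %*% Cj %*% C0_inv)) / (t_eff - j)
    racf[j, , ] <- Cj / outer(d0, d0)
  }
  q_stat <- q_stat * t_eff^2
  df <- m$K^2 * (h - m$k)
  structure(
    list(moduli = stab$moduli, stable = stab$stable,
         portmanteau = list(statistic = q_stat, df = df,
                            p_value = stats::pchisq(q_stat, df, lower.tail = FALSE),
                            h = h),
         residual_acf = racf),
    class = "var_diagnostics")
}

#' @export
print.var_diagnostics <- function(x, ...) {
  cat(sprintf("stability: max |eigenvalue| = %.4f -> %s\n", max(x$moduli),
              if (x$stable) "stable" else "NOT stable"))
  cat(sprintf("Portmanteau (adjusted, h = %d): Q = %.3f, df = %d, p = %.4f\n",
              x$portmanteau$h, x$portmanteau$statistic, x$portmanteau$df,
              x$portmanteau$p_value))
  invisible(x)
}

#' Fit a VAR with the diagnostic re-estimation loop
#'
#' Starts at the consensus order from [select_lag_order()] (parsimony first)
#' and, while the adjusted Portmanteau test rejects white-noise residuals at
#' 0.05 or the eigenvalue stability condition fails, increments the order up
#' to `p_max`. Returns the first model passing both checks.
#'
#' @param y Numeric matrix, T x K.
#' @param selection Optional precomputed `lag_selection`.
#' @param p_max Largest order tried; default as in [select_lag_order()].
#' @param h Portmanteau lag passed to [run_diagnostics()].
#' @param alpha Diagnostic level (default 0.05).
#' @param window Optional [analysis_window()] recorded on the model.
#' @return A `var_model` with an added `diagnostics` field and an
#'   `adjustment_log` listing each order tried and why it was rejected.
#' @export
fit_with_adjustment <- function(y, selection = NULL, p_max = NULL, h = NULL,
                                alpha = 0.05, window = NULL) {
  y <- as.matrix(y)
  if (is.null(p_max)) p_max <- min(10L, floor(nrow(y) / 10))
  if (is.null(selection)) selection <- select_lag_order(y, p_max)
  log_entries <- list()
  for (k in seq(selection$consensus, p_max)) {
    m <- tryCatch(fit_var(y, k, window = window),
                  diaryvar_error = function(e) e)
    if (inherits(m, "error")) {
      log_entries[[length(log_entries) + 1L]] <-
        list(order = k, outcome = paste("fit failed:", conditionMessage(m)))
      next
    }
    diag_res <- run_diagnostics(m, h = if (is.null(h)) NULL else max(h, k + 1L))
    ok_stable <- diag_res$stable
    ok_wn <- diag_res$portmanteau$p_value >= alpha
    log_entries[[length(log_entries) + 1L]] <- list(
      order = k,
      outcome = if (ok_stable && ok_wn) "accepted" else paste0(
        "rejected (", paste(c(if (!ok_stable) "unstable",
                              if (!ok_wn) sprintf("Portmanteau p = %.4f",
                                                  diag_res$portmanteau$p_value)),
                            collapse = "; "), ")"))
    if (ok_stable && ok_wn) {
      m$diagnostics <- diag_res
      m$adjustment_log <- log_entries
      m$selection <- selection
      return(m)
    }
  }
  dv_stop(sprintf("no VAR order in %d..%d satisfies stability and white-noise residuals",
                  selection$consensus, p_max),
          "diaryvar_no_valid_model")
}
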