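# Augmented Dickey-Fuller testing and analysis-window determination.
#
# P-values use the MacKinnon (1994) response-surface approximation
# p = pnorm(polynomial(tau)), with the published coefficient sets for the
# constant-only and constant+trend regressions (one I(1) variable).

.mackinnon <- list(
  constant = list(
    tau_star = -1.61, tau_min = -18.83, tau_max = 2.74,
    small = c(2.1659, 1.4412, 0.038269),
    large = c(1.7339, 0.93202, -0.12745, -0.010368)),
  trend = list(
    tau_star = -2.89, tau_min = -16.18, tau_max = 0.7,
    small = c(3.2512, 1.6047, 0.049588),
    large = c(2.5261, 0.61654, -0.37956, -0.060285))
)

.mackinnon_p <- function(tau, variant) {
  tab <- .mackinnon[[variant]]
  if (tau > tab$tau_max) return(1)
  if (tau < tab$tau_min) return(0)
  co <- if (tau <= tab$tau_star) tab$small else tab$large
  stats::pnorm(sum(co * tau^(seq_along(co) - 1)))
}

#' Schwert rule of thumb for the maximum ADF augmentation lag
#'
#' @param t_len Series length.
#' @return `floor(12 * (t_len / 100)^0.25)`.
#' @export
schwert_max_lags <- function(t_len) {
  max(0L, as.integer(floor(12 * (t_len / 100)^0.25)))
}

#' Augmented Dickey-Fuller unit-root test
#'
#' Fits the ADF regression
#' \deqn{\Delta x_t = \phi x_{t-1} + \sum_{j=1}^{q} \beta_j \Delta x_{t-j} +
#'   \mu (+ \delta t) + \varepsilon_t}
#' choosing the augmentation order q in 0..`max_lags` by minimum AIC on a
#' common estimation sample, then refitting at the chosen q on all usable
#' observations. The test statistic is the t-ratio of \eqn{\phi}; its p-value
#' comes from the MacKinnon response-surface approximation. Rejecting the unit
#' root (p < `alpha`) indicates stationarity.
#'
#' @param x Numeric series without missing values.
#' @param variant Deterministic terms: `"constant"` (default) or `"trend"`
#'   (constant plus linear trend).
#' @param max_lags Largest augmentation lag considered; defaults to the
#'   Schwert rule [schwert_max_lags()].
#' @param alpha Significance level (default 0.05).
#' @return An `adf_result`: `statistic` (tau), `lags`, `variant`, `p_value`,
#'   `reject_unit_root`, `alpha`, `nobs`.
#' @export
adf_test <- function(x, variant = c("constant", "trend"), max_lags = NULL,
                     alpha = 0.05) {
  variant <- match.arg(variant)
  x <- as.numeric(x)
  if (anyNA(x)) dv_stop("series contains missing values", "diaryvar_parameter_error")
  t_len <- length(x)
  if (stats::var(x) == 0) {
    dv_stop("constant series: unit-root test undefined", "diaryvar_degenerate_error")
  }
  if (is.null(max_lags)) max_lags <- schwert_max_lags(t_len)
  max_lags <- as.integer(max_lags)
  if (t_len - max_lags - 1L < 15L) {
    max_lags <- max(0L, t_len - 16L)
  }
  if (t_len - max_lags - 1L < 15L) {
    dv_stop("series too short for ADF regression (need >= 16 usable points)",
            "diaryvar_length_error")
  }
  dx <- diff(x)

  build <- function(q, common_start) {
    # rows are t = start..t_len (index into x), responding with dx[t-1]
    start <- max(q + 2L, common_start)
    idx <- start:t_len
    X <- cbind(lag1 = x[idx - 1L], const = 1)
    if (variant == "trend") X <- cbind(X, trend = idx)
    if (q > 0L) {
      lags <- sapply(seq_len(q), function(j) dx[idx - 1L - j])
      X <- cbind(X, lags)
    }
    list(X = X, y = dx[idx - 1L], n = length(idx))
  }

  common_start <- max_lags + 2L
  aics <- vapply(0:max_lags, function(q) {
    m <- build(q, common_start)
    fit <- dv_mls(m$X, cbind(m$y))
    rss <- sum(fit$resid^2)
    m$n * log(rss / m$n) + 2 * ncol(m$X)
  }, numeric(1))
  q_best <- which.min(aics) - 1L

  m <- build(q_best, q_best + 2L)
  fit <- dv_mls(m$X, cbind(m$y))
  df <- m$n - ncol(m$X)
  sigma2 <- sum(fit$resid^2) / df
  tau <- fit$coef[1, 1] / sqrt(sigma2 * fit$xtx_inv[1, 1])
  p <- .mackinnon_p(tau, variant)
  structure(
    list(statistic = unname(tau), lags = q_best, variant = variant,
         p_value = p, reject_unit_root = p < alpha, alpha = alpha, nobs = m$n),
    class = "adf_result")
}

#' @export
print.adf_result <- function(x, ...) {
  cat(sprintf("ADF test (%s): tau = %.4f, lags = %d, p = %.4f -> %s\n",
              x$variant, x$statistic, x$lags, x$p_value,
              if (x$reject_unit_root) "stationary (unit root rejected)"
              else "unit root not rejected"))
  invisible(x)
}

#' Construct an analysis window
#'
#' @param start_day,end_day Inclusive 1-based bounds on the diary day index.
#' @param stationary_items Optional item names known stationary on the window.
#' @return An `analysis_window` with `start_day`, `end_day`, `length`.
#' @export
analysis_window <- function(start_day, end_day, stationary_items = character()) {
  start_day <- as.integer(start_day); end_day <- as.integer(end_day)
  if (start_day < 1L || end_day < start_day) {
    dv_stop("need 1 <= start_day <= end_day", "diaryvar_parameter_error")
  }
  structure(list(start_day = start_day, end_day = end_day,
                 length = end_day - start_day + 1L,
                 stationary_items = stationary_items),
            class = "analysis_window")
}

#' @export
print.analysis_window <- function(x, ...) {
  cat(sprintf("analysis window: days %d-%d (length %d)\n",
              x$start_day, x$end_day, x$length))
  invisible(x)
}

#' Determine the stable analysis window for a focus pair
#'
#' If both focus items reject the unit root on the full participation period,
#' the full period is used. Otherwise candidate windows with start offsets
#' 0, `step`, 2*`step`, ... and end offsets likewise are scanned and the
#' longest window of at least `T_min` days on which both focus items are
#' stationary is returned, ties broken toward the earliest start. This
#' automates, deterministically, the stepwise inspection otherwise done by
#' eye; per-patient manual overrides can be supplied through the pipeline
#' configuration.
#'
#' @param d A complete (post-imputation) [diary_dataset()].
#' @param focus_items Character vector of the two focus item names.
#' @param step Scan step in days (default 7).
#' @param alpha ADF significance level.
#' @param T_min Minimum admissible window length (default 30).
#' @param variant,max_lags Passed to [adf_test()].
#' @return An `analysis_window`.
#' @export
find_stationary_window <- function(d, focus_items, step = 7L, alpha = 0.05,
                                   T_min = 30L, variant = "constant",
                                   max_lags = NULL) {
  stopifnot(inherits(d, "diary_dataset"), length(focus_items) == 2L)
  if (!all(focus_items %in% d$items)) {
    dv_stop("focus items not present in dataset", "diaryvar_parameter_error")
  }
  y <- d$values[, focus_items, drop = FALSE]
  if (anyNA(y)) {
    dv_stop("focus series must be complete (impute first)",
            "diaryvar_parameter_error")
  }
  t_len <- nrow(y)
  passes <- function(s, e) {
    all(vapply(seq_len(2L), function(j) {
      r <- tryCatch(adf_test(y[s:e, j], variant = variant, max_lags = max_lags,
                             alpha = alpha),
                    diaryvar_error = function(e) NULL)
      !is.null(r) && r$reject_unit_root
    }, logical(1)))
  }
  if (t_len >= T_min && passes(1L, t_len)) {
    return(analysis_window(1L, t_len, focus_items))
  }
  starts <- seq(1L, t_len, by = step)
  ends <- rev(seq(t_len, 1L, by = -step))
  cand <- expand.grid(start = starts, end = ends)
  cand <- cand[cand$end - cand$start + 1L >= T_min, , drop = FALSE]
  if (nrow(cand) > 0L) {
    cand <- cand[order(-(cand$end - cand$start), cand$start), , drop = FALSE]
    # skip the full range: already tested above
    for (i in seq_len(nrow(cand))) {
      s <- cand$start[i]; e <- cand$end[i]
      if (s == 1L && e == t_len) next
      if (passes(s, e)) {
        return(analysis_window(s, e, focus_items))
      }
    }
  }
  dv_stop(sprintf("no stationary window of length >= %d found for (%s)",
                  T_min, paste(focus_items, collapse = ", ")),
          "diaryvar_no_stationary_window")
}
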