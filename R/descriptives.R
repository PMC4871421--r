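# Linear time trends (standardised coefficients) and same-day correlations.

#' Linear time trend of a diary series
#'
#' Standardised coefficient from the regression of the z-scored series on the
#' z-scored day index; algebraically this equals the Pearson correlation of
#' the series with time. Two-sided t test with T - 2 degrees of freedom, no
#' serial-correlation correction (plain OLS inference).
#'
#' @param x Numeric series without missing values.
#' @param alpha Significance level (default 0.05).
#' @return A `trend_result`: `beta`, `p_value`, `significant`, `T`.
#' @export
linear_trend <- function(x, alpha = 0.05) {
  x <- as.numeric(x)
  t_len <- length(x)
  if (t_len < 3L) dv_stop("need at least 3 observations", "diaryvar_length_error")
  if (anyNA(x)) dv_stop("series contains missing values", "diaryvar_parameter_error")
  if (stats::var(x) == 0) {
    dv_stop("constant series has no trend", "diaryvar_degenerate_error")
  }
  beta <- stats::cor(x, seq_len(t_len))
  if (abs(beta) >= 1) {
    p <- 0
  } else {
    t_stat <- beta * sqrt((t_len - 2) / (1 - beta^2))
    p <- 2 * stats::pt(-abs(t_stat), t_len - 2)
  }
  structure(list(beta = beta, p_value = p, significant = p < alpha,
                 T = t_len, alpha = alpha),
            class = "trend_result")
}

#' Same-day Pearson correlation on an analysis window
#'
#' @param x,y Numeric series of equal length (full diary index).
#' @param window Optional [analysis_window()]; defaults to the full range.
#' @param alpha Significance level.
#' @return A `correlation_result`: `r`, `p_value`, `significant`, `window`.
#' @export
same_day_correlation <- function(x, y, window = NULL, alpha = 0.05) {
  x <- as.numeric(x); y <- as.numeric(y)
  stopifnot(length(x) == length(y))
  if (is.null(window)) window <- analysis_window(1L, length(x))
  idx <- window$start_day:window$end_day
  if (length(idx) < 3L) dv_stop("window too short for a correlation",
                                "diaryvar_length_error")
  xs <- x[idx]; ys <- y[idx]
  if (anyNA(xs) || anyNA(ys)) {
    dv_stop("series contain missing values on the window", "diaryvar_parameter_error")
  }
  if (stats::var(xs) == 0 || stats::var(ys) == 0) {
    dv_stop("constant series on the window", "diaryvar_degenerate_error")
  }
  ct <- stats::cor.test(xs, ys)
  structure(list(r = unname(ct$estimate), p_value = ct$p.value,
                 significant = ct$p.value < alpha, window = window,
                 alpha = alpha),
            class = "correlation_result")
}

#' Cohort summary of per-patient linear trends
#'
#' Aggregates per-patient, per-item trend results into group percentages of
#' significant trends and of significant negative trends (one decimal place,
#' the convention of cohort trend tables).
#'
#' @param results Data frame with columns `patient`, `group`, `item`, `beta`,
#'   `p_value`, `significant` (one row per patient x item).
#' @return Data frame with one row per group x item: `n_patients`,
#'   `pct_significant`, `pct_significant_negative`.
#' @export
cohort_trend_summary <- function(results) {
  need <- c("patient", "group", "item", "beta", "significant")
  if (!all(need %in% names(results))) {
    dv_stop(sprintf("results must have columns %s", paste(need, collapse = ", ")),
            "diaryvar_parameter_error")
  }
  groups <- unique(results$group)
  groups <- c(intersect(c("HSS", "LSS"), groups), setdiff(groups, c("HSS", "LSS")))
  out <- do.call(rbind, lapply(groups, function(g) {
    sub <- results[results$group == g, , drop = FALSE]
    do.call(rbind, lapply(unique(sub$item), function(it) {
      cell <- sub[sub$item == it, , drop = FALSE]
      n <- nrow(cell)
      data.frame(group = g, item = it, n_patients = n,
                 pct_significant = round(100 * mean(cell$significant), 1),
                 pct_significant_negative =
                   round(100 * mean(cell$significant & cell$beta < 0), 1),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}
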