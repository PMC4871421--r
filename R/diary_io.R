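#' Canonical diary item names
#'
#' The six visual-analogue-scale items recorded in the electronic diaries, in
#' the fixed canonical order used everywhere a deterministic ordering is
#' needed: emotional intolerance, food impact on emotions, restraint over
#' eating, weight concern, fear of losing control over eating, and
#' preoccupation with food.
#'
#' @return Character vector of length six.
#' @export
canonical_items <- function() {
  c("emotional_intolerance", "food_impact", "restraint",
    "weight_concern", "fear_losing_control", "preoccupation_food")
}

#' Construct a daily diary dataset
#'
#' A `diary_dataset` holds one patient's daily multivariate series of
#' visual-analogue-scale (VAS) items, each value in \[0, 100\] or missing, on a
#' gap-free day grid indexed 1..T.
#'
#' @param values Numeric matrix, T days x n items; `NA` marks a missing cell.
#' @param patient_id Patient identifier.
#' @param group Severity group label, `"HSS"` or `"LSS"`.
#' @param items Item names; defaults to `colnames(values)`.
#' @return An object of class `diary_dataset` with fields `patient_id`,
#'   `group`, `day`, `items`, `values` and `missing_mask`.
#' @export
diary_dataset <- function(values, patient_id = "patient", group = c("HSS", "LSS"),
                          items = colnames(values)) {
  group <- match.arg(group)
  values <- as.matrix(values)
  if (is.null(items)) {
    items <- paste0("item", seq_len(ncol(values)))
  }
  if (nrow(values) < 1L || ncol(values) < 1L) {
    dv_stop("diary values must have at least one day and one item",
            "diaryvar_validation_error")
  }
  if (length(items) != ncol(values)) {
    dv_stop("length of `items` must match the number of value columns",
            "diaryvar_validation_error")
  }
  storage.mode(values) <- "double"
  bad <- which(!is.na(values) & (values < 0 | values > 100), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    dv_stop(sprintf("value %.6g out of [0,100] at day %d, item '%s'",
                    values[bad[1, 1], bad[1, 2]], bad[1, 1], items[bad[1, 2]]),
            "diaryvar_validation_error")
  }
  dimnames(values) <- list(NULL, items)
  structure(
    list(patient_id = as.character(patient_id), group = group,
         day = seq_len(nrow(values)), items = items, values = values,
         missing_mask = is.na(values)),
    class = "diary_dataset")
}

#' @export
print.diary_dataset <- function(x, ...) {
  cat(sprintf("diary_dataset: patient %s (%s), T = %d days, %d items\n",
              x$patient_id, x$group, length(x$day), length(x$items)))
  cat(sprintf("  items: %s\n", paste(x$items, collapse = ", ")))
  cat(sprintf("  missing cells: %d of %d\n", sum(x$missing_mask),
              length(x$missing_mask)))
  invisible(x)
}

#' @export
dim.diary_dataset <- function(x) dim(x$values)

#' Read a diary CSV file
#'
#' Ingests a wide CSV with header columns `patient_id,group,day,<item...>`.
#' Days absent from the file become all-missing rows so that the returned day
#' grid is gap-free and equally spaced (a requirement for lagged modelling);
#' the grid is re-indexed to 1..T starting at the earliest recorded day.
#'
#' @param path Path to the CSV file.
#' @param schema Optional character vector naming (and ordering) the item
#'   columns to keep; defaults to every non-key column in file order.
#' @return A [diary_dataset()].
#' @export
read_diary <- function(path, schema = NULL) {
  if (!file.exists(path)) {
    dv_stop(sprintf("no such file: '%s'", path), "diaryvar_format_error")
  }
  raw <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                    na.strings = c("", "NA")),
    error = function(e) {
      dv_stop(sprintf("malformed CSV '%s': %s", path, conditionMessage(e)),
              "diaryvar_format_error")
    })
  need <- c("patient_id", "group", "day")
  if (!all(need %in% names(raw))) {
    dv_stop(sprintf("CSV must have columns %s", paste(need, collapse = ", ")),
            "diaryvar_format_error")
  }
  items <- if (is.null(schema)) setdiff(names(raw), need) else schema
  if (length(items) < 1L || !all(items %in% names(raw))) {
    dv_stop("no item columns found matching the schema", "diaryvar_format_error")
  }
  day <- suppressWarnings(as.integer(raw$day))
  if (anyNA(day)) {
    dv_stop("non-integer day index", "diaryvar_format_error")
  }
  if (anyDuplicated(day)) {
    dv_stop(sprintf("duplicate day %d", day[anyDuplicated(day)]),
            "diaryvar_validation_error")
  }
  vals <- as.matrix(raw[, items, drop = FALSE])
  if (!is.numeric(vals)) {
    suppressWarnings(storage.mode(vals) <- "double")
    if (anyNA(vals) && !all(is.na(raw[, items][is.na(vals)]))) {
      dv_stop("non-numeric item value", "diaryvar_format_error")
    }
  }
  for (j in seq_along(items)) {
    bad <- which(!is.na(vals[, j]) & (vals[, j] < 0 | vals[, j] > 100))
    if (length(bad) > 0L) {
      dv_stop(sprintf("value %.6g out of [0,100] at day %d, item '%s'",
                      vals[bad[1], j], day[bad[1]], items[j]),
              "diaryvar_validation_error")
    }
  }
  grid <- seq(min(day), max(day))
  full <- matrix(NA_real_, length(grid), length(items),
                 dimnames = list(NULL, items))
  full[match(day, grid), ] <- vals
  diary_dataset(full,
                patient_id = as.character(raw$patient_id[1]),
                group = as.character(raw$group[1]))
}

#' Write a diary dataset to CSV
#'
#' Emits the same wide dialect [read_diary()] consumes: header
#' `patient_id,group,day,<item...>`, one row per day, missing cells empty.
#'
#' @param d A [diary_dataset()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_diary <- function(d, path) {
  stopifnot(inherits(d, "diary_dataset"))
  out <- data.frame(patient_id = d$patient_id, group = d$group, day = d$day,
                    d$values, check.names = FALSE)
  utils::write.csv(out, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' Regression imputation of missing diary cells
#'
#' Replaces each missing cell of item j by the least-squares prediction from a
#' regression of item j on the other same-day items plus a linear day-index
#' term, fitted on fully observed rows. When some predictors are themselves
#' missing on a given day, the regression is refitted on the subset of items
#' observed that day (falling back to the day-only trend model when no other
#' item is available). Predictions are clamped to the VAS range \[0, 100\].
#' Observed cells are never altered.
#'
#' @param d A [diary_dataset()].
#' @param add_noise If `TRUE`, a seeded draw from the fitted residual
#'   distribution (normal, residual standard deviation) is added to each
#'   imputed value. Off by default for reproducibility.
#' @param seed Integer seed for the noise draws; required when `add_noise`.
#' @param max_missing Maximum tolerated fraction of missing cells per item
#'   (default 0.25).
#' @return A list with elements `data` (complete [diary_dataset()]) and
#'   `report` (an `imputation_report`: per-item imputed counts, per-cell
#'   provenance, and the coefficient vectors used).
#' @export
impute_missing <- function(d, add_noise = FALSE, seed = NULL, max_missing = 0.25) {
  stopifnot(inherits(d, "diary_dataset"))
  mask <- d$missing_mask
  n_items <- length(d$items)
  t_len <- length(d$day)
  provenance <- matrix("observed", t_len, n_items, dimnames = list(NULL, d$items))
  provenance[mask] <- "imputed"
  report <- structure(
    list(n_imputed = colSums(mask), provenance = provenance,
         coefficients = stats::setNames(vector("list", n_items), d$items)),
    class = "imputation_report")
  if (!any(mask)) {
    return(list(data = d, report = report))
  }
  if (add_noise && is.null(seed)) {
    dv_stop("`seed` is required when add_noise = TRUE", "diaryvar_parameter_error")
  }
  complete_rows <- rowSums(mask) == 0L
  for (j in seq_len(n_items)) {
    if (!any(mask[, j])) next
    if (all(mask[, j])) {
      dv_stop(sprintf("item '%s' has no observed values", d$items[j]),
              "diaryvar_imputation_error")
    }
    if (mean(mask[, j]) > max_missing) {
      dv_stop(sprintf("item '%s': %.1f%% missing exceeds the %.0f%% cap",
                      d$items[j], 100 * mean(mask[, j]), 100 * max_missing),
              "diaryvar_imputation_error")
    }
    if (sum(complete_rows) < 10L) {
      dv_stop("fewer than 10 complete rows available for regression imputation",
              "diaryvar_imputation_error")
    }
  }

  values <- d$values
  day_c <- as.numeric(d$day)
  fit_cache <- new.env(parent = emptyenv())
  fit_for <- function(j, predictors) {
    key <- paste(j, paste(predictors, collapse = ","), sep = "|")
    if (!is.null(fit_cache[[key]])) return(fit_cache[[key]])
    train <- if (length(predictors)) {
      complete_rows  # all items observed, a superset of what this model needs
    } else {
      !mask[, j]
    }
    X <- cbind(intercept = 1, day = day_c[train])
    if (length(predictors)) X <- cbind(X, values[train, predictors, drop = FALSE])
    fit <- dv_mls(X, values[train, j, drop = FALSE],
                  "collinear predictors in imputation regression")
    sigma <- sqrt(sum(fit$resid^2) / max(1, nrow(X) - ncol(X)))
    out <- list(coef = drop(fit$coef), sigma = sigma, predictors = predictors)
    fit_cache[[key]] <- out
    out
  }

  with_seed(if (add_noise) seed else NULL, {
    for (j in seq_len(n_items)) {
      rows <- which(mask[, j])
      if (!length(rows)) next
      for (t in rows) {
        predictors <- d$items[!mask[t, ] & seq_len(n_items) != j]
        fit <- fit_for(j, predictors)
        x_new <- c(1, day_c[t], if (length(predictors)) values[t, predictors])
        pred <- sum(fit$coef * x_new)
        if (add_noise) pred <- pred + stats::rnorm(1L, 0, fit$sigma)
        values[t, j] <- min(100, max(0, pred))
      }
      report$coefficients[[j]] <- fit_for(j, d$items[-j])$coef
    }
  })

  out <- d
  out$values <- values
  out$missing_mask <- matrix(FALSE, t_len, n_items, dimnames = dimnames(mask))
  list(data = out, report = report)
}

#' @export
print.imputation_report <- function(x, ...) {
  cat("imputation_report\n")
  for (nm in names(x$n_imputed)) {
    cat(sprintf("  %s: %d cells imputed\n", nm, x$n_imputed[[nm]]))
  }
  invisible(x)
}
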