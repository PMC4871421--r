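make_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, na = "")
  path
}

test_that("read_diary ingests a complete file and round-trips through write_diary", {
  df <- data.frame(patient_id = "p1", group = "HSS", day = 1:5,
                   emotional_intolerance = c(10, 30, 50, 70, 90),
                   restraint = c(90, 70, 50, 30, 10))
  d <- read_diary(make_csv(df))
  expect_s3_class(d, "diary_dataset")
  expect_equal(dim(d), c(5L, 2L))
  expect_equal(sum(d$missing_mask), 0L)
  expect_equal(unname(d$values[, "emotional_intolerance"]), c(10, 30, 50, 70, 90))
  expect_equal(d$group, "HSS")

  out <- tempfile(fileext = ".csv")
  write_diary(d, out)
  d2 <- read_diary(out)
  expect_equal(d2$values, d$values)
  expect_equal(d2$items, d$items)
})

test_that("absent days become all-missing rows on a gap-free grid", {
  df <- data.frame(patient_id = "p1", group = "LSS", day = c(1, 2, 4),
                   a = c(10, 20, 40), b = c(5, 15, 35))
  d <- read_diary(make_csv(df))
  expect_equal(length(d$day), 4L)
  expect_true(all(d$missing_mask[3, ]))
  expect_false(any(d$missing_mask[-3, ]))
  expect_equal(unname(d$values[4, "a"]), 40)
})

test_that("validation rejects out-of-range values and duplicate days", {
  df <- data.frame(patient_id = "p", group = "HSS", day = 1:3,
                   a = c(10, 105, 20), b = c(1, 2, 3))
  expect_error(read_diary(make_csv(df)), class = "diaryvar_validation_error")
  expect_error(read_diary(make_csv(df)), "105")

  df2 <- data.frame(patient_id = "p", group = "HSS", day = c(1, 2, 2),
                    a = c(1, 2, 3), b = c(1, 2, 3))
  expect_error(read_diary(make_csv(df2)), class = "diaryvar_validation_error")

  expect_error(read_diary(tempfile()), class = "diaryvar_format_error")
  expect_error(diary_dataset(matrix(c(-1, 5, 5, 5), 2, 2)),
               class = "diaryvar_validation_error")
})

test_that("imputation is the identity on complete data", {
  set.seed(11)
  d <- diary_dataset(matrix(runif(30, 20, 80), 15, 2,
                            dimnames = list(NULL, c("a", "b"))))
  res <- impute_missing(d)
  expect_identical(res$data$values, d$values)
  expect_equal(unname(res$report$n_imputed), c(0L, 0L))
})

test_that("a collinear generating rule forces the regression prediction", {
  # item2 = 2 * item1 exactly: the normal equations on the 11 complete rows
  # give the unique exact-fit coefficients, so the prediction is 2 * item1.
  set.seed(7)
  item1 <- round(runif(12, 10, 40), 3)
  vals <- cbind(item1 = item1, item2 = 2 * item1)
  vals[5, "item2"] <- NA
  d <- diary_dataset(vals)
  res <- impute_missing(d)
  expect_equal(unname(res$data$values[5, "item2"]), 2 * item1[5], tolerance = 1e-10)
  expect_equal(unname(res$report$n_imputed), c(0L, 1L))
  expect_equal(unname(res$report$provenance[5, "item2"]), "imputed")
})

test_that("imputed predictions match an independent normal-equations solve", {
  set.seed(21)
  for (rep in 1:3) {
    z <- sim_var(18, matrix(c(0.4, 0.2, 0.1, 0.3), 2, 2), seed = 30 + rep)
    vals <- vas_matrix(z)
    colnames(vals) <- c("a", "b")
    miss_row <- sample(3:16, 1)
    truth_free <- vals
    vals[miss_row, "b"] <- NA
    d <- diary_dataset(vals)
    res <- impute_missing(d)
    # oracle: solve the normal equations directly on the complete rows
    keep <- setdiff(seq_len(18), miss_row)
    X <- cbind(1, keep, truth_free[keep, "a"])
    beta <- solve(t(X) %*% X, t(X) %*% truth_free[keep, "b"])
    pred <- sum(c(1, miss_row, truth_free[miss_row, "a"]) * beta)
    expect_equal(unname(res$data$values[miss_row, "b"]), min(100, max(0, pred)),
                 tolerance = 1e-10)
  }
})

test_that("observed cells are never altered and noise is seed-deterministic", {
  set.seed(3)
  z <- sim_var(40, diag(0.3, 2), seed = 101)
  vals <- vas_matrix(z)
  colnames(vals) <- c("a", "b")
  mask <- matrix(runif(length(vals)) < 0.1, nrow(vals))
  vals_na <- vals
  vals_na[mask] <- NA
  d <- diary_dataset(vals_na)

  r1 <- impute_missing(d, add_noise = TRUE, seed = 99)
  r2 <- impute_missing(d, add_noise = TRUE, seed = 99)
  expect_identical(r1$data$values, r2$data$values)
  expect_false(identical(r1$data$values,
                         impute_missing(d, add_noise = TRUE, seed = 100)$data$values))
  # observed-cell preservation
  expect_identical(r1$data$values[!mask], vals[!mask])
  expect_equal(sum(r1$report$provenance == "imputed"), sum(mask & !is.na(vals)))
})

test_that("imputation preconditions are enforced", {
  vals <- matrix(runif(10, 20, 80), 5, 2, dimnames = list(NULL, c("a", "b")))
  vals[2, 1] <- NA
  expect_error(impute_missing(diary_dataset(vals)),
               class = "diaryvar_imputation_error")

  vals2 <- matrix(runif(80, 20, 80), 40, 2, dimnames = list(NULL, c("a", "b")))
  vals2[1:20, 1] <- NA  # 50% missing on item a
  expect_error(impute_missing(diary_dataset(vals2)),
               class = "diaryvar_imputation_error")

  vals3 <- matrix(runif(40, 20, 80), 20, 2, dimnames = list(NULL, c("a", "b")))
  vals3[, 2] <- NA
  expect_error(impute_missing(diary_dataset(vals3)),
               class = "diaryvar_imputation_error")
})
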