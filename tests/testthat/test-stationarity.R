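test_that("ADF decisions are right on archetypal series", {
  set.seed(1001)
  rw <- cumsum(rnorm(300))
  iid <- rnorm(300)
  r_rw <- adf_test(rw)
  r_iid <- adf_test(iid)
  expect_false(r_rw$reject_unit_root)
  expect_true(r_iid$reject_unit_root)
  expect_equal(r_rw$reject_unit_root, r_rw$p_value < r_rw$alpha)
  expect_equal(r_iid$reject_unit_root, r_iid$p_value < r_iid$alpha)
})

test_that("ADF statistic, lag choice and p-value match statsmodels", {
  set.seed(2002)
  series <- list(ar = as.vector(arima.sim(list(ar = 0.6), 250)),
                 rw = cumsum(rnorm(250)))
  # the same search range is pinned on both sides (the default rule differs:
  # Schwert floor here vs a ceiling rule in the reference implementation)
  tasks <- lapply(names(series), function(nm) {
    list(id = nm, kind = "adf", data = data.frame(x = series[[nm]]),
         variant = "constant", max_lags = 8)
  })
  res <- run_oracle(tasks)
  for (nm in names(series)) {
    mine <- adf_test(series[[nm]], max_lags = 8)
    expect_equal(mine$lags, res[[nm]]$lags, info = nm)
    expect_equal(mine$statistic, res[[nm]]$tau, tolerance = 1e-8, info = nm)
    expect_equal(mine$p_value, res[[nm]]$p_value, tolerance = 1e-6, info = nm)
  }
})

test_that("ADF rejects degenerate inputs", {
  expect_error(adf_test(rep(50, 50)), class = "diaryvar_degenerate_error")
  expect_error(adf_test(rnorm(10)), class = "diaryvar_length_error")
})

test_that("a fully stationary pair keeps the complete treatment period", {
  z <- sim_var(120, matrix(c(0.4, 0.2, 0.1, 0.3), 2, 2), seed = 5)
  vals <- vas_matrix(z)
  colnames(vals) <- c("emotional_intolerance", "restraint")
  d <- diary_dataset(vals)
  w <- find_stationary_window(d, c("emotional_intolerance", "restraint"))
  expect_equal(c(w$start_day, w$end_day), c(1L, 120L))
})

test_that("the length gate yields a no-stationary-window error", {
  set.seed(6)
  vals <- vas_matrix(matrix(rnorm(200), 100, 2))
  colnames(vals) <- c("a", "b")
  d <- diary_dataset(vals)
  expect_error(find_stationary_window(d, c("a", "b"), T_min = 200),
               class = "diaryvar_no_stationary_window")
})

test_that("a random-walk prefix is cut away and the returned window passes ADF", {
  cfg <- make_benchmark_suite(21)$nonstationary_prefix
  sim <- suppressWarnings(generate_diary(cfg))
  d <- sim$data
  focus <- cfg$items
  # the full range must indeed be non-stationary for this scenario to bite
  full_rejects <- vapply(focus, function(it) {
    adf_test(d$values[, it])$reject_unit_root
  }, logical(1))
  expect_false(all(full_rejects))
  w <- find_stationary_window(d, focus, step = 7)
  expect_gt(w$start_day, 1L)   # at least part of the prefix is cut away
  expect_equal(w$end_day, 160L)
  # window-validity invariant: both focus items reject the unit root there
  for (it in focus) {
    expect_true(adf_test(d$values[w$start_day:w$end_day, it])$reject_unit_root)
  }
  # every strictly longer candidate window fails ADF for at least one item
  starts <- seq(1, 160, by = 7)
  ends <- rev(seq(160, 1, by = -7))
  for (s in starts) {
    for (e in ends) {
      if (e - s <= w$end_day - w$start_day) next
      ok <- vapply(focus, function(it) {
        adf_test(d$values[s:e, it])$reject_unit_root
      }, logical(1))
      expect_false(all(ok), label = sprintf("window %d-%d should fail", s, e))
    }
  }
})

test_that("enlarging T_min never lengthens the chosen window", {
  cfg <- make_benchmark_suite(21)$nonstationary_prefix
  sim <- suppressWarnings(generate_diary(cfg))
  w30 <- find_stationary_window(sim$data, cfg$items, T_min = 30)
  w60 <- find_stationary_window(sim$data, cfg$items, T_min = 60)
  expect_lte(w60$length, w30$length)
})
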