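test_that("VAR coefficients equal the hand-solved per-equation OLS solution", {
  y <- cbind(y1 = c(1, 2, 3, 4, 5, 6), y2 = c(2, 1, 2, 1, 2, 1))
  m <- fit_var(y, 1)
  # oracle: equation-by-equation normal equations on the 5 usable rows
  X <- cbind(1, y[1:5, ])
  for (eq in 1:2) {
    b <- solve(t(X) %*% X, t(X) %*% y[2:6, eq])
    expect_equal(m$nu[[eq]], b[1], tolerance = 1e-10)
    expect_equal(unname(m$A[[1]][eq, ]), unname(b[2:3]), tolerance = 1e-10)
  }
})

test_that("multivariate LS equals equation-by-equation lm on random instances", {
  set.seed(31)
  for (rep in 1:5) {
    k <- sample(1:3, 1)
    y <- sim_var(60, replicate(k, diag(runif(2, 0, 0.3)), simplify = FALSE),
                 seed = 300 + rep)
    m <- fit_var(y, k)
    emb <- stats::embed(y, k + 1L)
    for (eq in 1:2) {
      fit <- lm(emb[, eq] ~ emb[, -(1:2)])
      mine <- c(m$nu[eq], unlist(lapply(m$A, function(a) a[eq, ])))
      expect_equal(unname(mine), unname(coef(fit)), tolerance = 1e-10)
    }
  }
})

test_that("estimates recover the truth at large T within three standard errors", {
  A <- matrix(c(0.5, 0.2, 0.0, 0.4), 2, 2, byrow = TRUE)
  y <- sim_var(2000, A, seed = 77)
  m <- fit_var(y, 1)
  expect_true(all(abs(m$A[[1]] - A) < 0.07))
  expect_true(all(abs(m$Sigma_u - diag(2)) < 0.15))
  # residual means vanish and Sigma_u is symmetric
  expect_lt(max(abs(colMeans(m$residuals))), 1e-8)
  expect_lt(max(abs(m$Sigma_u - t(m$Sigma_u))), 1e-10)
  expect_equal(m$T_eff, 1999L)
})

test_that("length and rank preconditions are enforced", {
  expect_error(fit_var(matrix(rnorm(8), 4, 2), 2), class = "diaryvar_length_error")
  y <- cbind(a = rnorm(30), b = rep(5, 30))
  expect_error(fit_var(y, 1), class = "diaryvar_rank_error")
})

test_that("information criteria pick the generating order in strong-signal simulations", {
  A1 <- matrix(c(0.6, 0.2, 0.15, 0.55), 2, 2)  # spectral radius ~0.7
  sel1 <- select_lag_order(sim_var(1000, A1, seed = 41), p_max = 6)
  expect_equal(sel1$consensus, 1L)

  A3 <- list(diag(0.2, 2), diag(0, 2),
             matrix(c(0.45, 0.2, 0.2, 0.45), 2, 2))
  sel3 <- select_lag_order(sim_var(1500, A3, seed = 42), p_max = 6)
  expect_equal(sel3$consensus, 3L)

  expect_error(select_lag_order(sim_var(100, A1, seed = 1), p_max = 0),
               class = "diaryvar_parameter_error")
})

test_that("the SC-chosen order never exceeds the AIC-chosen order", {
  set.seed(51)
  for (rep in 1:8) {
    y <- sim_var(80 + 20 * rep, diag(runif(2, 0.1, 0.5)), seed = 500 + rep)
    sel <- select_lag_order(y, p_max = 5)
    expect_lte(sel$orders$SC, sel$orders$AIC)
  }
})

test_that("companion eigenvalues agree with closed forms and polynomial roots", {
  expect_equal(check_stability(list(diag(0.5, 2)))$moduli, c(0.5, 0.5))
  expect_false(check_stability(list(diag(1, 2)))$stable)

  # K = 2, k <= 3: moduli equal reciprocals of det(I - A(z)) root moduli
  set.seed(61)
  for (rep in 1:4) {
    k <- sample(1:3, 1)
    A <- replicate(k, matrix(runif(4, -0.3, 0.3), 2, 2), simplify = FALSE)
    moduli <- check_stability(A)$moduli
    coef_mat <- function(i, j) {
      co <- numeric(k + 1)
      co[1] <- as.numeric(i == j)
      for (l in seq_len(k)) co[l + 1] <- -A[[l]][i, j]
      co
    }
    # det of the 2x2 matrix polynomial via polynomial arithmetic
    pmul <- function(a, b) {
      out <- numeric(length(a) + length(b) - 1L)
      for (i in seq_along(a)) out[i + seq_along(b) - 1L] <-
          out[i + seq_along(b) - 1L] + a[i] * b
      out
    }
    det_poly <- pmul(coef_mat(1, 1), coef_mat(2, 2)) -
      pmul(coef_mat(1, 2), coef_mat(2, 1))
    roots <- polyroot(det_poly)
    expect_equal(sort(moduli[moduli > 1e-10], decreasing = TRUE),
                 sort(1 / Mod(roots), decreasing = TRUE), tolerance = 1e-8)
  }
})

test_that("Portmanteau p-values are roughly uniform under the true model", {
  # Monte-Carlo calibration: share of p < 0.05 within the stated band
  set.seed(71)
  hits <- 0L
  n_rep <- 200L
  for (rep in seq_len(n_rep)) {
    y <- sim_var(150, matrix(c(0.4, 0.1, 0.1, 0.4), 2, 2), burn = 50)
    m <- fit_var(y, 1)
    d <- run_diagnostics(m, h = 10)
    hits <- hits + (d$portmanteau$p_value < 0.05)
  }
  expect_gte(hits / n_rep, 0.02)
  expect_lte(hits / n_rep, 0.09)
})

test_that("diagnostics validate their inputs", {
  m <- fit_var(sim_var(60, diag(0.3, 2), seed = 9), 2)
  expect_error(run_diagnostics(m, h = 2), class = "diaryvar_parameter_error")
  d <- run_diagnostics(m, h = 8)
  expect_equal(d$portmanteau$df, 4 * (8 - 2))
  expect_identical(d$stable, max(d$moduli) < 1)
})

test_that("the adjustment loop accepts a clean VAR(1) at order 1", {
  y <- sim_var(200, matrix(c(0.5, 0.1, 0.1, 0.4), 2, 2), seed = 81)
  m <- fit_with_adjustment(y)
  expect_equal(m$k, m$selection$consensus)
  expect_true(m$diagnostics$stable)
  expect_gte(m$diagnostics$portmanteau$p_value, 0.05)
})

test_that("MA-contaminated innovations push the loop past order 1", {
  # y follows a VAR(1) whose innovations are MA(1): residual autocorrelation
  # at an order-1 fit triggers re-estimation at a higher order
  set.seed(82)
  t_len <- 400
  e <- matrix(rnorm((t_len + 101) * 2), t_len + 101, 2)
  u <- e[-1, ] + 0.8 * e[-(t_len + 101), ]
  A <- diag(0.3, 2)
  y <- matrix(0, t_len + 100, 2)
  for (t in 2:(t_len + 100)) y[t, ] <- A %*% y[t - 1, ] + u[t, ]
  y <- y[101:(t_len + 100), ]
  colnames(y) <- c("x1", "x2")
  sel1 <- list(consensus = 1L, orders = list(AIC = 1L, FPE = 1L, HQ = 1L, SC = 1L),
               p_max = 8L)
  class(sel1) <- "lag_selection"
  m1 <- fit_var(y, 1)
  expect_lt(run_diagnostics(m1, h = 10)$portmanteau$p_value, 0.05)
  m <- fit_with_adjustment(y, selection = sel1, p_max = 8, h = 10)
  expect_gt(m$k, 1L)
  expect_equal(m$adjustment_log[[1]]$order, 1L)
})

test_that("an explosive process admits no valid model", {
  set.seed(83)
  t_len <- 80
  y <- matrix(0, t_len, 2)
  y[1, ] <- rnorm(2)
  for (t in 2:t_len) y[t, ] <- 1.05 * y[t - 1, ] + rnorm(2)
  expect_error(fit_with_adjustment(y, p_max = 3),
               class = "diaryvar_no_valid_model")
})
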