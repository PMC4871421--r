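# Internal helpers: classed conditions and small numerics shared across modules.

dv_stop <- function(msg, class, ...) {
  stop(errorCondition(msg, ..., class = c(class, "diaryvar_error", "error")))
}

dv_warn <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "diaryvar_warning", "warning")))
}

#' @keywords internal
is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Least-squares fit of Y (n x m) on X (n x p) via QR; errors on rank deficiency.
# Returns coefficients, residuals and (X'X)^{-1}.
dv_mls <- function(X, Y, rank_msg = "design matrix is rank deficient") {
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    dv_stop(rank_msg, "diaryvar_rank_error")
  }
  B <- qr.coef(qr_x, Y)
  U <- Y - X %*% B
  xtx_inv <- chol2inv(qr.R(qr_x))
  list(coef = B, resid = U, xtx_inv = xtx_inv)
}

# Seed scoping: run code under a seed without clobbering the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}
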