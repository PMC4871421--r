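# Shared simulation helpers, deliberately independent of the package's own
# generator so they can serve as oracles for it.

sim_var <- function(t_len, A, Sigma = diag(nrow(A[[1]])), seed = NULL,
                    burn = 100L, names = c("x1", "x2", "x3", "x4")) {
  if (is.matrix(A)) A <- list(A)
  n_vars <- nrow(A[[1]])
  k <- length(A)
  if (!is.null(seed)) set.seed(seed)
  L <- t(chol(Sigma))
  n <- burn + t_len
  y <- matrix(0, n + k, n_vars)
  for (t in (k + 1L):(n + k)) {
    acc <- as.vector(L %*% rnorm(n_vars))
    for (j in seq_len(k)) acc <- acc + as.vector(A[[j]] %*% y[t - j, ])
    y[t, ] <- acc
  }
  out <- y[(burn + k + 1L):(n + k), , drop = FALSE]
  colnames(out) <- names[seq_len(n_vars)]
  out
}

# Construct a minimal var_model-shaped object from true parameters, for
# closed-form checks of IRF/FEVD machinery that need no estimation step.
true_var_model <- function(A, Sigma, names = c("x1", "x2")) {
  if (is.matrix(A)) A <- list(A)
  n_vars <- nrow(A[[1]])
  dimnames(Sigma) <- list(names[1:n_vars], names[1:n_vars])
  structure(list(K = n_vars, k = length(A), A = A, Sigma_u = Sigma,
                 var_names = names[seq_len(n_vars)]),
            class = "var_model")
}

# Small diary dataset builder on the VAS scale.
vas_matrix <- function(z, mean = 50, sd = 12) {
  x <- mean + sd * scale(z)
  matrix(pmin(100, pmax(0, x)), nrow(z), ncol(z),
         dimnames = list(NULL, colnames(z)))
}
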