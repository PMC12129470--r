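# deterministic fixtures built in code

make_gaussian_data <- function(n, beta, sigma = 1, seed = 1, intercept = 0) {
  set.seed(seed)
  M <- length(beta)
  X <- matrix(rnorm(n * M), n, M, dimnames = list(NULL, paste0("x", seq_len(M))))
  d <- tibble::as_tibble(as.data.frame(X))
  d$y <- intercept + drop(X %*% beta) + rnorm(n, 0, sigma)
  d
}

# columns orthogonal, mean zero, population sd exactly 1
make_orthonormal_x <- function(n, M, seed = 1) {
  set.seed(seed)
  A <- scale(matrix(rnorm(n * (M + 1)), n), center = TRUE, scale = FALSE)
  Q <- qr.Q(qr(A))[, seq_len(M), drop = FALSE]
  X <- sqrt(n) * Q
  colnames(X) <- paste0("x", seq_len(M))
  X
}

tiny_design <- function(N, seed = 1, n_sims = 2L) {
  sim_design(N, n_sims = n_sims, seed = seed,
             corr = diag(5), transforms = rep(list(list(kind = "identity")), 5),
             beta0 = 1, beta = c(1, 0.5, 0, 0, 0), noise_var = 1)
}

with_null_y <- function(n, seed) {
  set.seed(seed + 777)
  rnorm(n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
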