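#' Generate one replicate dataset from a simulation design
#'
#' Draws N rows of latent deviates `Z ~ N(0, corr)`, applies the marginal
#' transforms columnwise to obtain the predictor matrix `X = T(Z)`, and
#' computes the outcome `y = beta0 + X beta + e` with iid Gaussian noise of
#' variance `noise_var`.  The RNG stream is derived from
#' `(design$seed, replicate)`, so the same pair always yields a bit-identical
#' dataset and distinct replicates are independent; the caller's RNG state
#' is left untouched.
#'
#' @param design a [sim_design()] object.
#' @param replicate positive integer replicate id.
#' @return a tibble with columns `x1..xM` and `y`, carrying attributes
#'   `replicate_id`, `seed_used` and `true_support`.
#' @examples
#' d <- sim_design(50, seed = 7)
#' head(sim_data(d, 1), 2)
#' @export
sim_data <- function(design, replicate = 1L) {
  stopifnot(inherits(design, "sim_design"))
  replicate <- as.integer(replicate)
  if (replicate < 1L) abort("`replicate` must be a positive integer")
  seed_used <- mix_seed(design$seed, replicate)
  L <- tryCatch(chol(design$corr),
    error = function(e) {
      abort(paste0("correlation matrix could not be factorized (not positive ",
                   "definite); adjust `corr` or project it to the nearest ",
                   "correlation matrix"))
    })
  N <- design$N
  M <- design$M
  dat <- with_seed(seed_used, {
    Z <- matrix(rnorm(N * M), N, M) %*% L
    X <- Z
    for (j in seq_len(M)) X[, j] <- apply_transform(Z[, j], design$transforms[[j]])
    e <- rnorm(N, 0, sqrt(design$noise_var))
    list(X = X, y = design$beta0 + drop(X %*% design$beta) + e)
  })
  out <- as_tibble(as.data.frame(dat$X, col.names = paste0("x", seq_len(M))))
  names(out) <- paste0("x", seq_len(M))
  out$y <- dat$y
  attr(out, "replicate_id") <- replicate
  attr(out, "seed_used") <- seed_used
  attr(out, "true_support") <- design$true_support
  out
}

#' Generate a suite of replicate datasets
#'
#' Yields the datasets for `replicates` (default `1:n_sims`).  Because each
#' replicate's RNG stream depends only on `(seed, replicate)`, the suite is
#' restartable at any replicate without regenerating its predecessors.
#'
#' @param design a [sim_design()] object.
#' @param replicates integer vector of replicate ids.
#' @return a list of dataset tibbles (see [sim_data()]).
#' @export
sim_suite <- function(design, replicates = seq_len(design$n_sims)) {
  lapply(replicates, function(r) sim_data(design, r))
}

#' Events-per-variable ratio
#'
#' The sample size divided by the number of candidate predictors; the axis
#' on which sample-size effects are usually reported for variable
#' selection.
#'
#' @param n sample size (or a data frame, whose rows are counted).
#' @param m number of candidate predictors (defaulting to `ncol - 1` when
#'   `n` is a data frame with an outcome column).
#' @return numeric ratio.
#' @examples
#' epv(1599, 10) # 159.9
#' @export
epv <- function(n, m = NULL) {
  if (is.data.frame(n)) {
    if (is.null(m)) m <- ncol(n) - 1L
    n <- nrow(n)
  }
  if (is.null(m)) abort("`m` must be supplied when `n` is not a data frame")
  n / m
}

#' Export / import a dataset as CSV with a JSON sidecar
#'
#' The CSV holds the `x1..xM, y` columns; the sidecar (same path with a
#' `.json` extension appended) records the true support and replicate
#' metadata when present.
#'
#' @param data a dataset tibble from [sim_data()] (or any data frame).
#' @param path CSV file path.
#' @return `write_dataset()` returns `path` invisibly; `read_dataset()`
#'   returns a tibble with the sidecar attributes restored when available.
#' @export
write_dataset <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE)
  meta <- list(
    replicate_id = attr(data, "replicate_id"),
    seed_used = attr(data, "seed_used"),
    true_support = attr(data, "true_support")
  )
  if (any(!vapply(meta, is.null, logical(1)))) {
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  out <- as_tibble(utils::read.csv(path))
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    attr(out, "replicate_id") <- meta$replicate_id
    attr(out, "seed_used") <- meta$seed_used
    attr(out, "true_support") <- meta$true_support
  }
  out
}
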