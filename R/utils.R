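# shared internal helpers

# Deterministic 32-bit seed mixing (Lehmer-style step per component).
# Constants small enough that all intermediates stay exact in doubles.
mix_seed <- function(seed, ...) {
  m <- 2147483563
  x <- as.numeric(seed) %% m
  for (k in c(...)) {
    x <- (48271 * x + as.numeric(k) + 1) %% m
  }
  as.integer(x)
}

# hash a method tag to a small integer for seed derivation
tag_key <- function(tag) {
  sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag))) %% 100000L
}

# run `expr` under a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# split a data frame into predictor matrix and outcome vector
split_xy <- function(data, outcome) {
  stopifnot(is.data.frame(data))
  if (!outcome %in% names(data)) {
    abort(sprintf("outcome column '%s' not found in `data`", outcome))
  }
  x_cols <- setdiff(names(data), outcome)
  X <- as.matrix(data[x_cols])
  if (!is.numeric(X)) abort("all predictor columns must be numeric")
  y <- data[[outcome]]
  if (anyNA(X) || anyNA(y)) abort("missing values are not supported")
  list(X = X, y = as.numeric(y), predictors = x_cols)
}
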