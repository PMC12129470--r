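#' Standardize the columns of a model matrix
#'
#' Centers every column to mean zero and scales it to unit sample standard
#' deviation (denominator `N - 1`).
#'
#' @param X numeric matrix.
#' @return the standardized matrix, same dimensions and column names.
#' @export
standardize_columns <- function(X) {
  X <- as.matrix(X)
  s <- apply(X, 2, sd)
  bad <- which(s == 0 | !is.finite(s))
  if (length(bad)) {
    nm <- colnames(X)[bad] %||% as.character(bad)
    abort(sprintf("degenerate (constant) column%s: %s",
                  if (length(bad) > 1) "s" else "", paste(nm, collapse = ", ")))
  }
  scale(X, center = TRUE, scale = s)[, , drop = FALSE]
}

#' Screening contrasts of predictors against an outcome
#'
#' Computes the contrast vector `C = X_std' y` (inner products of the
#' standardized predictor columns with the outcome) and the stable
#' permutation ordering the absolute contrasts ascendingly, ties broken by
#' ascending predictor index.
#'
#' @param X_std standardized predictor matrix (see [standardize_columns()]).
#' @param y numeric outcome vector (centered or not; callers that need the
#'   intercept excluded should center it first).
#' @return a tibble with columns `predictor`, `contrast`, `abs_contrast` and
#'   `rank` (1 = smallest absolute contrast), carrying the permutation as
#'   attribute `order`.
#' @export
compute_contrasts <- function(X_std, y) {
  X_std <- as.matrix(X_std)
  if (nrow(X_std) != length(y)) {
    abort(sprintf("dimension mismatch: nrow(X_std) = %d but length(y) = %d",
                  nrow(X_std), length(y)))
  }
  C <- unname(drop(crossprod(X_std, y)))
  M <- length(C)
  ord <- order(abs(C), seq_len(M))
  out <- tibble(
    predictor = colnames(X_std) %||% paste0("x", seq_len(M)),
    contrast = C,
    abs_contrast = abs(C),
    rank = order(ord)
  )
  attr(out, "order") <- ord
  out
}
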