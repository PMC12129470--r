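#' Sure independence screening
#'
#' Ranks predictors by the componentwise regression statistic
#' `omega = X_std' y` and retains the `d` with the largest absolute values
#' (ties broken by ascending index).
#'
#' @param X predictor matrix.
#' @param y outcome vector.
#' @param d number of predictors to retain, `1 <= d <= ncol(X)`.
#' @return integer vector of retained column indices (ascending).
#' @export
sis_screen <- function(X, y, d) {
  X <- as.matrix(X)
  M <- ncol(X)
  if (d < 1 || d > M) abort(sprintf("`d` must lie in [1, %d]", M))
  omega <- drop(crossprod(standardize_columns(X), y - mean(y)))
  ord <- order(-abs(omega), seq_len(M))
  sort(ord[seq_len(d)])
}

#' Iterative sure independence screening with SCAD pruning
#'
#' Round r screens the not-yet-chosen predictors against the current
#' residual response with [sis_screen()] and prunes the screened set with a
#' 10-fold-CV SCAD fit; the survivors form the submodel `A_r` (submodels
#' across rounds are disjoint by construction).  Residuals are refreshed by
#' an OLS fit of the outcome on the union of the submodels.  Rounds stop
#' when one adds nothing, when the union reaches the budget `d` (default
#' `floor(N / log N)`, capped at M), or after `max_rounds`.  A final
#' CV-SCAD fit on the union defines the selection; reported coefficients
#' are an OLS refit on the selected set.
#'
#' @inheritParams ssd_ci
#' @param d total screening budget.
#' @param max_rounds maximum number of screening rounds (default 5).
#' @param seed seed for the CV fold draws.
#' @return a `vs_result` tagged `"isis"`, with the per-round submodels in
#'   `details$rounds`.
#' @export
isis_select <- function(data, outcome = "y", d = NULL, max_rounds = 5L,
                        seed = 1L) {
  xy <- split_xy(data, outcome)
  X <- xy$X
  y <- xy$y
  n <- nrow(X)
  M <- ncol(X)
  d <- d %||% min(M, floor(n / log(n)))
  d <- max(1L, min(M, as.integer(d)))

  union_set <- integer(0)
  rounds <- list()
  resid <- y
  for (r in seq_len(max_rounds)) {
    remaining <- setdiff(seq_len(M), union_set)
    if (!length(remaining) || length(union_set) >= d) break
    d_r <- min(length(remaining), d - length(union_set))
    screened <- remaining[sis_screen(X[, remaining, drop = FALSE], resid, d_r)]
    A_r <- scad_prune(X[, screened, drop = FALSE], resid,
                      mix_seed(seed, r))
    A_r <- screened[A_r]
    rounds[[r]] <- A_r
    if (!length(A_r)) break
    union_set <- sort(c(union_set, A_r))
    ols <- lm.fit(cbind(1, X[, union_set, drop = FALSE]), y)
    resid <- y - drop(cbind(1, X[, union_set, drop = FALSE]) %*% ols$coefficients)
  }

  if (!length(union_set)) {
    return(new_vs_result("isis", xy$predictors, integer(0),
                         numeric(M), mean(y), n,
                         details = list(rounds = rounds, d = d,
                                        flagged = "empty-first-round")))
  }
  final <- scad_prune(X[, union_set, drop = FALSE], y, mix_seed(seed, 0L))
  selected <- union_set[final]
  refit <- refit_ols_matrix(X, y, selected)
  selected <- setdiff(selected, match(refit$dropped, xy$predictors))
  new_vs_result("isis", xy$predictors, selected, refit$coef,
                refit$intercept, n,
                details = list(rounds = rounds, d = d, union = union_set))
}

# indices (into the columns of Xsub) surviving a CV'd SCAD fit at lambda_min
scad_prune <- function(Xsub, y, seed) {
  cv <- cv_penalized(Xsub, y, family = "scad", seed = seed)
  unname(which(cv_coef(cv, "min")$coef != 0))
}
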