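#' Supported variable-selection method tags
#'
#' @return character vector of the method tags accepted by [vs_select()].
#' @export
vs_methods <- function() {
  c("be-p", "be-aic", "be-bic",
    "lasso-min", "lasso-1se", "alasso-min", "alasso-1se",
    "enet", "scad", "mcp", "isis", "ssdci")
}

#' Run a variable-selection method on a dataset
#'
#' Unified front end over the whole battery: backward elimination with
#' three criteria, the coordinate-descent penalized family (lasso, adaptive
#' lasso, elastic net, SCAD, MCP) with 10-fold CV and the
#' `lambda_min`/`lambda_1se` rules, iterative sure independence screening,
#' and SSD-CI contrast screening.  Every method returns the common
#' `vs_result` container so results can be compared, stacked and scored
#' identically.
#'
#' Penalized methods report the penalized coefficient estimates themselves
#' (set `refit = TRUE` to replace them with a post-selection OLS refit);
#' SSD-CI and ISIS always report OLS refits, and backward elimination its
#' terminal OLS fit.
#'
#' @inheritParams ssd_ci
#' @param method one of [vs_methods()].
#' @param seed seed for any method-internal randomness (CV folds).
#' @param refit replace penalized estimates by a post-selection OLS refit.
#' @param ... passed to the underlying method (e.g. `alpha`, `var_frac` for
#'   `"ssdci"`; `gamma` for `"scad"`/`"mcp"`; `d`, `max_rounds` for
#'   `"isis"`).
#' @return a `vs_result`.
#' @examples
#' d <- sim_data(sim_design(120, seed = 11))
#' vs_select(d, method = "lasso-1se", seed = 1)
#' @export
vs_select <- function(data, outcome = "y", method = "ssdci", seed = 1L,
                      refit = FALSE, ...) {
  method <- match.arg(method, vs_methods())
  res <- switch(method,
    "be-p"   = backward_eliminate(data, outcome, "pvalue", ...),
    "be-aic" = backward_eliminate(data, outcome, "aic", ...),
    "be-bic" = backward_eliminate(data, outcome, "bic", ...),
    "ssdci"  = ssd_ci(data, outcome, ...),
    "isis"   = isis_select(data, outcome, seed = seed, ...),
    "lasso-min"  = penalized_select(data, outcome, "lasso", "min", seed, ...),
    "lasso-1se"  = penalized_select(data, outcome, "lasso", "1se", seed, ...),
    "alasso-min" = penalized_select(data, outcome, "alasso", "min", seed, ...),
    "alasso-1se" = penalized_select(data, outcome, "alasso", "1se", seed, ...),
    "enet"       = penalized_select(data, outcome, "enet", "min", seed, ...),
    "scad"       = penalized_select(data, outcome, "scad", "min", seed, ...),
    "mcp"        = penalized_select(data, outcome, "mcp", "min", seed, ...)
  )
  res$method <- method
  if (refit && !method %in% c("ssdci", "isis", "be-p", "be-aic", "be-bic")) {
    xy <- split_xy(data, outcome)
    rf <- refit_ols_matrix(xy$X, xy$y, res$selected)
    sel <- setdiff(res$selected, match(rf$dropped, xy$predictors))
    res <- new_vs_result(method, xy$predictors, sel, rf$coef, rf$intercept,
                         res$n, details = c(res$details, list(refit = TRUE)))
  }
  res
}

penalized_select <- function(data, outcome, family, rule, seed, ...) {
  xy <- split_xy(data, outcome)
  weights <- NULL
  foldid <- with_seed(seed, sample(rep(seq_len(10L), length.out = nrow(xy$X))))
  if (family == "alasso") {
    weights <- alasso_weights(xy$X, xy$y, foldid = foldid)
  }
  cv <- cv_penalized(xy$X, xy$y, family = family, foldid = foldid,
                     weights = weights, ...)
  at <- cv_coef(cv, rule)
  selected <- unname(which(at$coef != 0))
  new_vs_result(paste0(family, "-", rule), xy$predictors, selected, at$coef,
                at$intercept, nrow(xy$X),
                details = list(cv = cv, lambda = at$lambda, rule = rule,
                               alpha = cv$alpha, weights = weights))
}
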