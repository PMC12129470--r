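#' 10-fold cross-validation for the penalized families
#'
#' Builds a grid of 100 log-spaced penalties from `lambda_max` down to
#' `lambda_max * 1e-3`, assigns seeded folds (no stratification), and for
#' each fold fits the whole path by warm-started coordinate descent on the
#' training part, scoring mean squared prediction error on the held-out
#' part.  `lambda_min` minimizes the CV error; `lambda_1se` is the largest
#' penalty whose CV error is within one standard error of the minimum.  For
#' the elastic net the mixing grid `alpha = 0.1, 0.2, ..., 0.9` is searched
#' jointly with the penalty (ties broken towards the smaller `alpha`).
#' `family = "ridge"` uses the closed-form ridge path and is mainly used to
#' build adaptive-lasso weights.
#'
#' @param X predictor matrix.
#' @param y outcome vector.
#' @param family one of `"lasso"`, `"alasso"`, `"enet"`, `"scad"`, `"mcp"`,
#'   `"ridge"`.
#' @param seed integer seed for the fold assignment.
#' @param nfolds number of folds (default 10).
#' @param nlambda grid size (default 100).
#' @param lambda_min_ratio ratio of the smallest to the largest grid value.
#' @param alpha_grid elastic-net mixing grid.
#' @param gamma concavity parameter for SCAD/MCP.
#' @param weights adaptive-lasso penalty weights.
#' @param foldid optional explicit fold assignment (overrides `seed`).
#' @return a `vs_cv` object: list with `path` (tibble `lambda`, `cv_error`,
#'   `cv_se`, and `alpha` for enet), `lambda_min`, `lambda_1se`, `alpha`,
#'   `foldid`, and `fit_at()`-style accessors via [cv_coef()].
#' @export
cv_penalized <- function(X, y,
                         family = c("lasso", "alasso", "enet", "scad",
                                    "mcp", "ridge"),
                         seed = 1L, nfolds = 10L, nlambda = 100L,
                         lambda_min_ratio = 1e-3,
                         alpha_grid = seq(0.1, 0.9, by = 0.1),
                         gamma = NULL, weights = NULL, foldid = NULL) {
  family <- match.arg(family)
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 30 && family != "ridge") abort("cross-validation needs N >= 30")
  if (n < nfolds) abort("fewer rows than folds")
  if (is.null(foldid)) {
    foldid <- with_seed(seed, sample(rep(seq_len(nfolds), length.out = n)))
  }
  gamma <- gamma %||% switch(family, scad = 3.7, mcp = 3, NA_real_)

  if (family == "ridge") {
    return(cv_ridge(X, y, foldid, nlambda))
  }

  alphas <- if (family == "enet") alpha_grid else 1
  w <- pmin(weights %||% rep(1, ncol(X)), 1e12)
  # fold pieces are alpha-independent: compute each training Gram once
  folds <- lapply(seq_len(nfolds), function(f) {
    tr <- foldid != f
    std <- standardize_for_cd(X[tr, , drop = FALSE], y[tr])
    list(std = std, X_te = X[!tr, , drop = FALSE], y_te = y[!tr])
  })
  best <- NULL
  for (a in alphas) {
    lmax <- lambda_max(X, y, family = if (family == "enet") "enet" else family,
                       alpha_mix = a, weights = weights)
    grid <- exp(seq(log(lmax), log(lmax * lambda_min_ratio),
                    length.out = nlambda))
    fold_mse <- matrix(NA_real_, nfolds, nlambda)
    for (f in seq_len(nfolds)) {
      std <- folds[[f]]$std
      B <- .cd_path_cpp(std$G, std$b, grid, family_code(family),
                        a, gamma %||% 0, w, 10000L, 1e-7)
      coef <- B / std$xs
      intercept <- std$ym - drop(crossprod(coef, std$xm))
      pred <- sweep(folds[[f]]$X_te %*% coef, 2, intercept, "+")
      fold_mse[f, ] <- colMeans((folds[[f]]$y_te - pred)^2)
    }
    cv_error <- colMeans(fold_mse)
    cv_se <- apply(fold_mse, 2, sd) / sqrt(nfolds)
    i_min <- which.min(cv_error)
    cand <- list(alpha = a, grid = grid, cv_error = cv_error, cv_se = cv_se,
                 i_min = i_min, err = cv_error[i_min])
    if (is.null(best) || cand$err < best$err) best <- cand
  }

  thresh <- best$cv_error[best$i_min] + best$cv_se[best$i_min]
  i_1se <- min(which(best$cv_error <= thresh))  # grid is decreasing in lambda
  lambda_min <- best$grid[best$i_min]
  lambda_1se <- best$grid[i_1se]

  full <- path_on(X, y, best$grid, family, best$alpha, gamma, weights)
  path <- tibble(lambda = best$grid, cv_error = best$cv_error,
                 cv_se = best$cv_se)
  if (family == "enet") path$alpha <- best$alpha
  structure(
    list(family = family, path = path, lambda_min = lambda_min,
         lambda_1se = lambda_1se, alpha = best$alpha, gamma = gamma,
         weights = weights, foldid = foldid, grid = best$grid,
         coef_path = full$coef, intercept_path = full$intercept,
         predictors = colnames(X) %||% paste0("x", seq_len(ncol(X)))),
    class = "vs_cv"
  )
}

# fit a whole path on (X, y); returns original-scale coefficients
path_on <- function(X, y, grid, family, alpha, gamma, weights) {
  std <- standardize_for_cd(X, y)
  w <- pmin(weights %||% rep(1, ncol(X)), 1e12)
  B <- .cd_path_cpp(std$G, std$b, grid, family_code(family),
                    alpha, gamma %||% 0, w, 10000L, 1e-7)
  coef <- B / std$xs
  intercept <- std$ym - drop(crossprod(coef, std$xm))
  list(coef = coef, intercept = intercept)
}

cv_ridge <- function(X, y, foldid, nlambda) {
  n <- nrow(X)
  nfolds <- max(foldid)
  lmax <- 100 * lambda_max(X, y)
  grid <- exp(seq(log(lmax), log(lmax * 1e-6), length.out = nlambda))
  fold_mse <- matrix(NA_real_, nfolds, nlambda)
  for (f in seq_len(nfolds)) {
    tr <- foldid != f
    fit <- ridge_path(X[tr, , drop = FALSE], y[tr], grid)
    pred <- sweep(X[!tr, , drop = FALSE] %*% fit$coef, 2, fit$intercept, "+")
    fold_mse[f, ] <- colMeans((y[!tr] - pred)^2)
  }
  cv_error <- colMeans(fold_mse)
  cv_se <- apply(fold_mse, 2, sd) / sqrt(nfolds)
  i_min <- which.min(cv_error)
  thresh <- cv_error[i_min] + cv_se[i_min]
  full <- ridge_path(X, y, grid)
  structure(
    list(family = "ridge",
         path = tibble(lambda = grid, cv_error = cv_error, cv_se = cv_se),
         lambda_min = grid[i_min], lambda_1se = grid[min(which(cv_error <= thresh))],
         alpha = 0, foldid = foldid, grid = grid,
         coef_path = full$coef, intercept_path = full$intercept,
         beta_std_path = full$beta_std,
         predictors = colnames(X) %||% paste0("x", seq_len(ncol(X)))),
    class = "vs_cv"
  )
}

# closed-form ridge path on the standardized problem:
# beta_std(lambda) = (G + lambda I)^{-1} b
ridge_path <- function(X, y, grid) {
  std <- standardize_for_cd(X, y)
  M <- ncol(X)
  B <- vapply(grid, function(l) solve(std$G + diag(l, M), std$b), numeric(M))
  B <- matrix(B, nrow = M)
  coef <- B / std$xs
  intercept <- std$ym - drop(crossprod(coef, std$xm))
  list(coef = coef, intercept = intercept, beta_std = B)
}

#' Coefficients of a cross-validated fit at a penalty rule
#'
#' @param cv a `vs_cv` object.
#' @param rule `"min"` or `"1se"` (or a numeric penalty value, matched to
#'   the nearest grid point).
#' @return list with `coef` (original scale, named), `intercept`, `lambda`.
#' @export
cv_coef <- function(cv, rule = c("min", "1se")) {
  if (is.character(rule)) {
    rule <- match.arg(rule)
    lambda <- if (rule == "min") cv$lambda_min else cv$lambda_1se
  } else {
    lambda <- rule
  }
  i <- which.min(abs(cv$grid - lambda))
  list(coef = setNames(cv$coef_path[, i], cv$predictors),
       intercept = cv$intercept_path[i], lambda = cv$grid[i])
}

#' @export
print.vs_cv <- function(x, ...) {
  cat("<vs_cv>", x$family,
      if (x$family == "enet") sprintf("(alpha = %.1f)", x$alpha) else "",
      "\n  lambda_min =", signif(x$lambda_min, 4),
      " lambda_1se =", signif(x$lambda_1se, 4), "\n")
  invisible(x)
}

#' Plot a cross-validation curve
#'
#' CV error against `log(lambda)` with one-standard-error ribbon and the
#' `lambda_min` / `lambda_1se` rules marked.
#'
#' @param object a `vs_cv`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.vs_cv <- function(object, ...) {
  d <- object$path
  ggplot2::ggplot(d, ggplot2::aes(x = log(.data$lambda), y = .data$cv_error)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$cv_error - .data$cv_se,
                                      ymax = .data$cv_error + .data$cv_se),
                         fill = "grey85") +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = log(c(object$lambda_min, object$lambda_1se)),
                        linetype = c(1, 2), colour = "#b2182b") +
    ggplot2::labs(x = "log(lambda)", y = "cross-validated MSE",
                  title = paste0("10-fold CV (", object$family, ")")) +
    ggplot2::theme_minimal()
}

#' Adaptive-lasso penalty weights from a ridge fit
#'
#' Fits a ridge regression with its own 10-fold-CV penalty and returns
#' `w_j = 1 / |beta_ridge_j|` computed on the standardized scale; a
#' numerically zero ridge coefficient maps to the large finite weight
#' `1e12`.
#'
#' @inheritParams cv_penalized
#' @param rule which ridge penalty to take the coefficients from
#'   (`"min"`, the CV-optimal one, by default).
#' @return numeric weight vector, one entry per predictor.
#' @export
alasso_weights <- function(X, y, seed = 1L, foldid = NULL,
                           rule = c("min", "1se")) {
  rule <- match.arg(rule)
  cv <- cv_penalized(X, y, family = "ridge", seed = seed, foldid = foldid)
  i <- which.min(abs(cv$grid - if (rule == "min") cv$lambda_min else cv$lambda_1se))
  b <- abs(cv$beta_std_path[, i])
  ifelse(b < 1e-12, 1e12, 1 / b)
}
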