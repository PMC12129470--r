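#' Default correlation structure of the simulation design
#'
#' A 15 x 15 positive-definite correlation matrix with all entries in
#' \[-0.3, 0.8\].  The structure drives the documented selection behaviours
#' of the study: X1 and X2 form a strongly correlated pair (r = 0.8), the
#' false predictor X9 is moderately correlated with the true predictors X3
#' (r = 0.6) and X6 (r = 0.45), X11 is correlated with X6 (r = 0.5), and X5
#' with X6 (r = 0.35), plus mild background correlations.
#'
#' @return a 15 x 15 symmetric numeric matrix with unit diagonal.
#' @export
default_correlation <- function() {
  M <- 15L
  R <- diag(M)
  pairs <- list(
    c(1, 2, 0.80), c(3, 9, 0.60), c(6, 9, 0.45), c(6, 11, 0.50),
    c(5, 6, 0.35), c(1, 3, 0.15), c(2, 4, -0.10), c(2, 5, 0.10),
    c(3, 5, 0.10), c(3, 11, 0.10), c(5, 9, 0.15), c(5, 11, 0.20),
    c(9, 11, 0.20), c(4, 10, 0.05), c(4, 8, -0.08), c(7, 12, 0.20),
    c(7, 14, 0.10), c(8, 13, 0.30), c(10, 14, -0.20), c(12, 15, 0.15),
    c(13, 15, 0.20)
  )
  for (p in pairs) {
    R[p[1], p[2]] <- R[p[2], p[1]] <- p[3]
  }
  dimnames(R) <- list(paste0("x", 1:M), paste0("x", 1:M))
  R
}

#' Default marginal transforms of the simulation design
#'
#' Componentwise transforms applied to the correlated standard-normal
#' deviates Z to emulate heterogeneous biomedical-style marginals.  True
#' predictors use affine rescalings (so the linear model in X is exact);
#' two false predictors (x8, x12) are lognormal for skewness.
#'
#' @return a list of 15 transform descriptors, each a list with a `kind`
#'   field (`"identity"`, `"affine"` or `"exponential"`) and parameters
#'   `center`/`scale` (affine) or `rate` (exponential).
#' @export
default_transforms <- function() {
  affine <- function(center, scale) list(kind = "affine", center = center, scale = scale)
  expo <- function(rate = 1) list(kind = "exponential", rate = rate)
  idn <- list(kind = "identity")
  list(
    affine(52, 9),      # x1  age-like, wide
    affine(5.4, 0.33),  # x2  narrow lab value
    idn,                # x3
    idn,                # x4
    affine(3.1, 1.2),   # x5
    affine(25, 5.25),   # x6
    affine(130, 8),     # x7  pressure-like
    expo(),             # x8  lognormal (skewed)
    idn,                # x9
    affine(10.5, 2),    # x10
    affine(14, 3),      # x11
    expo(),             # x12 lognormal (skewed)
    affine(4.2, 1.5),   # x13
    idn,                # x14
    affine(1.6, 0.5)    # x15
  )
}

#' Default true coefficient vector
#'
#' The first seven predictors carry the non-zero effects of the true model
#' `y = 11.206 + 0.041 x1 - 1.061 x2 + 0.249 x3 + 0.625 x4 + 0.104 x5 +
#' 0.022 x6 - 0.01 x7 + e`; the remaining eight are false predictors with
#' zero coefficients.
#'
#' @return numeric vector of length 15.
#' @export
default_beta <- function() {
  c(0.041, -1.061, 0.249, 0.625, 0.104, 0.022, -0.01, rep(0, 8))
}

#' Construct a simulation design
#'
#' Bundles everything that defines the synthetic data-generating process: a
#' correlation matrix for the latent Gaussian deviates, marginal transforms,
#' a sparse coefficient vector, the noise variance, the sample size and the
#' replicate count.  `sim_design()` with no arguments other than `N` returns
#' the packaged default design (15 predictors, 7 true).
#'
#' @param N sample size per replicate; must exceed the predictor count.
#' @param n_sims number of replicates the design describes.
#' @param seed master RNG seed; per-replicate streams are derived from it.
#' @param corr correlation matrix of the latent deviates (symmetric, unit
#'   diagonal, eigenvalues >= -1e-10).
#' @param transforms list of per-predictor marginal transform descriptors,
#'   see [default_transforms()].
#' @param beta0 intercept of the true model.
#' @param beta coefficient vector; its non-zero entries define the true
#'   support.
#' @param noise_var error variance (`> 0`); errors are iid Gaussian.
#'
#' @return an object of class `sim_design`.
#' @examples
#' d <- sim_design(225)
#' d$beta0
#' @export
sim_design <- function(N, n_sims = 1000L, seed = 1L,
                       corr = default_correlation(),
                       transforms = default_transforms(),
                       beta0 = 11.206, beta = default_beta(),
                       noise_var = 0.868) {
  M <- nrow(corr)
  if (!isTRUE(all.equal(corr, t(corr), tolerance = 1e-12)) ||
      any(abs(diag(corr) - 1) > 1e-12)) {
    abort("invalid design: `corr` must be symmetric with unit diagonal")
  }
  ev <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) {
    abort(paste0("invalid design: `corr` is not positive semi-definite ",
                 "(smallest eigenvalue ", signif(min(ev), 3),
                 "); supply a valid correlation matrix"))
  }
  if (length(beta) != M) abort("invalid design: length(beta) must equal ncol(corr)")
  if (length(transforms) != M) abort("invalid design: one transform per predictor required")
  if (noise_var <= 0) abort("invalid design: `noise_var` must be positive")
  if (N <= M) {
    abort(sprintf("invalid design: sample size N (%d) must exceed the predictor count M (%d)",
                  as.integer(N), M))
  }
  structure(
    list(M = M, corr = corr, transforms = transforms, beta0 = beta0,
         beta = beta, noise_var = noise_var, N = as.integer(N),
         n_sims = as.integer(n_sims), seed = as.integer(seed),
         true_support = which(beta != 0)),
    class = "sim_design"
  )
}

#' The packaged default design
#'
#' Convenience wrapper returning [sim_design()] with all defaults: the
#' documented correlation matrix, marginal transforms and the sparse true
#' model with seven non-zero coefficients.
#'
#' @inheritParams sim_design
#' @return a `sim_design` object.
#' @export
default_design <- function(N, n_sims = 1000L, seed = 1L) {
  sim_design(N = N, n_sims = n_sims, seed = seed)
}

#' @export
print.sim_design <- function(x, ...) {
  cat("<sim_design>", x$M, "predictors,", length(x$true_support),
      "true; N =", x$N, ", replicates =", x$n_sims, "\n")
  cat("  beta0 =", x$beta0, ", noise_var =", x$noise_var,
      ", seed =", x$seed, "\n")
  invisible(x)
}

transform_kinds <- c("identity", "affine", "exponential")

apply_transform <- function(z, tr) {
  switch(tr$kind,
    identity = z,
    affine = tr$center + tr$scale * z,
    exponential = exp((tr$rate %||% 1) * z),
    abort(sprintf("unknown transform kind '%s'", tr$kind))
  )
}

#' Write / read a simulation design as YAML or JSON
#'
#' The on-disk representation uses keys `m`, `corr`, `transforms`, `beta0`,
#' `beta`, `noise_var`, `n`, `n_sims` and `seed`.  The format is chosen from
#' the file extension (`.yaml`/`.yml` or `.json`).
#'
#' @param design a `sim_design` object.
#' @param path file path.
#' @return `write_design()` returns `path` invisibly; `read_design()`
#'   returns a `sim_design`.
#' @export
write_design <- function(design, path) {
  obj <- list(
    m = design$M, corr = unname(apply(design$corr, 1, as.numeric, simplify = FALSE)),
    transforms = design$transforms, beta0 = design$beta0,
    beta = design$beta, noise_var = design$noise_var,
    n = design$N, n_sims = design$n_sims, seed = design$seed
  )
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(obj, path)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  corr <- if (is.matrix(obj$corr)) obj$corr else
    do.call(rbind, lapply(obj$corr, as.numeric))
  dimnames(corr) <- list(paste0("x", seq_len(obj$m)), paste0("x", seq_len(obj$m)))
  trs <- obj$transforms
  if (is.data.frame(trs)) {
    trs <- lapply(seq_len(nrow(trs)), function(i) {
      as.list(trs[i, !vapply(trs[i, ], function(v) is.na(v) %in% TRUE, logical(1)),
                  drop = FALSE])
    })
  }
  transforms <- lapply(trs, function(tr) {
    tr$kind <- match.arg(tr$kind, transform_kinds)
    tr
  })
  sim_design(N = obj$n, n_sims = obj$n_sims, seed = obj$seed, corr = corr,
             transforms = transforms, beta0 = obj$beta0,
             beta = as.numeric(obj$beta), noise_var = obj$noise_var)
}
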