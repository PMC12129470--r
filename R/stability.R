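#' Resampling draws for the stability analysis
#'
#' `draw_subsample()` takes `floor(0.5 N)` rows without replacement;
#' `draw_bootstrap()` takes `N` rows with replacement.  Both are seeded and
#' reproducible.
#'
#' @param data a data frame.
#' @param seed integer seed.
#' @return a data frame of resampled rows.
#' @export
draw_subsample <- function(data, seed) {
  n <- nrow(data)
  idx <- with_seed(seed, sample.int(n, floor(0.5 * n), replace = FALSE))
  data[idx, , drop = FALSE]
}

#' @rdname draw_subsample
#' @export
draw_bootstrap <- function(data, seed) {
  n <- nrow(data)
  idx <- with_seed(seed, sample.int(n, n, replace = TRUE))
  data[idx, , drop = FALSE]
}

# core measure computation, exposed for unit testing:
#   est: n_res x M matrix of resample estimates (zeros when unselected)
#   sel: n_res x M logical matrix of inclusion
compute_stability_measures <- function(est, sel, beta_global, se_global,
                                       vif_prop = NULL) {
  n_res <- nrow(est)
  vif_prop <- vif_prop %||% colMeans(sel)
  vif_prop <- unname(vif_prop)
  cond_mean <- vapply(seq_len(ncol(est)), function(j) {
    if (!any(sel[, j])) NA_real_ else mean(est[sel[, j], j])
  }, numeric(1))
  rcb <- unname(ifelse(beta_global == 0 | is.na(cond_mean), NA_real_,
                       (cond_mean / beta_global - 1) * 100))
  dev <- sweep(est, 2, beta_global)
  rmsd <- unname(sqrt(colSums(dev^2) / n_res))
  tibble(
    predictor = colnames(est) %||% paste0("x", seq_len(ncol(est))),
    vif_pct = 100 * vif_prop,
    rcb_pct = rcb,
    rmsd = rmsd,
    rmsdr = unname(rmsd / se_global)
  )
}

#' Resampling-based stability analysis of a variable-selection method
#'
#' Follows the two-resampling-scheme protocol: inclusion frequencies
#' (`sub_VIF`) and the model-selection frequency (`sub_MSF`, the share of
#' the most frequently selected predictor set) are estimated from `n_res`
#' half-size subsamples drawn without replacement, while the
#' coefficient-stability measures are estimated from `n_res` bootstrap
#' samples (full size, with replacement) against the global model — the
#' full-data OLS fit including all predictors:
#' relative conditional bias
#' `RCB = (mean of the selection-conditional resample estimates /
#' global estimate - 1) * 100` (equivalently the zero-imputed resample mean
#' divided by the global estimate times the inclusion proportion, minus 1),
#' and the RMSD ratio `RMSDR = sqrt(mean((est_l - global)^2)) / se_global`
#' with zeros imputed for unselected resamples.  A predictor never selected
#' across the bootstrap resamples has an undefined RCB, reported `NA`.
#'
#' @inheritParams ssd_ci
#' @param method a method tag from [vs_methods()], or a function
#'   `function(data, outcome, seed)` returning a `vs_result`.
#' @param n_res number of resamples per scheme (default 1000).
#' @param seed master seed; per-resample seeds are derived from it.
#' @param ... passed through to [vs_select()].
#' @return a `vs_stability` object: list with `measures` (per-predictor
#'   tibble: `predictor`, `sub_vif_pct`, `rcb_pct`, `rmsdr`, ...), `msf`
#'   (model-frequency tibble), `global` (tibble of global estimates and
#'   standard errors), `n_res`, `method`.
#' @export
stability_run <- function(data, outcome = "y", method = "be-p",
                          n_res = 1000L, seed = 1L, ...) {
  xy <- split_xy(data, outcome)
  M <- ncol(xy$X)
  run_method <- if (is.function(method)) {
    meth_tag <- "custom"
    function(d, s) method(d, outcome, s)
  } else {
    meth_tag <- method
    function(d, s) vs_select(d, outcome, method = method, seed = s, ...)
  }

  gfit <- lm(y ~ ., data = data.frame(xy$X, y = xy$y, check.names = FALSE))
  gsum <- summary(gfit)$coefficients
  beta_global <- setNames(coef(gfit)[-1], xy$predictors)
  se_global <- setNames(gsum[-1, 2], xy$predictors)
  if (any(se_global <= 0)) abort("degenerate global fit: non-positive SE")

  # subsamples: inclusion and model frequencies
  sub_sel <- matrix(FALSE, n_res, M, dimnames = list(NULL, xy$predictors))
  models <- character(n_res)
  for (l in seq_len(n_res)) {
    d_l <- draw_subsample(data, mix_seed(seed, 1L, l))
    r_l <- run_method(d_l, mix_seed(seed, 11L, l))
    sub_sel[l, r_l$selected] <- TRUE
    models[l] <- paste(r_l$predictors[r_l$selected], collapse = "+")
  }
  msf <- tibble(model = models) |>
    dplyr::count(.data$model, name = "count") |>
    dplyr::mutate(pct = 100 * .data$count / n_res) |>
    dplyr::arrange(dplyr::desc(.data$count))

  # bootstrap: coefficient stability against the global fit
  boot_est <- matrix(0, n_res, M, dimnames = list(NULL, xy$predictors))
  boot_sel <- matrix(FALSE, n_res, M)
  for (l in seq_len(n_res)) {
    d_l <- draw_bootstrap(data, mix_seed(seed, 2L, l))
    r_l <- run_method(d_l, mix_seed(seed, 22L, l))
    boot_est[l, ] <- r_l$coef
    boot_sel[l, r_l$selected] <- TRUE
  }
  meas <- compute_stability_measures(boot_est, boot_sel, beta_global, se_global)
  measures <- tibble(
    predictor = xy$predictors,
    sub_vif_pct = unname(100 * colMeans(sub_sel)),
    boot_vif_pct = meas$vif_pct,
    rcb_pct = meas$rcb_pct,
    rmsd = meas$rmsd,
    rmsdr = meas$rmsdr
  )
  structure(
    list(method = meth_tag, n_res = n_res, measures = measures, msf = msf,
         global = tibble(predictor = xy$predictors,
                         beta_global = unname(beta_global),
                         se_global = unname(se_global))),
    class = "vs_stability"
  )
}

#' @export
print.vs_stability <- function(x, ...) {
  cat("<vs_stability>", x$method, "over", x$n_res, "resamples\n")
  print(x$measures, n = Inf)
  cat("most frequent model:", x$msf$model[1],
      sprintf("(%.1f%%)\n", x$msf$pct[1]))
  invisible(x)
}

#' @export
tidy.vs_stability <- function(x, ...) x$measures

#' @export
glance.vs_stability <- function(x, ...) {
  tibble(method = x$method, n_res = x$n_res,
         n_models = nrow(x$msf),
         msf_model = x$msf$model[1], msf_pct = x$msf$pct[1])
}

#' Plot stability measures
#'
#' Inclusion frequency bars with RMSD-ratio overlay per predictor.
#'
#' @param object a `vs_stability`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.vs_stability <- function(object, ...) {
  d <- object$measures
  d$predictor <- factor(d$predictor, levels = d$predictor)
  scale_f <- max(d$sub_vif_pct, 1) / max(d$rmsdr, 1e-9)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$predictor)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$sub_vif_pct), fill = "#74add1") +
    ggplot2::geom_point(ggplot2::aes(y = .data$rmsdr * scale_f), colour = "#b2182b") +
    ggplot2::scale_y_continuous(
      name = "subsample inclusion frequency (%)",
      sec.axis = ggplot2::sec_axis(~ . / scale_f, name = "RMSD ratio")
    ) +
    ggplot2::labs(x = NULL, title = paste0("Selection stability (", object$method, ")")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
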