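#' Truth specification of a simulation design
#'
#' The true/false predictor partition and the true coefficient vector used
#' by the performance metrics.
#'
#' @param design a [sim_design()] object (or a coefficient vector).
#' @return a list with `true_support`, `false_support`, `beta_true`, `M`.
#' @export
truth_spec <- function(design) {
  beta <- if (inherits(design, "sim_design")) design$beta else as.numeric(design)
  M <- length(beta)
  ts <- which(beta != 0)
  list(true_support = ts, false_support = setdiff(seq_len(M), ts),
       beta_true = beta, M = M)
}

check_results <- function(results) {
  if (!is.data.frame(results) || !nrow(results)) {
    abort("`results` must be a non-empty results tibble (see `run_study()`)")
  }
  stopifnot(all(c("method", "n", "replicate", "selected") %in% names(results)))
  invisible(results)
}

#' Type I / type II selection error rates
#'
#' Per replicate, the type I (false positive) rate is the number of falsely
#' selected non-predictors over the number of true non-predictors, and the
#' type II (false negative) rate the number of missed true predictors over
#' the number of true predictors; both are averaged over the replicates of
#' each (method, n) cell.
#'
#' @param results a results tibble with columns `method`, `n`, `replicate`
#'   and a list-column `selected` (as produced by [run_study()]).
#' @param truth a [truth_spec()].
#' @return a tibble with columns `method`, `n`, `fpr`, `fnr`.
#' @export
error_rates <- function(results, truth) {
  check_results(results)
  n_false <- length(truth$false_support)
  n_true <- length(truth$true_support)
  results |>
    dplyr::mutate(
      fp = purrr::map_dbl(.data$selected,
                          ~ length(intersect(.x, truth$false_support)) / n_false),
      fn = purrr::map_dbl(.data$selected,
                          ~ length(setdiff(truth$true_support, .x)) / n_true)
    ) |>
    dplyr::summarise(fpr = mean(.data$fp), fnr = mean(.data$fn),
                     .by = c("method", "n"))
}

#' Average selected model size
#'
#' Mean number of predictors selected per (method, n) cell, irrespective of
#' their true status.
#'
#' @inheritParams error_rates
#' @return a tibble with columns `method`, `n`, `avg_selected`.
#' @export
avg_model_size <- function(results) {
  check_results(results)
  results |>
    dplyr::mutate(size = lengths(.data$selected)) |>
    dplyr::summarise(avg_selected = mean(.data$size), .by = c("method", "n"))
}

#' Variable inclusion frequency
#'
#' Percentage of replicates in which each predictor was selected, per
#' (method, n) cell.
#'
#' @inheritParams error_rates
#' @param M number of candidate predictors.
#' @return a tibble with columns `method`, `n`, `predictor`, `vif_pct`.
#' @export
inclusion_frequency <- function(results, M) {
  check_results(results)
  results |>
    dplyr::reframe(
      predictor = seq_len(M),
      vif_pct = 100 * vapply(seq_len(M), function(j) {
        mean(vapply(.data$selected, function(s) j %in% s, logical(1)))
      }, numeric(1)),
      .by = c("method", "n")
    )
}

#' Per-predictor absolute bias and root mean squared error
#'
#' Coefficient estimates are scored against the true coefficients with
#' zeros imputed for unselected predictors, so both measures are defined
#' for every predictor in every replicate:
#' `abs_bias = |mean(est - beta_true)|`,
#' `rmse = sqrt(mean((est - beta_true)^2))`.
#'
#' @inheritParams error_rates
#' @param truth a [truth_spec()]; the `coef` list-column of `results` must
#'   hold full-length coefficient vectors.
#' @return a tibble with columns `method`, `n`, `predictor`, `abs_bias`,
#'   `rmse`.
#' @export
bias_rmse <- function(results, truth) {
  check_results(results)
  stopifnot("coef" %in% names(results))
  results |>
    dplyr::reframe(
      {
        est <- do.call(rbind, .data$coef)             # replicates x M
        dev <- sweep(est, 2, truth$beta_true)
        tibble(predictor = seq_len(truth$M),
               abs_bias = abs(colMeans(dev)),
               rmse = sqrt(colMeans(dev^2)))
      },
      .by = c("method", "n")
    )
}

#' All performance metrics in one tidy table
#'
#' Long format mirroring a per-method/per-predictor summary layout:
#' `metric` is one of `fpr`, `fnr`, `avg_selected` (predictor `NA`) or
#' `vif_pct`, `abs_bias`, `rmse` (per predictor).
#'
#' @inheritParams bias_rmse
#' @return a tibble with columns `method`, `n`, `metric`, `predictor`,
#'   `value`.
#' @export
metric_table <- function(results, truth) {
  er <- error_rates(results, truth) |>
    tidyr::pivot_longer(c("fpr", "fnr"), names_to = "metric") |>
    dplyr::mutate(predictor = NA_integer_)
  sz <- avg_model_size(results) |>
    tidyr::pivot_longer("avg_selected", names_to = "metric") |>
    dplyr::mutate(predictor = NA_integer_)
  vf <- inclusion_frequency(results, truth$M) |>
    tidyr::pivot_longer("vif_pct", names_to = "metric")
  br <- bias_rmse(results, truth) |>
    tidyr::pivot_longer(c("abs_bias", "rmse"), names_to = "metric")
  dplyr::bind_rows(er, sz, vf, br) |>
    dplyr::select("method", "n", "metric", "predictor", "value") |>
    dplyr::arrange(.data$method, .data$n, .data$metric, .data$predictor)
}
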