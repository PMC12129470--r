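# common container returned by every selector

new_vs_result <- function(method, predictors, selected, coef, intercept,
                          n, details = list()) {
  stopifnot(length(coef) == length(predictors))
  coef <- setNames(as.numeric(coef), predictors)
  coef[setdiff(seq_along(coef), selected)] <- 0
  structure(
    list(method = method, predictors = predictors,
         selected = as.integer(sort(selected)), coef = coef,
         intercept = intercept, n = n, details = details),
    class = "vs_result"
  )
}

#' @export
print.vs_result <- function(x, ...) {
  cat("<vs_result> method:", x$method, " (n =", x$n, ")\n")
  if (length(x$selected)) {
    cat("  selected:", paste(x$predictors[x$selected], collapse = ", "), "\n")
  } else {
    cat("  selected: (none)\n")
  }
  if (!is.null(x$details$terminal_rule)) {
    cat("  terminal rule:", x$details$terminal_rule, "\n")
  }
  invisible(x)
}

#' Tidy a selection result
#'
#' One row per predictor with its (refit or penalized) coefficient estimate
#' and selection indicator, broom-style.
#'
#' @param x a `vs_result`.
#' @param ... unused.
#' @return a tibble with columns `term`, `estimate`, `selected`.
#' @export
tidy.vs_result <- function(x, ...) {
  tibble(
    term = x$predictors,
    estimate = unname(x$coef),
    selected = seq_along(x$predictors) %in% x$selected
  )
}

#' One-row summary of a selection result
#'
#' @param x a `vs_result`.
#' @param ... unused.
#' @return a tibble with columns `method`, `n`, `n_selected`, `intercept`.
#' @export
glance.vs_result <- function(x, ...) {
  tibble(method = x$method, n = x$n, n_selected = length(x$selected),
         intercept = x$intercept)
}

#' Plot a selection result
#'
#' Lollipop plot of coefficient estimates, selected predictors highlighted.
#'
#' @param object a `vs_result`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.vs_result <- function(object, ...) {
  d <- tidy(object)
  d$term <- factor(d$term, levels = d$term)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$term, y = .data$estimate,
                                  colour = .data$selected)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$term, yend = 0)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, linewidth = 0.3) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#2166ac", `FALSE` = "grey65")) +
    ggplot2::labs(x = NULL, y = "coefficient estimate",
                  title = paste0("Selected model (", object$method, ")")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
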