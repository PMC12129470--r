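#' Backward elimination
#'
#' Starts from the full linear model and removes predictors step by step.
#' With `criterion = "pvalue"` the predictor with the largest coefficient
#' t-test p-value is dropped while that p-value exceeds `p_threshold`
#' (default 0.05); with `"aic"`/`"bic"` each step drops the single
#' predictor whose removal most decreases the criterion, stopping when no
#' removal decreases it (backward-only; re-entry of dropped predictors is
#' not allowed).  Reported coefficients come from the terminal OLS fit.
#'
#' @inheritParams ssd_ci
#' @param criterion `"pvalue"`, `"aic"` or `"bic"`.
#' @param p_threshold p-value threshold for `criterion = "pvalue"`.
#' @return a `vs_result` tagged `be-p`, `be-aic` or `be-bic`.
#' @examples
#' d <- sim_data(sim_design(120, seed = 2))
#' backward_eliminate(d, criterion = "aic")
#' @export
backward_eliminate <- function(data, outcome = "y",
                               criterion = c("pvalue", "aic", "bic"),
                               p_threshold = 0.05) {
  criterion <- match.arg(criterion)
  xy <- split_xy(data, outcome)
  X <- xy$X
  n <- nrow(X)
  M <- ncol(X)
  if (n <= M + 1) abort("backward elimination needs N > M + 1")
  qrX <- qr(cbind(1, X))
  if (qrX$rank < M + 1) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    collinear <- xy$predictors[setdiff(seq_len(M), keep - 1L)]
    abort(paste("rank-deficient model matrix; collinear columns:",
                paste(collinear, collapse = ", ")))
  }
  df <- data.frame(X, check.names = FALSE)
  df$.y <- xy$y

  if (criterion == "pvalue") {
    keep <- xy$predictors
    repeat {
      fit <- lm(as.formula(paste(".y ~", paste(sprintf("`%s`", keep), collapse = "+"))),
                data = df)
      p <- summary(fit)$coefficients[-1, 4]
      if (!length(p) || max(p) <= p_threshold) break
      keep <- keep[-which.max(p)]
      if (!length(keep)) {
        fit <- lm(.y ~ 1, data = df)
        break
      }
    }
    tag <- "be-p"
  } else {
    k_pen <- if (criterion == "aic") 2 else log(n)
    full <- lm(as.formula(paste(".y ~", paste(sprintf("`%s`", xy$predictors),
                                              collapse = "+"))), data = df)
    fit <- step(full, direction = "backward", trace = 0, k = k_pen)
    tag <- paste0("be-", criterion)
  }

  kept <- attr(terms(fit), "term.labels")
  kept <- gsub("^`|`$", "", kept)
  selected <- match(kept, xy$predictors)
  coef_full <- setNames(numeric(M), xy$predictors)
  est <- coef(fit)
  est_terms <- gsub("^`|`$", "", names(est)[-1])
  coef_full[est_terms] <- unname(est[-1])
  new_vs_result(tag, xy$predictors, selected, coef_full,
                unname(est[1]), n,
                details = list(criterion = criterion,
                               p_threshold = p_threshold,
                               fit_summary = summary(fit)$coefficients))
}
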