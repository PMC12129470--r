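# independent step-by-step transcription of the screening loop, written
# directly against the procedure (base R only, no shared package internals)
ssdci_oracle <- function(X, y, alpha = 0.05, var_frac = 0.75) {
  M <- ncol(X)
  Xs <- scale(X)
  C <- as.numeric(t(Xs) %*% (y - mean(y)))
  aC <- abs(C)
  ord <- order(aC, seq_len(M))
  k <- 0; v_prev <- Inf; ucl_all <- c()
  repeat {
    avail <- M - k
    top <- aC[ord[avail]]
    m <- max(2, floor(var_frac * avail))
    win <- aC[ord[(avail - m + 1):avail]]
    v <- sum(win^2) / m
    tc <- qt(1 - alpha / 2, M - k - 1)
    ucl <- top - tc * sqrt(v)
    ucl_all <- c(ucl_all, ucl)
    if (!(v < v_prev) || !(top > tc * sqrt(v))) {
      if (k == 0) return(list(sel = integer(0), ucl = ucl_all))
      return(list(sel = which(aC > ucl_all[k]), ucl = ucl_all))
    }
    if (!((M - (k + 1)) > m)) {
      return(list(sel = which(aC > ucl), ucl = ucl_all))
    }
    v_prev <- v; k <- k + 1
  }
}

test_that("the screening loop matches an independent step-by-step transcription", {
  for (seed in c(3, 17, 101, 555)) {
    d <- sim_data(default_design(225, 1, seed = seed), 1)
    X <- as.matrix(d[paste0("x", 1:15)])
    oracle <- ssdci_oracle(X, d$y)
    fit <- ssd_ci(d)
    expect_equal(fit$selected, sort(oracle$sel))
    expect_equal(fit$details$trace$ucl, oracle$ucl, tolerance = 1e-10)
  }
})

test_that("critical limits are symmetric and accepted variances strictly decrease", {
  for (seed in 1:25) {
    d <- sim_data(default_design(120, 1, seed = seed), 1)
    tr <- ssd_ci(d)$details$trace
    expect_equal(tr$lcl, -tr$ucl)
    acc <- tr$var_hat[tr$accepted]
    if (length(acc) > 1) expect_true(all(diff(acc) < 0))
    expect_lte(nrow(tr), 15)
    expect_true(all(tr$t_crit > 0))
    expect_true(all(tr$var_hat >= 0))
  }
})

test_that("selection is invariant to outcome scaling and predictor relocation", {
  d <- sim_data(default_design(150, 1, seed = 7), 1)
  base <- ssd_ci(d)$selected
  d2 <- d; d2$y <- 3.7 * d2$y
  expect_equal(ssd_ci(d2)$selected, base)
  d3 <- d
  for (j in 1:15) d3[[j]] <- 10 * d3[[j]] - 4   # affine relocation of X
  expect_equal(ssd_ci(d3)$selected, base)
})

test_that("permuting predictor columns permutes the selected set", {
  d <- sim_data(default_design(150, 1, seed = 12), 1)
  base <- ssd_ci(d)$selected
  perm <- c(4, 1, 15, 7, 2, 9, 11, 3, 5, 13, 6, 8, 14, 10, 12)
  dp <- d[c(perm, 16)]
  names(dp) <- c(paste0("x", 1:15), "y")
  got <- ssd_ci(dp)$selected
  expect_equal(sort(perm[got]), sort(base))
})

test_that("under a pure null the selected set stays far below the FPR ceiling", {
  sizes <- vapply(1:200, function(r) {
    d <- sim_data(default_design(225, 1, seed = 9000 + r), 1)
    d$y <- with_null_y(225, 9000 + r)
    length(ssd_ci(d)$selected)
  }, numeric(1))
  expect_lt(mean(sizes), 15 * 0.26)
})

test_that("a single strong predictor is recovered almost always", {
  # default (inclusive-window) reading at the study dimension M = 15
  hits15 <- vapply(1:200, function(r) {
    set.seed(4000 + r)
    X <- matrix(rnorm(100 * 15), 100, 15, dimnames = list(NULL, paste0("x", 1:15)))
    d <- tibble::as_tibble(as.data.frame(X))
    d$y <- 5 * d$x3 + rnorm(100)
    3 %in% ssd_ci(d)$selected
  }, logical(1))
  expect_gte(mean(hits15), 0.95)
  # in a small candidate set with a lone active contrast the exclusive
  # window is the sensitive variant (the inclusive window is dominated by
  # the contrast under test there)
  hits8 <- vapply(1:200, function(r) {
    set.seed(4000 + r)
    X <- matrix(rnorm(60 * 8), 60, 8, dimnames = list(NULL, paste0("x", 1:8)))
    d <- tibble::as_tibble(as.data.frame(X))
    d$y <- 5 * d$x3 + rnorm(60)
    3 %in% ssd_ci(d, window = "exclusive")$selected
  }, logical(1))
  expect_gte(mean(hits8), 0.95)
})

test_that("no signal at k = 0 returns the empty model with its terminal rule", {
  found <- FALSE
  for (r in 1:50) {
    d <- sim_data(default_design(80, 1, seed = 100 + r), 1)
    d$y <- with_null_y(80, 100 + r)
    fit <- ssd_ci(d)
    if (fit$details$terminal_rule == "no-signal-at-k0") {
      found <- TRUE
      expect_length(fit$selected, 0)
      expect_equal(unname(fit$coef), rep(0, 15))
      expect_equal(fit$intercept, mean(d$y))
      break
    }
  }
  expect_true(found)
})

test_that("the k0 full-variance variant runs and uses all contrasts at k = 0", {
  d <- sim_data(default_design(100, 1, seed = 31), 1)
  fit <- ssd_ci(d, k0_full_variance = TRUE)
  expect_equal(fit$details$trace$m[1], 15)
  fit2 <- ssd_ci(d, var_center = "mean")
  expect_s3_class(fit2, "vs_result")
})

test_that("the OLS refit honours its edge cases and a closed-form oracle", {
  d <- make_gaussian_data(40, c(2, -1, 0.5), seed = 6)
  X <- as.matrix(d[1:3])

  full <- refit_ols(d, selected = 1:3)
  lm_fit <- lm(y ~ ., data = d)
  expect_equal(unname(full$coef), unname(coef(lm_fit)[-1]), tolerance = 1e-10)
  expect_equal(full$intercept, unname(coef(lm_fit)[1]), tolerance = 1e-10)

  none <- refit_ols(d, selected = integer(0))
  expect_equal(none$intercept, mean(d$y))
  expect_equal(unname(none$coef), rep(0, 3))

  sub <- refit_ols(d, selected = c(1, 3))
  Z <- cbind(1, X[, c(1, 3)])
  beta_ne <- solve(crossprod(Z), crossprod(Z, d$y))   # normal equations
  expect_equal(unname(sub$coef[c(1, 3)]), unname(beta_ne[-1]), tolerance = 1e-8)
  expect_equal(unname(sub$coef[2]), 0)

  ddup <- d; ddup$x3 <- ddup$x1
  expect_warning(r <- refit_ols(ddup, selected = 1:3), "dropped")
  expect_false(3 %in% r$selected)
})

test_that("tidy and glance expose the selection as tibbles", {
  d <- sim_data(default_design(100, 1, seed = 2), 1)
  fit <- ssd_ci(d)
  td <- tidy(fit)
  expect_equal(nrow(td), 15)
  expect_true(all(td$estimate[!td$selected] == 0))
  gl <- glance(fit)
  expect_equal(gl$n_selected, length(fit$selected))
  expect_s3_class(autoplot(fit), "ggplot")
})
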