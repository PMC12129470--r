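test_that("the unpenalized limit reproduces OLS", {
  d <- make_gaussian_data(80, c(1.5, -2, 0.3, 0), seed = 3)
  X <- as.matrix(d[1:4])
  fit <- cd_fit(X, d$y, penalty_spec("lasso", lambda = 0))
  ols <- coef(lm(y ~ ., data = d))
  expect_equal(unname(fit$coef), unname(ols[-1]), tolerance = 1e-6)
  expect_equal(fit$intercept, unname(ols[1]), tolerance = 1e-6)
})

test_that("penalties at or above lambda_max give the null solution", {
  d <- make_gaussian_data(100, c(2, -1, 0.5, 0, 0), seed = 5)
  X <- as.matrix(d[1:5])
  lmax <- lambda_max(X, d$y)
  for (fam in c("lasso", "scad", "mcp")) {
    fit <- cd_fit(X, d$y, penalty_spec(fam, lambda = lmax * 1.0000001))
    expect_equal(unname(fit$coef), rep(0, 5))
  }
})

test_that("orthonormal designs reproduce the published closed forms", {
  n <- 128
  X <- make_orthonormal_x(n, 6, seed = 2)
  set.seed(9)
  y <- drop(X %*% c(2, -1.2, 0.6, 0.25, 0.08, 0)) + rnorm(n)
  z <- unname(drop(crossprod(X, y - mean(y)))) / n
  lam <- 0.3
  soft <- function(z, t) sign(z) * pmax(abs(z) - t, 0)

  las <- cd_fit(X, y, penalty_spec("lasso", lambda = lam))
  expect_equal(unname(las$beta_std), unname(soft(z, lam)), tolerance = 1e-8)

  g <- 3.7
  scad_closed <- vapply(z, function(zz) {
    az <- abs(zz)
    if (az <= 2 * lam) sign(zz) * max(az - lam, 0)
    else if (az <= g * lam) ((g - 1) * zz - sign(zz) * g * lam) / (g - 2)
    else zz
  }, numeric(1))
  sc <- cd_fit(X, y, penalty_spec("scad", lambda = lam))
  expect_equal(unname(sc$beta_std), scad_closed, tolerance = 1e-8)

  gm <- 3
  mcp_closed <- vapply(z, function(zz) {
    az <- abs(zz)
    if (az <= gm * lam) sign(zz) * max(az - lam, 0) / (1 - 1 / gm)
    else zz
  }, numeric(1))
  mc <- cd_fit(X, y, penalty_spec("mcp", lambda = lam))
  expect_equal(unname(mc$beta_std), mcp_closed, tolerance = 1e-8)
})

test_that("KKT residuals are tiny and the objective never increases", {
  d <- make_gaussian_data(90, c(1, -0.7, 0.4, 0, 0, 0), seed = 11)
  X <- as.matrix(d[1:6])
  lmax <- lambda_max(X, d$y)
  specs <- list(
    penalty_spec("lasso", lambda = lmax / 10),
    penalty_spec("enet", lambda = lmax / 5, alpha_mix = 0.3),
    penalty_spec("scad", lambda = lmax / 8),
    penalty_spec("mcp", lambda = lmax / 8),
    penalty_spec("alasso", lambda = lmax / 10,
                 weights = c(0.5, 1, 2, 4, 8, 16))
  )
  for (sp in specs) {
    fit <- cd_fit(X, d$y, sp)
    expect_lt(fit$kkt, 1e-5)
    expect_true(all(diff(fit$objective) <= 1e-12))
  }
})

test_that("elastic net with full L1 mixing equals the lasso", {
  d <- make_gaussian_data(70, c(1.2, 0, -0.8, 0.2), seed = 21)
  X <- as.matrix(d[1:4])
  lam <- lambda_max(X, d$y) / 4
  a <- cd_fit(X, d$y, penalty_spec("enet", lambda = lam, alpha_mix = 1))
  b <- cd_fit(X, d$y, penalty_spec("lasso", lambda = lam))
  expect_equal(a$coef, b$coef, tolerance = 1e-8)
})

test_that("the lasso path agrees with an independent solver", {
  skip_if_not_installed("glmnet")
  d <- make_gaussian_data(150, c(2, -1.5, 1, 0.5, 0, 0, 0, 0), seed = 42,
                          intercept = 3)
  X <- as.matrix(d[1:8])
  for (lam in c(0.5, 0.1, 0.02)) {
    mine <- cd_fit(X, d$y, penalty_spec("lasso", lambda = lam))
    ref <- glmnet::glmnet(X, d$y, lambda = lam, thresh = 1e-12)
    expect_equal(unname(mine$coef), as.vector(coef(ref))[-1], tolerance = 1e-6)
    expect_equal(mine$intercept, as.vector(coef(ref))[1], tolerance = 1e-6)
  }
  # elastic net: our solution must attain at least as low a value of the
  # stated objective (the reference rescales the ridge term internally)
  lam <- 0.3; a <- 0.4
  mine <- cd_fit(X, d$y, penalty_spec("enet", lambda = lam, alpha_mix = a))
  ref <- glmnet::glmnet(X, d$y, lambda = lam, alpha = a, thresh = 1e-12)
  obj <- function(b0, b) {
    mean((d$y - b0 - X %*% b)^2) / 2 +
      lam * (a * sum(abs(b) * apply(X, 2, function(c) sqrt(mean((c - mean(c))^2)))) +
             (1 - a) / 2 * sum((b * apply(X, 2, function(c) sqrt(mean((c - mean(c))^2))))^2))
  }
  expect_lte(obj(mine$intercept, mine$coef),
             obj(as.vector(coef(ref))[1], as.vector(coef(ref))[-1]) + 1e-10)
})

test_that("penalty specifications validate their parameters", {
  expect_error(penalty_spec("scad", lambda = 1, gamma = 2), "gamma > 2")
  expect_error(penalty_spec("mcp", lambda = 1, gamma = 1), "gamma > 1")
  expect_error(penalty_spec("lasso", lambda = -1), ">= 0")
  expect_error(penalty_spec("enet", lambda = 1, alpha_mix = 1.5), "0, 1")
  expect_error(penalty_spec("alasso", lambda = 1, weights = c(1, 0)), "positive")
  expect_equal(penalty_spec("scad", lambda = 1)$gamma, 3.7)
  expect_equal(penalty_spec("mcp", lambda = 1)$gamma, 3)
})
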