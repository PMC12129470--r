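# build a results tibble by hand
fake_results <- function(selections, coefs = NULL, method = "m", n = 225) {
  tibble::tibble(
    method = method, n = n, replicate = seq_along(selections),
    selected = lapply(selections, as.integer),
    coef = coefs %||% lapply(selections, function(s) {
      v <- numeric(15); v[s] <- 1; v
    }),
    error = NA_character_
  )
}

truth15 <- truth_spec(default_design(225, 1, 1))

test_that("error rates use the true/false support sizes as denominators", {
  perfect <- fake_results(list(1:7, 1:7))
  expect_equal(error_rates(perfect, truth15)[, c("fpr", "fnr")],
               tibble::tibble(fpr = 0, fnr = 0))
  one <- fake_results(list(c(1:6, 9)))
  er <- error_rates(one, truth15)
  expect_equal(er$fpr, 1 / 8)
  expect_equal(er$fnr, 1 / 7)
  everything <- fake_results(list(1:15, 1:15, 1:15))
  er2 <- error_rates(everything, truth15)
  expect_equal(er2$fpr, 1)
  expect_equal(er2$fnr, 0)
  expect_error(error_rates(fake_results(list())[0, ], truth15), "non-empty")
})

test_that("average model size is the plain mean over replicates", {
  expect_equal(avg_model_size(fake_results(list(1:7, 1:7)))$avg_selected, 7)
  expect_equal(avg_model_size(fake_results(list(1:6, 1:8)))$avg_selected, 7)
})

test_that("inclusion frequency counts per-predictor percentages", {
  r <- fake_results(rep(list(5L), 4))
  v <- inclusion_frequency(r, 15)
  expect_equal(v$vif_pct[v$predictor == 5], 100)
  expect_equal(sum(v$vif_pct[v$predictor != 5]), 0)
  half <- fake_results(list(3L, integer(0)))
  expect_equal(inclusion_frequency(half, 15)$vif_pct[3], 50)
})

test_that("bias and rmse impute zeros for unselected predictors", {
  bt <- truth15$beta_true
  exact <- fake_results(list(1:7, 1:7), coefs = list(bt, bt))
  br <- bias_rmse(exact, truth15)
  expect_equal(br$abs_bias, rep(0, 15))
  expect_equal(br$rmse, rep(0, 15))

  sym <- fake_results(list(1:15, 1:15), coefs = list(bt + 1, bt - 1))
  br2 <- bias_rmse(sym, truth15)
  expect_equal(br2$abs_bias, rep(0, 15))
  expect_equal(br2$rmse, rep(1, 15))

  # a never-selected null predictor scores zero on both
  never <- fake_results(list(1:7, 1:7))
  never$coef <- list(bt, bt)
  br3 <- bias_rmse(never, truth15)
  expect_equal(br3$abs_bias[9], 0)
  expect_equal(br3$rmse[9], 0)
})

test_that("avg size decomposes exactly into the error rates", {
  set.seed(77)
  sels <- lapply(1:50, function(i) sort(sample(15, rpois(1, 6), replace = FALSE)))
  r <- fake_results(sels)
  er <- error_rates(r, truth15)
  avg <- avg_model_size(r)$avg_selected
  expect_equal(avg, 8 * er$fpr + 7 * (1 - er$fnr), tolerance = 1e-12)
})

test_that("rmse dominates bias and metrics ignore replicate order", {
  set.seed(42)
  sels <- lapply(1:30, function(i) sort(sample(15, 5)))
  coefs <- lapply(sels, function(s) {
    v <- numeric(15); v[s] <- rnorm(5); v
  })
  r <- fake_results(sels, coefs = coefs)
  br <- bias_rmse(r, truth15)
  expect_true(all(br$rmse^2 >= br$abs_bias^2 - 1e-12))

  shuffled <- r[rev(seq_len(nrow(r))), ]
  expect_equal(bias_rmse(shuffled, truth15), br)
  expect_equal(error_rates(shuffled, truth15), error_rates(r, truth15))

  mt <- metric_table(r, truth15)
  expect_setequal(unique(mt$metric),
                  c("fpr", "fnr", "avg_selected", "vif_pct", "abs_bias", "rmse"))
})
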