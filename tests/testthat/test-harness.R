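test_that("a study produces one record per (method, n, replicate) cell", {
  cfg <- study_config(tiny_design(40), methods = c("be-aic", "ssdci"),
                      sample_sizes = 40, n_sims = 2, master_seed = 1)
  st <- run_study(cfg)
  expect_equal(nrow(st$results), 4)
  expect_setequal(st$results$method, c("be-aic", "ssdci"))
  expect_true(all(is.na(st$results$error)))
})

test_that("reruns with the same master seed are bit-identical and datasets are paired", {
  cfg <- study_config(tiny_design(40), methods = c("be-aic", "ssdci"),
                      sample_sizes = c(40, 60), n_sims = 2, master_seed = 11)
  a <- run_study(cfg)
  b <- run_study(cfg)
  expect_identical(a$results$selected, b$results$selected)
  expect_identical(a$results$coef, b$results$coef)
  # paired design: each (n, replicate) cell shares one dataset seed
  by_cell <- split(a$results$seed_used, paste(a$results$n, a$results$replicate))
  expect_true(all(vapply(by_cell, function(s) length(unique(s)) == 1, logical(1))))
  # and distinct cells use distinct seeds
  expect_equal(anyDuplicated(vapply(by_cell, unique, numeric(1))), 0)
})

test_that("the archive round-trips and the study resumes without recomputing", {
  dir1 <- file.path(tempdir(), "study-a")
  unlink(dir1, recursive = TRUE)
  cfg1 <- study_config(tiny_design(40), methods = c("be-aic", "ssdci"),
                       sample_sizes = 40, n_sims = 1, master_seed = 3,
                       output_dir = dir1)
  st1 <- run_study(cfg1)
  arch <- read_archive(file.path(dir1, "archive.jsonl"))
  expect_equal(nrow(arch), 2)
  expect_identical(arch$selected, st1$results$selected)

  # enlarge to 2 replicates: the first replicate's records must be reused
  cfg2 <- study_config(tiny_design(40), methods = c("be-aic", "ssdci"),
                       sample_sizes = 40, n_sims = 2, master_seed = 3,
                       output_dir = dir1)
  st2 <- run_study(cfg2)
  expect_equal(nrow(st2$results), 4)
  lines <- readLines(file.path(dir1, "archive.jsonl"))
  expect_length(lines, 4)

  # equal to a fresh full run
  cfg3 <- study_config(tiny_design(40), methods = c("be-aic", "ssdci"),
                       sample_sizes = 40, n_sims = 2, master_seed = 3)
  st3 <- run_study(cfg3)
  expect_equal(dplyr::arrange(st2$results, method, replicate)$coef,
               dplyr::arrange(st3$results, method, replicate)$coef)
})

test_that("summaries are pure functions of the archive with stable layout", {
  cfg <- study_config(tiny_design(60), methods = c("be-bic", "ssdci"),
                      sample_sizes = 60, n_sims = 3, master_seed = 5)
  st <- run_study(cfg)
  s1 <- summarize_study(st)
  expect_named(s1, c("avg_selected", "error_rates", "vif", "bias_rmse"))
  expect_equal(nrow(s1$avg_selected), 2)
  expect_equal(nrow(s1$vif), 2 * 5)
  s2 <- summarize_study(st$results, truth = truth_spec(tiny_design(60)))
  expect_equal(s1$avg_selected, s2$avg_selected)
  out <- file.path(tempdir(), "study-tables")
  summarize_study(st, out_dir = out)
  expect_true(all(file.exists(file.path(out, paste0(names(s1), ".csv")))))
})

test_that("a method failure is logged as a missing cell, never aborting", {
  # N = 17 > M = 15 lets the design build, but cross-validation
  # requires N >= 30, so the lasso cell fails while SSD-CI succeeds
  cfg <- study_config(default_design(17, 1, 1), methods = c("lasso-min", "ssdci"),
                      sample_sizes = 17, n_sims = 1, master_seed = 2)
  st <- run_study(cfg)
  expect_equal(nrow(st$results), 2)
  expect_true(any(!is.na(st$results$error)))
})

test_that("invalid configurations are rejected", {
  expect_error(study_config(tiny_design(40), methods = "nope"), "unknown method")
  expect_error(study_config(tiny_design(40), sample_sizes = 3), "exceed")
})
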