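#' Configuration of a simulation study
#'
#' @param design a [sim_design()]; its `N` is overridden per study cell.
#' @param methods character vector of method tags from [vs_methods()].
#' @param sample_sizes sample sizes to run (each must exceed `design$M`).
#' @param n_sims replicates per sample size.
#' @param master_seed seed from which all dataset and method streams derive.
#' @param output_dir optional directory for the JSON-lines archive; enables
#'   resuming.
#' @return a `study_config` list.
#' @export
study_config <- function(design, methods = vs_methods(),
                         sample_sizes = c(225, 375, 500, 750, 1000),
                         n_sims = 1000L, master_seed = 1L,
                         output_dir = NULL) {
  stopifnot(inherits(design, "sim_design"))
  bad <- setdiff(methods, vs_methods())
  if (length(bad)) {
    abort(paste("unknown method tag(s):", paste(bad, collapse = ", ")))
  }
  if (any(sample_sizes <= design$M)) {
    abort("every sample size must exceed the predictor count")
  }
  structure(list(design = design, methods = methods,
                 sample_sizes = as.integer(sample_sizes),
                 n_sims = as.integer(n_sims),
                 master_seed = as.integer(master_seed),
                 output_dir = output_dir),
            class = "study_config")
}

archive_path <- function(config) {
  file.path(config$output_dir, "archive.jsonl")
}

record_key <- function(method, n, replicate) {
  paste(method, n, replicate, sep = "|")
}

#' Run a simulation study
#'
#' For every (sample size, replicate) cell one dataset is generated — with
#' a seed derived from `(master_seed, N, replicate)` — and fed to every
#' method (paired comparison; method-internal randomness such as CV folds
#' derives from `(master_seed, N, replicate, method)` so methods share data
#' but not RNG streams).  A method failure on one replicate is logged as a
#' missing cell and never aborts the study.  With an `output_dir`, each
#' completed record is appended to a JSON-lines archive and completed cells
#' are skipped when the study is rerun.
#'
#' @param config a [study_config()].
#' @param progress print a line per (N, replicate) block to stderr.
#' @return a `vs_study`: list with `results` (tibble: `method`, `n`,
#'   `replicate`, `seed_used`, `selected` list-column, `coef` list-column,
#'   `intercept`, `error`) and `config`.
#' @export
run_study <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "study_config"))
  design <- config$design
  done <- character(0)
  rows <- list()
  apath <- NULL
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    apath <- archive_path(config)
    if (file.exists(apath)) {
      prior <- read_archive(apath)
      rows <- lapply(seq_len(nrow(prior)), function(i) prior[i, ])
      done <- record_key(prior$method, prior$n, prior$replicate)
    }
  }
  for (n in config$sample_sizes) {
    design_n <- design
    design_n$N <- as.integer(n)
    for (r in seq_len(config$n_sims)) {
      todo <- config$methods[!record_key(config$methods, n, r) %in% done]
      if (!length(todo)) next
      data_seed <- mix_seed(config$master_seed, n, r)
      design_r <- design_n
      design_r$seed <- data_seed
      dat <- sim_data(design_r, 1L)
      if (progress) {
        message(sprintf("N = %d, replicate %d (%d method(s))", n, r, length(todo)))
      }
      for (m in todo) {
        seed_m <- mix_seed(config$master_seed, n, r, tag_key(m))
        rec <- tryCatch({
          res <- vs_select(dat, method = m, seed = seed_m)
          tibble(method = m, n = as.integer(n), replicate = r,
                 seed_used = attr(dat, "seed_used"),
                 selected = list(res$selected), coef = list(unname(res$coef)),
                 intercept = res$intercept, error = NA_character_)
        }, error = function(e) {
          tibble(method = m, n = as.integer(n), replicate = r,
                 seed_used = attr(dat, "seed_used"),
                 selected = list(integer(0)), coef = list(numeric(design$M)),
                 intercept = NA_real_, error = conditionMessage(e))
        })
        rows[[length(rows) + 1L]] <- rec
        if (!is.null(apath)) append_archive(apath, rec)
      }
    }
  }
  results <- dplyr::bind_rows(rows) |>
    dplyr::arrange(.data$n, .data$replicate, .data$method)
  structure(list(results = results, config = config), class = "vs_study")
}

append_archive <- function(path, rec) {
  line <- jsonlite::toJSON(
    list(method = rec$method, n = rec$n, replicate = rec$replicate,
         seed_used = rec$seed_used, selected = rec$selected[[1]],
         coef = rec$coef[[1]], intercept = rec$intercept,
         error = rec$error),
    auto_unbox = TRUE, digits = NA, null = "null", na = "null"
  )
  cat(line, "\n", file = path, sep = "", append = TRUE)
}

#' Read a study archive back into a results tibble
#'
#' @param path path to an `archive.jsonl` written by [run_study()].
#' @return a results tibble (see [run_study()]).
#' @export
read_archive <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) abort("empty archive")
  recs <- lapply(lines, jsonlite::fromJSON, simplifyVector = TRUE)
  dplyr::bind_rows(lapply(recs, function(x) {
    tibble(method = x$method, n = as.integer(x$n),
           replicate = as.integer(x$replicate),
           seed_used = as.integer(x$seed_used),
           selected = list(as.integer(unlist(x$selected))),
           coef = list(as.numeric(unlist(x$coef))),
           intercept = x$intercept %||% NA_real_,
           error = x$error %||% NA_character_)
  }))
}

#' Summarize a study into the four report tables
#'
#' A pure function of the per-replicate archive: average model size, error
#' rates, inclusion frequencies, and per-predictor bias/RMSE, each as a
#' tidy tibble ordered stably.
#'
#' @param study a `vs_study`, a results tibble, or an archive path.
#' @param truth a [truth_spec()]; defaults to the study design's.
#' @param out_dir optional directory to write the four CSVs into.
#' @return a named list of tibbles: `avg_selected`, `error_rates`, `vif`,
#'   `bias_rmse`.
#' @export
summarize_study <- function(study, truth = NULL, out_dir = NULL) {
  results <- if (inherits(study, "vs_study")) {
    truth <- truth %||% truth_spec(study$config$design)
    study$results
  } else if (is.character(study)) {
    read_archive(study)
  } else {
    study
  }
  if (is.null(truth)) abort("`truth` must be supplied")
  ok <- results[is.na(results$error), ]
  out <- list(
    avg_selected = avg_model_size(ok),
    error_rates = error_rates(ok, truth),
    vif = inclusion_frequency(ok, truth$M),
    bias_rmse = bias_rmse(ok, truth)
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(out)) {
      utils::write.csv(out[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                       row.names = FALSE)
    }
  }
  out
}

#' @export
print.vs_study <- function(x, ...) {
  cat("<vs_study>", length(unique(x$results$method)), "methods x",
      length(unique(x$results$n)), "sample sizes x",
      max(x$results$replicate), "replicates\n")
  invisible(x)
}

#' Plot inclusion frequencies across methods
#'
#' Dot plot of per-predictor inclusion frequency faceted by method, true
#' and false predictors coloured differently.
#'
#' @param vif tibble from [inclusion_frequency()].
#' @param truth a [truth_spec()].
#' @return a ggplot object.
#' @export
plot_inclusion <- function(vif, truth) {
  vif$status <- ifelse(vif$predictor %in% truth$true_support, "true", "false")
  ggplot2::ggplot(vif, ggplot2::aes(x = .data$predictor, y = .data$vif_pct,
                                    colour = .data$status,
                                    group = factor(.data$n))) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::facet_wrap(~method) +
    ggplot2::scale_colour_manual(values = c(true = "#b2182b", false = "#2166ac")) +
    ggplot2::labs(x = "predictor index", y = "inclusion frequency (%)") +
    ggplot2::theme_minimal()
}
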