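#' Specify a noise-sweep experiment
#'
#' One sweep cell = (noise level, method, seed): the clean training split is
#' corrupted at the given false-negative rate (false-positive rate held
#' constant), the method is trained, the threshold is tuned on the
#' validation split to the target sensitivity, and the model is evaluated on
#' the clean-labeled test split. Corruption is a deterministic function of
#' (noise level, seed) only, so every method within a cell sees identical
#' corrupted labels, and test labels are never corrupted.
#'
#' @param noise_levels False-negative rates on cases to sweep (default
#'   0, 0.1, 0.2, 0.3, 0.4).
#' @param fp_rate False-positive rate on controls, held constant (default
#'   0.005, matching the near-perfect specificity of the reference test).
#' @param methods Subset of `"baseline"`, `"smoothing"`, `"mixup"`, `"ncr"`,
#'   `"mixup+ncr"`, `"gbt"`.
#' @param n_seeds Number of independent repetitions.
#' @param cohort A [cohort_spec()] for the synthetic cohort.
#' @param config A [train_config()]; its method field is overridden per cell.
#' @param gbt_params Parameters for the gradient-boosted baseline.
#' @param target_sensitivity Sensitivity target for threshold tuning.
#' @param fractions Train/val/test fractions.
#' @param n_boot Bootstrap resamples per evaluation (0 disables CIs in the
#'   per-cell report and keeps only point metrics, which is much faster for
#'   large sweeps).
#' @param seed Base seed; cohort, split, corruption and training seeds are
#'   derived from it.
#' @param out_dir Optional directory for CSV results and the run log.
#' @return A `sweep_spec` list.
#' @export
sweep_spec <- function(noise_levels = c(0, 0.1, 0.2, 0.3, 0.4),
                       fp_rate = 0.005,
                       methods = c("baseline", "ncr"),
                       n_seeds = 5,
                       cohort = cohort_spec(),
                       config = train_config(),
                       gbt_params = list(),
                       target_sensitivity = 0.85,
                       fractions = c(0.6, 0.2, 0.2),
                       n_boot = 0,
                       seed = 1,
                       out_dir = NULL) {
  for (nl in noise_levels) check_fraction(nl, "noise_levels")
  check_fraction(fp_rate, "fp_rate")
  ok <- c("baseline", "smoothing", "mixup", "ncr", "mixup+ncr", "gbt")
  if (!all(methods %in% ok)) {
    abort(sprintf("unknown method(s): %s",
                  paste(setdiff(methods, ok), collapse = ", ")))
  }
  n_seeds <- check_count(n_seeds, "n_seeds")
  structure(list(noise_levels = noise_levels, fp_rate = fp_rate,
                 methods = methods, n_seeds = n_seeds, cohort = cohort,
                 config = config, gbt_params = gbt_params,
                 target_sensitivity = target_sensitivity,
                 fractions = fractions, n_boot = n_boot,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "sweep_spec")
}

# Train one method on corrupted train / clean val, tune threshold, evaluate
# on the clean test labels. Returns a one-row tibble of metrics.
run_cell <- function(method, train_noisy, val, test, spec, run_seed,
                     record_confidence = FALSE) {
  if (method == "gbt") {
    model <- train_gbt_baseline(train_noisy, spec$gbt_params, seed = run_seed)
    fit <- NULL
    score <- function(tbl) predict(model, tbl)
  } else {
    cfg <- spec$config
    cfg$method <- method
    cfg$seed <- run_seed
    cfg$record_confidence <- record_confidence
    fit <- train_model(train_noisy, val, cfg)
    score <- function(tbl) predict(fit, tbl)
  }
  thr <- tune_threshold(val$label, score(val), spec$target_sensitivity)
  test_clean <- test
  test_clean$label <- test_clean$clean_label
  metrics <- compute_metrics(test_clean$label, score(test_clean), thr)
  list(metrics = metrics, fit = fit)
}

#' Run the noise-level x method sweep
#'
#' For each seed, one clean cohort is generated, split and preprocessed; for
#' each noise level the training labels are corrupted once and every method
#' is trained on the identical corrupted split. Evaluation is always against
#' the clean test labels.
#'
#' @param spec A [sweep_spec()].
#' @param keep_fits If `TRUE`, also return the fitted models of the highest
#'   noise level (used by the memorization diagnostics).
#' @return A tibble with one row per (seed, fn_rate, method) carrying the
#'   test metrics; failures are recorded as `NA` rows and the sweep
#'   continues. Summaries via [summarize_sweep()].
#' @export
run_sweep <- function(spec, keep_fits = FALSE) {
  stopifnot(inherits(spec, "sweep_spec"))
  rows <- list()
  fits <- list()
  for (s in seq_len(spec$n_seeds)) {
    cspec <- spec$cohort
    cspec$seed <- derive_seed(spec$seed, s, 11L)
    cohort <- generate_cohort(cspec)
    splits <- split_cohort(cohort, spec$fractions,
                           seed = derive_seed(spec$seed, s, 12L))
    state <- fit_preprocess(splits$train)
    train0 <- apply_preprocess(splits$train, state)
    val <- apply_preprocess(splits$val, state)
    test <- apply_preprocess(splits$test, state)
    for (fn in spec$noise_levels) {
      nspec <- noise_spec(fn_rate = fn, fp_rate = spec$fp_rate,
                          seed = derive_seed(spec$seed, s, round(fn * 1000), 13L))
      train_noisy <- inject_label_noise(train0, nspec)
      for (method in spec$methods) {
        run_seed <- derive_seed(spec$seed, s, 14L)
        keep <- keep_fits && fn == max(spec$noise_levels) && method != "gbt"
        cell <- tryCatch(
          run_cell(method, train_noisy, val, test, spec, run_seed,
                   record_confidence = keep),
          error = function(e) {
            inform(sprintf("cell failed (seed %d, fn %.2f, %s): %s",
                           s, fn, method, conditionMessage(e)))
            NULL
          })
        if (is.null(cell)) {
          rows[[length(rows) + 1L]] <-
            tibble::tibble(seed = s, fn_rate = fn, method = method,
                           auroc = NA_real_)
        } else {
          rows[[length(rows) + 1L]] <-
            dplyr::bind_cols(tibble::tibble(seed = s, fn_rate = fn,
                                            method = method), cell$metrics)
          if (keep) {
            fits[[paste(method, s, sep = "_")]] <-
              list(fit = cell$fit, train = train_noisy, seed = s)
          }
        }
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  if (!is.null(spec$out_dir)) {
    dir.create(spec$out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(out, file.path(spec$out_dir, "sweep_results.csv"))
    summ <- summarize_sweep(out)
    readr::write_csv(summ$by_level,
                     file.path(spec$out_dir, "sweep_summary_by_level.csv"))
    readr::write_csv(summ$by_method,
                     file.path(spec$out_dir, "sweep_summary_by_method.csv"))
  }
  if (keep_fits) attr(out, "fits") <- fits
  out
}

#' Summarize a sweep: per-method consistency across noise levels
#'
#' Per (method, noise level), the across-seed mean AUROC; then per method,
#' the mean and standard deviation of those level means across noise levels.
#' The standard deviation is the consistency statistic: a noise-robust
#' method keeps it small.
#'
#' @param results The tibble returned by [run_sweep()].
#' @return List of two tibbles: `by_level` (method x fn_rate means) and
#'   `by_method` (`mean_auroc`, `sd_auroc` across levels).
#' @export
summarize_sweep <- function(results) {
  by_level <- results |>
    dplyr::group_by(.data$method, .data$fn_rate) |>
    dplyr::summarise(mean_auroc = mean(.data$auroc, na.rm = TRUE),
                     sd_auroc = sd(.data$auroc, na.rm = TRUE),
                     n = sum(!is.na(.data$auroc)), .groups = "drop")
  by_method <- by_level |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(sd_auroc = sd(.data$mean_auroc),
                     mean_auroc = mean(.data$mean_auroc), .groups = "drop") |>
    dplyr::select("method", "mean_auroc", "sd_auroc")
  structure(list(by_level = by_level, by_method = by_method),
            class = "sweep_summary")
}

#' @export
print.sweep_summary <- function(x, ...) {
  cat("Across-noise AUROC by method (sd = consistency across noise levels):\n")
  print(x$by_method)
  cat("\nPer noise level:\n")
  print(x$by_level)
  invisible(x)
}

#' Plot sweep results: AUROC against noise level by method
#'
#' @param results The tibble returned by [run_sweep()].
#' @return A ggplot.
#' @export
plot_sweep <- function(results) {
  lev <- results |>
    dplyr::group_by(.data$method, .data$fn_rate) |>
    dplyr::summarise(mean_auroc = mean(.data$auroc, na.rm = TRUE),
                     .groups = "drop")
  ggplot2::ggplot(lev, ggplot2::aes(x = .data$fn_rate, y = .data$mean_auroc,
                                    colour = .data$method)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "false-negative rate on cases (training labels)",
                  y = "clean-test AUROC")
}

#' NCR hyperparameter ablation
#'
#' Re-runs the NCR arm of the sweep once per value of one hyperparameter
#' axis, all else held fixed, and reports AUROC per (value, noise level).
#'
#' @param spec A [sweep_spec()] (its `methods` field is ignored; the NCR arm
#'   is run).
#' @param axis One of `"warmup_epochs"`, `"ncr_weight"`, `"k"`,
#'   `"ncr_layer"`, `"batch_size"`.
#' @param values Numeric vector of axis values.
#' @return Tibble: `axis`, `value`, plus the [run_sweep()] columns.
#' @export
run_ncr_ablation <- function(spec, axis, values) {
  ok <- c("warmup_epochs", "ncr_weight", "k", "ncr_layer", "batch_size")
  if (!axis %in% ok) {
    abort(sprintf("invalid axis '%s'; must be one of %s", axis,
                  paste(ok, collapse = ", ")))
  }
  purrr::map_dfr(values, function(v) {
    sp <- spec
    sp$methods <- "ncr"
    sp$out_dir <- NULL
    switch(axis,
           warmup_epochs = { sp$config$ncr$warmup_epochs <- as.integer(v) },
           ncr_weight = { sp$config$ncr$weight <- v },
           k = { sp$config$ncr$k <- as.integer(v) },
           ncr_layer = { sp$config$mlp$ncr_layer <- as.integer(v) },
           batch_size = { sp$config$mlp$batch_size <- as.integer(v) })
    run_sweep(sp) |>
      dplyr::mutate(axis = axis, value = v, .before = 1)
  })
}
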