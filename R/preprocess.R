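#' Fit median-imputation and standardization on a training split
#'
#' Computes, per feature: the median over observed (non-missing) training
#' entries, then the mean and standard deviation of the imputed training
#' column. [apply_preprocess()] replays these statistics on any split, so no
#' information leaks from validation or test data into the transform. The
#' even-length median is the mean of the two central order statistics.
#'
#' @param train Training-split cohort tibble.
#' @param on_constant What to do with a constant training feature (sd = 0):
#'   `"error"` (default) or `"unit_scale"` (leave the column unscaled).
#' @return A `preprocess_state` object: a tibble with one row per feature
#'   (`feature`, `median`, `mean`, `sd`).
#' @export
fit_preprocess <- function(train, on_constant = c("error", "unit_scale")) {
  on_constant <- match.arg(on_constant)
  x <- feature_matrix(train)
  n_obs <- colSums(!is.na(x))
  if (any(n_obs == 0L)) {
    abort(sprintf("feature(s) fully missing in training split: %s",
                  paste(which(n_obs == 0L), collapse = ", ")))
  }
  med <- apply(x, 2, median, na.rm = TRUE)
  for (j in seq_len(ncol(x))) x[is.na(x[, j]), j] <- med[j]
  mu <- colMeans(x)
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    if (on_constant == "error") {
      abort(sprintf("constant training feature(s): %s (set on_constant = 'unit_scale' to pass through)",
                    paste(which(sds == 0), collapse = ", ")))
    }
    sds[sds == 0] <- 1
  }
  structure(tibble::tibble(feature = colnames(x), median = unname(med),
                           mean = unname(mu), sd = unname(sds)),
            class = c("preprocess_state", "tbl_df", "tbl", "data.frame"))
}

#' Apply fitted preprocessing to a split
#'
#' Imputes missing entries with the training medians, then standardizes each
#' feature with the training mean and standard deviation. Only training
#' statistics are used; applied to the training split itself, every column
#' comes out with mean 0 and sd 1.
#'
#' @param table Cohort tibble with the same features as the fitted split.
#' @param state A `preprocess_state` from [fit_preprocess()].
#' @return The table with transformed, complete feature columns.
#' @export
apply_preprocess <- function(table, state) {
  stopifnot(inherits(state, "preprocess_state"))
  feats <- feature_cols(table)
  if (length(feats) != nrow(state) || !all(feats == state$feature)) {
    abort("feature columns do not match the fitted preprocess state")
  }
  for (j in seq_along(feats)) {
    col <- table[[feats[j]]]
    col[is.na(col)] <- state$median[j]
    table[[feats[j]]] <- (col - state$mean[j]) / state$sd[j]
  }
  table
}

#' Serialize / restore a preprocess state
#'
#' Written as plain CSV (one row per feature) so a test-time application is
#' reproducible outside the fitting session.
#'
#' @param state A `preprocess_state`.
#' @param path File path.
#' @export
write_preprocess_state <- function(state, path) {
  readr::write_csv(state, path)
  invisible(state)
}

#' @rdname write_preprocess_state
#' @export
read_preprocess_state <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  structure(out[c("feature", "median", "mean", "sd")],
            class = c("preprocess_state", "tbl_df", "tbl", "data.frame"))
}
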