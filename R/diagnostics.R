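#' Latent-similarity distributions stratified by label correctness
#'
#' Computes cosine similarities between pairs of training samples in the same
#' representation space the NCR term uses (the configured hidden layer), and
#' stratifies each pair by (i) whether the two assigned labels agree and
#' (ii) whether either member is mislabeled. The four strata are disjoint and
#' exhaust all evaluated pairs:
#' `same_label_clean`, `same_label_noisy`, `diff_label_clean`,
#' `diff_label_noisy`. A well-separated representation shows high
#' same-class-clean similarity and low different-class-clean similarity.
#'
#' All pairs are used when their number does not exceed `max_pairs`;
#' otherwise `max_pairs` pairs are subsampled under `seed`.
#'
#' @param fit An `mlp_fit` (or bare `mlp_model`).
#' @param table The (noisy) training cohort tibble; must carry `noise_flag`
#'   and `clean_label`.
#' @param max_pairs Pair budget before subsampling (default 1e5).
#' @param seed Seed for pair subsampling.
#' @return A `similarity_strata` tibble: `i`, `j`, `similarity`, `stratum`.
#'   Summaries via [summary.similarity_strata()] / [similarity_gap()].
#' @export
similarity_strata <- function(fit, table, max_pairs = 1e5, seed = 1) {
  model <- if (inherits(fit, "mlp_fit")) fit$model else fit
  stopifnot(inherits(model, "mlp_model"))
  if (!all(c("noise_flag", "clean_label") %in% names(table))) {
    abort("table must carry `noise_flag` and `clean_label` (synthetic metadata)")
  }
  V <- mlp_forward(model, table)$v
  n <- nrow(V)
  total <- n * (n - 1) / 2
  pairs <- if (total <= max_pairs) {
    ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    tibble::tibble(i = ij[, 1], j = ij[, 2])
  } else {
    with_seed(seed, function() {
      # sample linear indices of the upper triangle without replacement
      lin <- sample(total, max_pairs)
      j <- ceiling((sqrt(8 * lin + 1) + 1) / 2)
      i <- lin - (j - 1) * (j - 2) / 2
      tibble::tibble(i = as.integer(i), j = as.integer(j))
    })
  }
  nrm <- sqrt(rowSums(V^2))
  Vn <- V / ifelse(nrm > 0, nrm, 1)
  sim <- rowSums(Vn[pairs$i, , drop = FALSE] * Vn[pairs$j, , drop = FALSE])
  sim[nrm[pairs$i] == 0 | nrm[pairs$j] == 0] <- 0
  same <- table$label[pairs$i] == table$label[pairs$j]
  noisy <- table$noise_flag[pairs$i] == 1L | table$noise_flag[pairs$j] == 1L
  stratum <- dplyr::case_when(
    same & !noisy ~ "same_label_clean",
    same & noisy ~ "same_label_noisy",
    !same & !noisy ~ "diff_label_clean",
    TRUE ~ "diff_label_noisy")
  out <- tibble::tibble(i = pairs$i, j = pairs$j, similarity = sim,
                        stratum = factor(stratum,
                                         levels = c("same_label_clean",
                                                    "same_label_noisy",
                                                    "diff_label_clean",
                                                    "diff_label_noisy")))
  class(out) <- c("similarity_strata", class(out))
  out
}

#' @describeIn similarity_strata Per-stratum mean, median and pair count; an
#'   empty stratum yields `NA` summaries with `n = 0`.
#' @param object,... Method arguments.
#' @export
summary.similarity_strata <- function(object, ...) {
  tibble::as_tibble(object) |>
    dplyr::group_by(.data$stratum, .drop = FALSE) |>
    dplyr::summarise(n = dplyr::n(),
                     mean = mean(.data$similarity),
                     median = median(.data$similarity),
                     .groups = "drop")
}

#' Class-separation gap of a representation
#'
#' `mean(same-label clean pairs) - mean(different-label clean pairs)`: how
#' much more similar correctly labeled same-class pairs are than correctly
#' labeled different-class pairs. Larger = better class separation.
#'
#' @param strata A `similarity_strata` tibble.
#' @return Scalar gap.
#' @export
similarity_gap <- function(strata) {
  s <- summary(strata)
  s$mean[s$stratum == "same_label_clean"] -
    s$mean[s$stratum == "diff_label_clean"]
}

#' Per-epoch confidence trajectories of clean vs mislabeled samples
#'
#' The confidence of a training sample is the probability the model assigns
#' to that sample's (possibly noisy) training label: `p` when the label is 1,
#' `1 - p` when it is 0. A network memorizing noise shows confidence on
#' mislabeled samples climbing over training; a noise-robust objective keeps
#' it low while clean-sample confidence stays high.
#'
#' @param history A `train_history` recorded with `record_confidence = TRUE`.
#' @param noise_flags Binary vector flagging mislabeled training rows; taken
#'   from the history attributes when omitted.
#' @return A `confidence_trace` tibble: `epoch`, `group`
#'   (`"clean"`/`"mislabeled"`), `mean_confidence`, `n`.
#' @export
confidence_trace <- function(history, noise_flags = NULL) {
  conf <- attr(history, "confidence")
  if (is.null(conf)) {
    abort("history carries no per-sample confidences; train with record_confidence = TRUE")
  }
  noise_flags <- noise_flags %||% attr(history, "noise_flags")
  if (is.null(noise_flags)) abort("noise_flags missing")
  if (length(noise_flags) != ncol(conf)) {
    abort("noise_flags length does not match the number of training samples")
  }
  flags <- as.integer(noise_flags)
  out <- purrr::map_dfr(c(clean = 0L, mislabeled = 1L), function(fl) {
    cols <- flags == fl
    tibble::tibble(epoch = seq_len(nrow(conf)),
                   mean_confidence = if (any(cols)) {
                     rowMeans(conf[, cols, drop = FALSE])
                   } else NA_real_,
                   n = sum(cols))
  }, .id = "group")
  out <- out[c("epoch", "group", "mean_confidence", "n")]
  class(out) <- c("confidence_trace", class(out))
  out
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @exportS3Method ggplot2::autoplot
autoplot.train_history <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              c("ce", "ncr", "val_auroc"),
                              names_to = "term", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$term), scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL)
}

#' @exportS3Method ggplot2::autoplot
autoplot.similarity_strata <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$similarity, fill = .data$stratum)) +
    ggplot2::geom_density(alpha = 0.4) +
    ggplot2::labs(x = "cosine similarity", y = "density")
}

#' @exportS3Method ggplot2::autoplot
autoplot.confidence_trace <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$epoch, y = .data$mean_confidence,
                               colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "epoch", y = "mean confidence in assigned label")
}

#' Export a similarity-strata histogram as CSV
#'
#' @param strata A `similarity_strata` tibble.
#' @param path Output CSV path.
#' @param breaks Number of histogram bins over [-1, 1].
#' @export
write_strata_histogram <- function(strata, path, breaks = 50) {
  edges <- seq(-1, 1, length.out = breaks + 1)
  out <- tibble::as_tibble(strata) |>
    dplyr::mutate(bin = cut(.data$similarity, edges, include.lowest = TRUE)) |>
    dplyr::count(.data$stratum, .data$bin, .drop = FALSE)
  readr::write_csv(out, path)
  invisible(out)
}
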