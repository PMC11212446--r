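#' Area under the ROC curve (rank statistic)
#'
#' Mann-Whitney formulation with midranks, so tied scores count one half:
#' `AUROC = (sum of positive ranks - n1(n1+1)/2) / (n1 n0)`.
#'
#' @param labels Binary labels (0/1), both classes present.
#' @param scores Numeric scores, higher = more positive.
#' @return AUROC in [0, 1].
#' @export
auroc <- function(labels, scores) {
  y <- check_binary(labels)
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) {
    abort("AUROC undefined: labels contain a single class")
  }
  r <- rank(scores)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve (step integration)
#'
#' Thresholds sweep the distinct score values from high to low; the curve is
#' integrated as `sum over threshold steps of (delta recall) * precision`
#' at each achieved recall level (average-precision form). Tied scores enter
#' the confusion counts together.
#'
#' @inheritParams auroc
#' @return AUPRC in [0, 1].
#' @export
auprc <- function(labels, scores) {
  y <- check_binary(labels)
  n1 <- sum(y == 1L)
  if (n1 == 0L) abort("AUPRC undefined: no positives")
  ord <- order(scores, decreasing = TRUE)
  y <- y[ord]
  s <- scores[ord]
  keep <- c(s[-length(s)] != s[-1L], TRUE)  # last index of each tie group
  tp <- cumsum(y)[keep]
  fp <- cumsum(1L - y)[keep]
  prec <- tp / (tp + fp)
  rec <- tp / n1
  sum(diff(c(0, rec)) * prec)
}

#' Confusion-matrix metrics at a decision threshold
#'
#' Predicts positive when `score >= threshold` and reports the standard
#' operating-point metrics alongside AUROC and AUPRC. PPV (NPV) is `NA` when
#' no positive (negative) predictions are made.
#'
#' @inheritParams auroc
#' @param threshold Decision threshold.
#' @return One-row tibble: `auroc`, `auprc`, `sensitivity`, `specificity`,
#'   `ppv`, `npv`, `threshold`, plus the confusion counts.
#' @export
compute_metrics <- function(labels, scores, threshold) {
  y <- check_binary(labels)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & y == 1L)
  fp <- sum(pred == 1L & y == 0L)
  fn <- sum(pred == 0L & y == 1L)
  tn <- sum(pred == 0L & y == 0L)
  tibble::tibble(
    auroc = auroc(y, scores),
    auprc = auprc(y, scores),
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
    threshold = threshold,
    tp = tp, fp = fp, fn = fn, tn = tn)
}

#' Tune the decision threshold to a target sensitivity
#'
#' Grid-searches candidate thresholds — the midpoints of consecutive sorted
#' unique validation scores, plus one candidate below the minimum and one
#' above the maximum — and returns the highest threshold whose validation
#' sensitivity is still >= `target_sensitivity` (i.e. the most specific
#' admissible operating point). With `target_sensitivity = 0` the candidate
#' above the maximum score is admissible and is returned (predict nothing
#' positive). If no candidate attains the target, the minimum score is
#' returned with a warning.
#'
#' @param val_labels Binary validation labels (>= 1 positive).
#' @param val_scores Validation scores.
#' @param target_sensitivity Required sensitivity, default 0.85 (chosen to
#'   exceed lateral-flow-device sensitivity in the triage setting).
#' @return The tuned threshold.
#' @export
tune_threshold <- function(val_labels, val_scores, target_sensitivity = 0.85) {
  y <- check_binary(val_labels, "val_labels")
  if (sum(y == 1L) == 0L) abort("validation split contains no positives")
  u <- sort(unique(val_scores))
  span <- max(diff(range(u)), 1)
  cand <- c(u[1L] - span * 1e-6,
            if (length(u) > 1L) (u[-length(u)] + u[-1L]) / 2,
            u[length(u)] + span * 1e-6)
  sens <- vapply(cand, function(thr) {
    sum(val_scores >= thr & y == 1L) / sum(y == 1L)
  }, numeric(1))
  ok <- sens >= target_sensitivity
  if (!any(ok)) {
    warn("no threshold attains the target sensitivity; returning the minimum score")
    return(min(val_scores))
  }
  max(cand[ok])
}

# Bootstrap resample indices: with replacement, redrawn (up to 100 attempts)
# when the resample contains a single class. Returns n x draws index matrix
# and the redraw count.
bootstrap_indices <- function(labels, n_boot) {
  n <- length(labels)
  idx <- matrix(0L, n, n_boot)
  redraws <- 0L
  for (b in seq_len(n_boot)) {
    for (attempt in seq_len(100L)) {
      cand <- sample.int(n, n, replace = TRUE)
      if (length(unique(labels[cand])) > 1L) break
      redraws <- redraws + 1L
    }
    idx[, b] <- cand
  }
  list(idx = idx, redraws = redraws)
}

resolve_metric <- function(metric) {
  if (is.function(metric)) return(metric)
  switch(metric,
         auroc = auroc,
         auprc = auprc,
         abort(sprintf("unknown metric '%s'", metric)))
}

#' Percentile bootstrap confidence interval for a test-set metric
#'
#' Draws `n_boot` resamples of the test set with replacement, recomputes the
#' metric on each, and reports the percentile interval (2.5th and 97.5th
#' percentiles at the default level). Single-class resamples are redrawn and
#' the redraw count reported via a message.
#'
#' @inheritParams auroc
#' @param metric Metric function `f(labels, scores)` or one of `"auroc"`,
#'   `"auprc"`.
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param level Confidence level (default 0.95).
#' @param seed Seed for the resampling.
#' @param keep_draws If `TRUE`, attach the per-resample metric values and the
#'   resample index matrix as attributes (used for oracle checks and paired
#'   comparisons sharing the same resamples).
#' @return Named numeric `c(lower, upper)`.
#' @export
bootstrap_ci <- function(labels, scores, metric = "auroc", n_boot = 1000,
                         level = 0.95, seed = 1, keep_draws = FALSE) {
  y <- check_binary(labels)
  if (n_boot < 2L) abort("`n_boot` must be at least 2")
  f <- resolve_metric(metric)
  bs <- with_seed(seed, function() bootstrap_indices(y, n_boot))
  if (bs$redraws > 0L) {
    inform(sprintf("bootstrap: %d single-class resample(s) redrawn", bs$redraws))
  }
  vals <- apply(bs$idx, 2, function(i) {
    tryCatch(f(y[i], scores[i]), error = function(e) NA_real_)
  })
  if (mean(is.na(vals)) > 0.5) {
    abort("metric undefined on more than half of the bootstrap resamples")
  }
  qs <- quantile(vals, c((1 - level) / 2, 1 - (1 - level) / 2), na.rm = TRUE,
                 names = FALSE)
  out <- c(lower = qs[1], upper = qs[2])
  if (keep_draws) {
    attr(out, "draws") <- vals
    attr(out, "indices") <- bs$idx
  }
  out
}

#' Paired-bootstrap comparison of two models
#'
#' Both score vectors are evaluated on the same resamples of the same test
#' rows. With model A as the candidate, the p-value is the fraction of
#' resamples on which A fails to beat B, ties counted one half:
#' `p = (#\{m_A < m_B\} + 0.5 #\{m_A = m_B\}) / n_boot`. Identical score
#' vectors therefore give p = 0.5, and p = 0 means A won every resample.
#'
#' @inheritParams bootstrap_ci
#' @param scores_A,scores_B Scores of the candidate (A) and comparator (B) on
#'   the same test rows.
#' @return One-sided p-value in [0, 1].
#' @export
paired_bootstrap_pvalue <- function(labels, scores_A, scores_B,
                                    metric = "auroc", n_boot = 1000, seed = 1) {
  y <- check_binary(labels)
  if (length(scores_A) != length(y) || length(scores_B) != length(y)) {
    abort("scores_A, scores_B and labels must have equal length")
  }
  f <- resolve_metric(metric)
  bs <- with_seed(seed, function() bootstrap_indices(y, n_boot))
  wins <- apply(bs$idx, 2, function(i) {
    ma <- f(y[i], scores_A[i])
    mb <- f(y[i], scores_B[i])
    if (ma < mb) 1 else if (ma == mb) 0.5 else 0
  })
  mean(wins)
}

#' Full evaluation report for one scored test set
#'
#' Point metrics at the supplied threshold plus percentile-bootstrap 95% CIs
#' for AUROC, AUPRC, sensitivity and specificity.
#'
#' @inheritParams compute_metrics
#' @param n_boot,level,seed Bootstrap settings (see [bootstrap_ci()]).
#' @return An `eval_report`: tibble with `metric`, `estimate`, `lower`,
#'   `upper`; threshold and `n_boot` kept as attributes.
#' @export
evaluate_scores <- function(labels, scores, threshold, n_boot = 1000,
                            level = 0.95, seed = 1) {
  pt <- compute_metrics(labels, scores, threshold)
  metric_fns <- list(
    auroc = auroc,
    auprc = auprc,
    sensitivity = function(l, s) compute_metrics(l, s, threshold)$sensitivity,
    specificity = function(l, s) compute_metrics(l, s, threshold)$specificity)
  rows <- purrr::imap(metric_fns, function(f, nm) {
    ci <- suppressMessages(
      bootstrap_ci(labels, scores, f, n_boot = n_boot, level = level,
                   seed = derive_seed(seed, match(nm, names(metric_fns)))))
    tibble::tibble(metric = nm, estimate = pt[[nm]],
                   lower = ci[["lower"]], upper = ci[["upper"]])
  })
  extra <- tibble::tibble(metric = c("ppv", "npv"),
                          estimate = c(pt$ppv, pt$npv),
                          lower = NA_real_, upper = NA_real_)
  out <- dplyr::bind_rows(dplyr::bind_rows(rows), extra)
  attr(out, "threshold") <- threshold
  attr(out, "n_boot") <- n_boot
  class(out) <- c("eval_report", class(out))
  out
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Evaluation report (threshold = %.4g, %d bootstrap resamples)\n",
              attr(x, "threshold"), attr(x, "n_boot")))
  cat("Paired comparisons, when reported, are one-sided: p is the fraction of\n")
  cat("shared resamples on which the candidate fails to beat the comparator.\n")
  NextMethod()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.eval_report <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @exportS3Method generics::glance
glance.eval_report <- function(x, ...) {
  est <- stats::setNames(x$estimate, x$metric)
  tibble::tibble(auroc = est[["auroc"]], auprc = est[["auprc"]],
                 sensitivity = est[["sensitivity"]],
                 specificity = est[["specificity"]],
                 threshold = attr(x, "threshold"),
                 n_boot = attr(x, "n_boot"))
}

#' @exportS3Method generics::tidy
tidy.mlp_fit <- function(x, ...) {
  tibble::as_tibble(as.data.frame(x$history))
}

#' @exportS3Method generics::glance
glance.mlp_fit <- function(x, ...) {
  h <- x$history
  tibble::tibble(method = x$config$method,
                 n_epochs = nrow(h),
                 final_ce = h$ce[nrow(h)],
                 final_ncr = h$ncr[nrow(h)],
                 final_val_auroc = h$val_auroc[nrow(h)])
}
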