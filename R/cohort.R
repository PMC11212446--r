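#' Specify a synthetic EHR-like cohort
#'
#' Defines the generating distribution for a synthetic tabular cohort that
#' emulates the statistical shape of emergency-department presentation data:
#' continuous laboratory/vital-sign features, strong class imbalance, missing
#' values, and (after [inject_label_noise()]) class-conditional label noise.
#'
#' Each class is an equicorrelated multivariate normal. Feature `j` of sample
#' `i` is \eqn{x_{ij} = \mu_c + \sqrt{\rho} f_i + \sqrt{1-\rho} e_{ij}} with a
#' per-sample shared factor \eqn{f_i \sim N(0,1)} and independent
#' \eqn{e_{ij} \sim N(0,1)}, so every feature has unit variance and every
#' feature pair has correlation \eqn{\rho}. The positive class mean is shifted
#' by `separation` standard deviations in every feature. This family has a
#' closed-form Bayes discriminant (see [bayes_discriminant()]), which makes
#' oracle checks of downstream classifiers possible.
#'
#' @param n_samples Number of presentations (rows).
#' @param n_features Number of continuous features.
#' @param prevalence Fraction of positives, in (0, 1). The realized count is
#'   `round(prevalence * n_samples)` (round-half-to-even) and must be >= 1.
#' @param separation Mean shift of the positive class, in units of the
#'   feature standard deviation; non-negative.
#' @param correlation Shared-factor correlation among features, in [0, 1).
#' @param missing_rate Probability that any individual feature entry is
#'   missing (completely at random), in [0, 1).
#' @param seed Integer seed; generation is fully reproducible.
#' @return A `cohort_spec` list.
#' @seealso [generate_cohort()], [bayes_auroc()]
#' @export
cohort_spec <- function(n_samples = 6000, n_features = 20, prevalence = 0.05,
                        separation = 1.0, correlation = 0.3,
                        missing_rate = 0.15, seed = 1) {
  n_samples <- check_count(n_samples, "n_samples")
  n_features <- check_count(n_features, "n_features")
  check_fraction(prevalence, "prevalence", lo_open = TRUE, hi_open = TRUE)
  if (!is.numeric(separation) || length(separation) != 1L || separation < 0) {
    abort("`separation` must be a single non-negative number.")
  }
  check_fraction(correlation, "correlation", hi_open = TRUE)
  check_fraction(missing_rate, "missing_rate", hi_open = TRUE)
  if (round(prevalence * n_samples) < 1) {
    abort("`prevalence` * `n_samples` must round to at least one positive.")
  }
  structure(list(n_samples = n_samples, n_features = n_features,
                 prevalence = prevalence, separation = separation,
                 correlation = correlation, missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic labeled cohort
#'
#' Draws a cohort from the class-conditional Gaussian model in [cohort_spec()].
#' The returned tibble has one presentation per row: feature columns
#' `f01 ... f<d>`, the (initially clean) `label`, the generator-known
#' `clean_label`, and `noise_flag` (all zero until [inject_label_noise()]).
#'
#' @param spec A [cohort_spec()].
#' @return A tibble with `n_samples` rows; exactly
#'   `round(prevalence * n_samples)` positives.
#' @examples
#' tab <- generate_cohort(cohort_spec(n_samples = 200, prevalence = 0.1,
#'                                    missing_rate = 0, seed = 7))
#' sum(tab$clean_label)  # 20 positives
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_samples
  d <- spec$n_features
  n_pos <- as.integer(round(spec$prevalence * n))
  with_seed(spec$seed, function() {
    y <- c(rep(1L, n_pos), rep(0L, n - n_pos))
    y <- y[sample.int(n)]
    f <- rnorm(n)
    e <- matrix(rnorm(n * d), n, d)
    x <- sqrt(spec$correlation) * f + sqrt(1 - spec$correlation) * e
    x <- x + spec$separation * y
    if (spec$missing_rate > 0) {
      x[runif(n * d) < spec$missing_rate] <- NA_real_
    }
    colnames(x) <- sprintf("f%02d", seq_len(d))
    out <- tibble::as_tibble(x)
    out$label <- y
    out$clean_label <- y
    out$noise_flag <- 0L
    out
  })
}

#' Bayes discriminant scores for a synthetic cohort
#'
#' For the equicorrelated Gaussian generator the two classes share covariance
#' \eqn{\Sigma = (1-\rho) I + \rho J} and differ by a constant mean shift
#' \eqn{\delta} in every feature, so the Bayes (LDA) direction
#' \eqn{\Sigma^{-1}\delta\mathbf{1}} is proportional to the feature sum. The
#' returned score is the linear discriminant
#' \eqn{\delta\, \mathbf{1}^\top x / (1-\rho+\rho d)}; any strictly monotone
#' transform of it has the same ROC curve.
#'
#' @param table A labeled cohort tibble with complete features (generate with
#'   `missing_rate = 0`, or impute first).
#' @param spec The [cohort_spec()] the table was drawn from.
#' @return Numeric score vector, higher = more case-like.
#' @export
bayes_discriminant <- function(table, spec) {
  x <- feature_matrix(table)
  if (anyNA(x)) abort("Bayes discriminant requires complete features.")
  d <- spec$n_features
  drop(x %*% rep(spec$separation / (1 - spec$correlation + spec$correlation * d), d))
}

#' Closed-form Bayes AUROC of the synthetic generator
#'
#' The Mahalanobis distance between the class means is
#' \eqn{\Delta^2 = \delta^2 d / (1 - \rho + \rho d)} and the optimal AUROC is
#' \eqn{\Phi(\Delta/\sqrt{2})} — the ceiling any classifier can reach on data
#' from this generator.
#'
#' @param spec A [cohort_spec()].
#' @return AUROC of the Bayes classifier, in [0.5, 1).
#' @export
bayes_auroc <- function(spec) {
  d <- spec$n_features
  delta2 <- spec$separation^2 * d / (1 - spec$correlation + spec$correlation * d)
  pnorm(sqrt(delta2) / sqrt(2))
}

#' Specify class-conditional label noise
#'
#' Asymmetric, class-conditional corruption: a fraction `fn_rate` of true
#' positives is flipped to negative (false negatives, mimicking imperfect
#' test sensitivity) and a fraction `fp_rate` of true negatives is flipped to
#' positive (false positives, mimicking imperfect specificity).
#'
#' @param fn_rate Fraction of positives flipped to 0, in [0, 1].
#' @param fp_rate Fraction of negatives flipped to 1, in [0, 1].
#' @param seed Integer seed for the uniform choice of flipped rows.
#' @return A `noise_spec` list.
#' @export
noise_spec <- function(fn_rate = 0, fp_rate = 0, seed = 1) {
  check_fraction(fn_rate, "fn_rate")
  check_fraction(fp_rate, "fp_rate")
  structure(list(fn_rate = fn_rate, fp_rate = fp_rate, seed = as.integer(seed)),
            class = "noise_spec")
}

#' Inject class-conditional label noise
#'
#' Flips exactly `round(fn_rate * #positives)` clean positives to 0 and
#' `round(fp_rate * #negatives)` clean negatives to 1 (round-half-to-even),
#' each chosen uniformly at random under the noise seed. Flips are always
#' computed from `clean_label`, so re-applying any noise spec to an
#' already-corrupted table replaces the previous corruption rather than
#' compounding it, and applying the same spec twice is idempotent. Features
#' are never touched.
#'
#' @param table A labeled cohort tibble carrying `clean_label`.
#' @param noise A [noise_spec()].
#' @return The table with updated `label` and `noise_flag`
#'   (`noise_flag[i] = 1` iff `label[i] != clean_label[i]`).
#' @export
inject_label_noise <- function(table, noise) {
  stopifnot(inherits(noise, "noise_spec"))
  clean <- check_binary(table$clean_label, "clean_label")
  check_binary(table$label, "label")
  pos <- which(clean == 1L)
  neg <- which(clean == 0L)
  n_fn <- as.integer(round(noise$fn_rate * length(pos)))
  n_fp <- as.integer(round(noise$fp_rate * length(neg)))
  labels <- clean
  with_seed(noise$seed, function() {
    if (n_fn > 0) labels[sample(pos, n_fn)] <<- 0L
    if (n_fp > 0) labels[sample(neg, n_fp)] <<- 1L
  })
  table$label <- labels
  table$noise_flag <- as.integer(labels != clean)
  table
}

#' Split a cohort into train/validation/test
#'
#' Random row-disjoint partition. The validation and test sizes are
#' `round(fraction * n)`; the remainder goes to the training split (the
#' largest split absorbs rounding).
#'
#' @param table A labeled cohort tibble.
#' @param fractions Length-3 numeric `(train, val, test)`, positive, summing
#'   to 1 within 1e-9.
#' @param seed Integer seed for the row permutation.
#' @return Named list of tibbles: `train`, `val`, `test`.
#' @export
split_cohort <- function(table, fractions = c(0.6, 0.2, 0.2), seed = 1) {
  if (length(fractions) != 3L || any(fractions <= 0)) {
    abort("`fractions` must be three positive numbers (train, val, test).")
  }
  if (abs(sum(fractions) - 1) > 1e-9) {
    abort("`fractions` must sum to 1 (within 1e-9).")
  }
  n <- nrow(table)
  n_val <- as.integer(round(fractions[2] * n))
  n_test <- as.integer(round(fractions[3] * n))
  n_train <- n - n_val - n_test
  perm <- with_seed(seed, function() sample.int(n))
  list(train = table[sort(perm[seq_len(n_train)]), , drop = FALSE],
       val   = table[sort(perm[n_train + seq_len(n_val)]), , drop = FALSE],
       test  = table[sort(perm[n_train + n_val + seq_len(n_test)]), , drop = FALSE])
}

#' Read / write labeled cohort tables as CSV
#'
#' Plain CSV with a header row, one row per presentation; missing feature
#' values are encoded as empty fields. `label` is required; `clean_label`
#' and `noise_flag` are kept when present.
#'
#' @param table A labeled cohort tibble.
#' @param path File path.
#' @return `read_cohort()` returns a tibble; `write_cohort()` returns the
#'   input invisibly.
#' @export
write_cohort <- function(table, path) {
  readr::write_csv(table, path, na = "")
  invisible(table)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  out <- readr::read_csv(path, na = "", show_col_types = FALSE,
                         progress = FALSE)
  if (!"label" %in% names(out)) abort("cohort CSV must have a `label` column")
  for (col in intersect(c("label", "clean_label", "noise_flag"), names(out))) {
    out[[col]] <- as.integer(out[[col]])
  }
  out
}
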