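test_that("AUROC equals exhaustive pair enumeration, including ties", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(6:50, 1)
    y <- c(1, 0, sample(0:1, n - 2, replace = TRUE))
    s <- round(runif(n), 2)  # rounding forces ties
    expect_equal(auroc(y, s), pairwise_auroc(y, s), tolerance = 1e-12)
  }
  expect_equal(auroc(c(1, 1, 0, 0), c(5, 5, 5, 5)), 0.5)
  expect_equal(auroc(c(1, 0), c(2, 1)), 1)
  expect_error(auroc(c(1, 1), c(0.2, 0.3)), "single class")
})

test_that("AUPRC step integration matches perfect and degenerate orderings", {
  expect_equal(auprc(c(1, 1, 0, 0), c(4, 3, 2, 1)), 1)
  # all scores tied: single PR point at (recall 1, precision = prevalence)
  expect_equal(auprc(c(1, 0, 0, 0), rep(1, 4)), 0.25)
  # worst ordering of 1 positive among 4: precision 1/4 reached at recall 1
  expect_equal(auprc(c(0, 0, 0, 1), c(4, 3, 2, 1)), 0.25)
})

test_that("confusion-matrix metrics are integer-consistent at the threshold", {
  y <- c(1, 1, 0, 0)
  m <- compute_metrics(y, c(0.9, 0.4, 0.3, 0.1), threshold = 0.5)
  expect_equal(m$sensitivity, 0.5)
  expect_equal(m$specificity, 1)
  expect_equal(m$ppv, 1)
  expect_equal(m$npv, 2 / 3)
  set.seed(7)
  y2 <- sample(0:1, 40, replace = TRUE)
  s2 <- runif(40)
  m2 <- compute_metrics(y2, s2, 0.6)
  expect_equal(m2$sensitivity * sum(y2 == 1), m2$tp)
  expect_equal(m2$specificity * sum(y2 == 0), m2$tn)
})

test_that("threshold tuning returns the most specific admissible operating point", {
  y <- c(1, 1, 1, 1, 0)
  s <- c(0.9, 0.8, 0.7, 0.2, 0.1)
  thr <- tune_threshold(y, s, target_sensitivity = 0.85)
  expect_lte(thr, 0.2)
  expect_equal(sum(s >= thr & y == 1) / 4, 1)  # achieved sensitivity
  # with a laxer target the tuned threshold becomes more specific
  thr75 <- tune_threshold(y, s, target_sensitivity = 0.75)
  expect_gt(thr75, 0.2)
  expect_equal(sum(s >= thr75 & y == 1) / 4, 0.75)
  # degenerate target 0: nothing needs to be caught
  thr0 <- tune_threshold(y, s, target_sensitivity = 0)
  expect_gt(thr0, max(s))
  # scores identical to labels separate perfectly
  thr_perfect <- tune_threshold(c(1, 0, 1), c(1, 0, 1), 0.85)
  expect_equal(sum(c(1, 0, 1) >= thr_perfect & c(1, 0, 1) == 1) / 2, 1)
})

test_that("percentile bootstrap matches an independent recomputation on shared resamples", {
  skip_if_not_installed("pROC")
  set.seed(12)
  y <- c(rep(1, 12), rep(0, 28))
  s <- runif(40) + 0.5 * y
  ci <- bootstrap_ci(y, s, "auroc", n_boot = 200, seed = 4, keep_draws = TRUE)
  idx <- attr(ci, "indices")
  oracle <- apply(idx, 2, function(i) {
    as.numeric(pROC::auc(pROC::roc(y[i], s[i], quiet = TRUE,
                                   direction = "<")))
  })
  expect_equal(attr(ci, "draws"), oracle, tolerance = 1e-12)
  expect_equal(unname(ci["lower"]),
               unname(quantile(oracle, 0.025, names = FALSE)),
               tolerance = 1e-12)
  expect_equal(unname(ci["upper"]),
               unname(quantile(oracle, 0.975, names = FALSE)),
               tolerance = 1e-12)
  expect_true(ci["lower"] >= 0 && ci["upper"] <= 1)
})

test_that("bootstrap CI degenerates to zero width for a constant metric", {
  y <- rep(c(1, 0), 10)
  s <- y  # every resample with both classes has AUROC exactly 1
  ci <- bootstrap_ci(y, s, "auroc", n_boot = 100, seed = 3)
  expect_equal(unname(ci["lower"]), 1)
  expect_equal(unname(ci["upper"]), 1)
})

test_that("paired bootstrap counts ties as half and dominance as zero", {
  set.seed(5)
  y <- rep(c(1, 0), 15)
  s <- runif(30)
  expect_equal(paired_bootstrap_pvalue(y, s, s, n_boot = 100, seed = 7), 0.5)
  # candidate scores the labels themselves: AUROC 1 on every resample
  sB <- 0.5 + 0.1 * (runif(30) - 0.5)  # near-random comparator
  p <- paired_bootstrap_pvalue(y, as.numeric(y), sB, n_boot = 100, seed = 7)
  expect_equal(p, 0)
  expect_error(paired_bootstrap_pvalue(y, s[-1], s, n_boot = 10), "length")
})

test_that("paired bootstrap equals a shared-index brute-force recomputation", {
  set.seed(8)
  y <- rep(c(1, 0), 10)
  sA <- runif(20) + 0.3 * y
  sB <- runif(20) + 0.2 * y
  ciA <- bootstrap_ci(y, sA, "auroc", n_boot = 150, seed = 9,
                      keep_draws = TRUE)
  idx <- attr(ciA, "indices")
  wins <- apply(idx, 2, function(i) {
    ma <- pairwise_auroc(y[i], sA[i])
    mb <- pairwise_auroc(y[i], sB[i])
    if (ma < mb) 1 else if (ma == mb) 0.5 else 0
  })
  expect_equal(paired_bootstrap_pvalue(y, sA, sB, n_boot = 150, seed = 9),
               mean(wins), tolerance = 1e-12)
})

test_that("evaluation report satisfies its interval and range invariants", {
  set.seed(21)
  y <- rep(c(1, 0, 0, 0), 15)
  s <- runif(60) + 0.6 * y
  rep_ <- evaluate_scores(y, s, threshold = 0.5, n_boot = 100, seed = 2)
  booted <- rep_[rep_$metric %in% c("auroc", "auprc", "sensitivity",
                                    "specificity"), ]
  expect_true(all(booted$lower <= booted$estimate + 1e-12))
  expect_true(all(booted$upper >= booted$estimate - 1e-12))
  expect_true(all(booted$lower >= 0 & booted$upper <= 1))
  g <- glance(rep_)
  expect_equal(g$threshold, 0.5)
  expect_equal(g$auroc, auroc(y, s))
  expect_s3_class(tidy(rep_), "tbl_df")
})
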