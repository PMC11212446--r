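test_that("generated cohorts have the exact prescribed class balance", {
  tab <- generate_cohort(cohort_spec(n_samples = 1000, prevalence = 0.05,
                                     missing_rate = 0, seed = 3))
  expect_equal(sum(tab$clean_label), 50)
  expect_equal(tab$label, tab$clean_label)
  expect_true(all(tab$noise_flag == 0L))
  expect_equal(nrow(tab), 1000)
  expect_length(feature_cols(tab), 20)
})

test_that("missing_rate = 0 yields complete features; positive rates yield misses", {
  spec0 <- cohort_spec(n_samples = 500, missing_rate = 0, seed = 1)
  expect_false(anyNA(feature_matrix(generate_cohort(spec0))))
  spec1 <- cohort_spec(n_samples = 500, missing_rate = 0.2, seed = 1)
  x <- feature_matrix(generate_cohort(spec1))
  expect_gt(mean(is.na(x)), 0.15)
  expect_lt(mean(is.na(x)), 0.25)
})

test_that("generation is reproducible and spec validation names the field", {
  s <- cohort_spec(n_samples = 200, seed = 11)
  expect_identical(generate_cohort(s), generate_cohort(s))
  expect_error(cohort_spec(prevalence = 0), "prevalence")
  expect_error(cohort_spec(correlation = 1), "correlation")
  expect_error(cohort_spec(missing_rate = 1.2), "missing_rate")
  expect_error(cohort_spec(separation = -1), "separation")
  expect_error(cohort_spec(n_samples = 10, prevalence = 0.01), "prevalence")
})

test_that("separation 0 gives chance-level discrimination; the closed-form Bayes AUROC matches Monte Carlo", {
  null_spec <- cohort_spec(n_samples = 10000, separation = 0,
                           missing_rate = 0, prevalence = 0.3, seed = 21)
  tab <- generate_cohort(null_spec)
  # the discriminant direction for any separated spec is the feature sum;
  # on separation-0 data it must score at chance
  scores <- rowSums(feature_matrix(tab))
  expect_equal(auroc(tab$clean_label, scores), 0.5, tolerance = 0.03 / 0.5)
  # and on separated data the Bayes discriminant attains the closed form
  sep_spec <- cohort_spec(n_samples = 10000, separation = 1, correlation = 0.3,
                          missing_rate = 0, prevalence = 0.3, seed = 22)
  tab2 <- generate_cohort(sep_spec)
  mc <- auroc(tab2$clean_label, bayes_discriminant(tab2, sep_spec))
  expect_equal(mc, bayes_auroc(sep_spec), tolerance = 0.03 / mc)
})

test_that("noise injection flips the exact per-class counts and nothing else", {
  tab <- generate_cohort(cohort_spec(n_samples = 10000, prevalence = 0.1,
                                     missing_rate = 0, seed = 5))
  stopifnot(sum(tab$clean_label) == 1000)
  noisy <- inject_label_noise(tab, noise_spec(fn_rate = 0.10, fp_rate = 0.005,
                                              seed = 7))
  expect_equal(sum(noisy$clean_label == 1 & noisy$label == 0), 100)
  expect_equal(sum(noisy$clean_label == 0 & noisy$label == 1), 45)
  expect_equal(sum(noisy$noise_flag), 145)
  expect_identical(noisy$noise_flag,
                   as.integer(noisy$label != noisy$clean_label))
  expect_identical(feature_matrix(noisy), feature_matrix(tab))
  expect_identical(noisy$clean_label, tab$clean_label)
})

test_that("noise injection edge rates and idempotence behave as specified", {
  tab <- generate_cohort(cohort_spec(n_samples = 400, prevalence = 0.25,
                                     missing_rate = 0, seed = 2))
  clean <- inject_label_noise(tab, noise_spec(0, 0, seed = 1))
  expect_identical(clean$label, clean$clean_label)
  all_fn <- inject_label_noise(tab, noise_spec(fn_rate = 1, seed = 1))
  expect_equal(sum(all_fn$label[all_fn$clean_label == 1]), 0)
  ns <- noise_spec(0.3, 0.01, seed = 13)
  once <- inject_label_noise(tab, ns)
  twice <- inject_label_noise(once, ns)
  expect_identical(once, twice)
  # re-corruption replaces rather than compounds
  expect_error(inject_label_noise(dplyr::mutate(tab, label = label + 2),
                                  noise_spec(0.1, 0)), "binary")
})

test_that("splits are sized by the round rule, disjoint, exhaustive and reproducible", {
  tab <- generate_cohort(cohort_spec(n_samples = 1000, missing_rate = 0,
                                     seed = 4))
  sp <- split_cohort(tab, c(0.6, 0.2, 0.2), seed = 9)
  expect_equal(vapply(sp, nrow, integer(1)),
               c(train = 600L, val = 200L, test = 200L))
  key <- function(t) paste(t$f01, t$f02, t$label)
  all_rows <- c(key(sp$train), key(sp$val), key(sp$test))
  expect_setequal(all_rows, key(tab))
  expect_equal(anyDuplicated(all_rows), 0)
  expect_identical(sp, split_cohort(tab, c(0.6, 0.2, 0.2), seed = 9))
  # remainder rows absorbed by train
  sp2 <- split_cohort(tab[1:7, ], c(1 / 3, 1 / 3, 1 / 3), seed = 1)
  expect_equal(vapply(sp2, nrow, integer(1)),
               c(train = 3L, val = 2L, test = 2L))
  expect_error(split_cohort(tab, c(0.5, 0.2, 0.2)), "sum to 1")
})

test_that("cohort CSV round-trips with empty-field missing encoding", {
  tab <- generate_cohort(cohort_spec(n_samples = 60, n_features = 4,
                                     prevalence = 0.2, missing_rate = 0.3,
                                     seed = 8))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(tab, path)
  raw <- readLines(path)
  expect_match(raw[1], "^f01,f02,f03,f04,label,clean_label,noise_flag$")
  expect_true(any(grepl(",,", raw[-1])))  # missing values as empty fields
  back <- read_cohort(path)
  expect_equal(as.data.frame(back), as.data.frame(tab), tolerance = 1e-12)
})
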