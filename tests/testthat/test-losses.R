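test_that("label smoothing redistributes exactly epsilon of target mass", {
  expect_equal(smooth_labels(c(0L, 1L), smoothing_spec(epsilon = 0)),
               rbind(c(1, 0), c(0, 1)))
  expect_equal(smooth_labels(1L, smoothing_spec(epsilon = 0.2)),
               matrix(c(0.2, 0.8), 1))
  s5 <- smooth_labels(0L, smoothing_spec(epsilon = 0.2, n_classes = 5))
  expect_equal(drop(s5), c(0.8, 0.05, 0.05, 0.05, 0.05))
  expect_error(smoothing_spec(epsilon = 1), "epsilon")
  expect_error(smooth_labels(2L, smoothing_spec()), "labels")
})

test_that("smoothed targets are valid distributions for any epsilon and C", {
  for (eps in c(0, 0.1, 0.5, 0.99)) {
    for (C in c(2L, 3L, 7L)) {
      tg <- smooth_labels(sample(0:(C - 1L), 20, replace = TRUE),
                          smoothing_spec(epsilon = eps, n_classes = C))
      expect_true(all(tg >= 0))
      expect_equal(rowSums(tg), rep(1, 20))
    }
  }
})

test_that("mix-up produces convex combinations against a permuted batch", {
  set.seed(3)
  X <- matrix(rnorm(40), 10, 4)
  y <- runif(10)
  out <- mixup_batch(X, y, mixup_spec(alpha = 0.4, p_apply = 1, seed = 5))
  expect_true(out$mixed)
  lam <- out$lambda
  expect_true(lam >= 0 && lam <= 1)
  # recover the permutation row by row and check features and targets agree
  for (i in 1:10) {
    resid <- sweep(-(1 - lam) * X, 2, out$X[i, ] - lam * X[i, ], `+`)
    j <- which(rowSums(abs(resid)) < 1e-10)
    expect_length(j, 1)
    expect_equal(out$Y[i], lam * y[i] + (1 - lam) * y[j])
    expect_true(all(out$X[i, ] >= pmin(X[i, ], X[j, ]) - 1e-12))
    expect_true(all(out$X[i, ] <= pmax(X[i, ], X[j, ]) + 1e-12))
  }
})

test_that("mix-up respects p_apply and degenerate batches", {
  X <- matrix(1:4, 2, 2)
  off <- mixup_batch(X, c(0, 1), mixup_spec(p_apply = 0, seed = 1))
  expect_false(off$mixed)
  expect_identical(off$X, X)
  expect_equal(off$lambda, 1)
  expect_warning(one <- mixup_batch(X[1, , drop = FALSE], 1,
                                    mixup_spec(p_apply = 1, seed = 1)),
                 "fewer than 2")
  expect_false(one$mixed)
  expect_error(mixup_spec(alpha = 0), "alpha")
})

test_that("cosine similarity matches direct evaluation and handles zero rows", {
  v <- rbind(c(1, 0), c(1, 1), c(2, 0), c(0, 0))
  S <- cosine_similarity_matrix(v)
  expect_equal(S[1, 2], 0.7071068, tolerance = 1e-6)
  expect_equal(S[1, 3], 1)
  expect_equal(S[2, 1], S[1, 2])
  expect_equal(S[4, ], rep(0, 4))
  expect_equal(cosine_similarity_matrix(rbind(c(1, 0), c(0, 2)))[1, 2], 0)
})

test_that("NCR loss equals the brute-force formulation on random batches", {
  for (div in c("kl", "js", "mae")) {
    for (rep in 1:10) {
      b <- random_batch(m = sample(4:12, 1), d = sample(2:6, 1),
                        seed = rep * 31 + match(div, c("kl", "js", "mae")))
      k <- sample(seq_len(nrow(b$V) - 1), 1)
      spec <- ncr_spec(k = k, divergence = div)
      expect_equal(ncr_loss(b$V, b$Z, spec),
                   brute_ncr(b$V, b$Z, k, div), tolerance = 1e-6)
    }
  }
})

test_that("NCR loss identities: zero on consensus, scale invariance, batch symmetry", {
  b <- random_batch(8, 4, seed = 2)
  for (div in c("kl", "js", "mae")) {
    spec <- ncr_spec(k = 3, divergence = div)
    expect_equal(ncr_loss(b$V, rep(1.3, 8), spec), 0, tolerance = 1e-12)
    expect_gte(ncr_loss(b$V, b$Z, spec), 0)
    # cosine similarity ignores uniform rescaling of the representations
    expect_equal(ncr_loss(b$V * 37, b$Z, spec), ncr_loss(b$V, b$Z, spec),
                 tolerance = 1e-12)
  }
  # permuting rows permutes per-sample terms but not the mean
  perm <- sample(8)
  expect_equal(ncr_loss(b$V[perm, ], b$Z[perm], ncr_spec(k = 3)),
               ncr_loss(b$V, b$Z, ncr_spec(k = 3)), tolerance = 1e-12)
  expect_error(ncr_loss(b$V, b$Z, ncr_spec(k = 8)), "batch")
  # an all-zero-similarity row contributes zero
  V <- rbind(c(1, 0), c(2, 0), c(0, 0))
  l3 <- ncr_loss(V, c(0.5, -0.2, 3), ncr_spec(k = 1))
  expect_equal(l3, brute_ncr(V, c(0.5, -0.2, 3), 1, "kl"), tolerance = 1e-12)
})

test_that("NCR analytic gradients match finite differences", {
  for (div in c("kl", "js", "mae")) {
    b <- random_batch(7, 3, seed = 17 + match(div, c("kl", "js", "mae")))
    spec <- ncr_spec(k = 2, divergence = div)
    g <- ncr_loss(b$V, b$Z, spec, grad = TRUE)
    fd_z <- finite_diff(function(z) ncr_loss(b$V, z, spec), b$Z)
    expect_equal(g$dZ, fd_z, tolerance = 1e-4)
    fd_v <- finite_diff(function(v) ncr_loss(v, b$Z, spec), b$V)
    expect_equal(g$dV, fd_v, tolerance = 1e-4)
  }
})

test_that("total loss reduces to cross-entropy under warm-up or zero weight", {
  b <- random_batch(9, 4, seed = 23)
  p <- plogis(b$Z)
  t <- round(runif(9))
  ce <- -mean(t * log(p) + (1 - t) * log(1 - p))
  spec0 <- ncr_spec(k = 2, weight = 0, warmup_epochs = 0)
  expect_equal(total_loss(p, t, b$V, b$Z, epoch = 50, spec0), ce,
               tolerance = 1e-9)
  spec_w <- ncr_spec(k = 2, weight = 2, warmup_epochs = 30)
  expect_equal(total_loss(p, t, b$V, b$Z, epoch = 29, spec_w), ce,
               tolerance = 1e-9)
  expect_equal(total_loss(p, t, b$V, b$Z, epoch = 30, spec_w),
               ce + 2 * brute_ncr(b$V, b$Z, 2, "kl"), tolerance = 1e-6)
})
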