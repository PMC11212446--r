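# Independent oracles, coded straight from the definitions with plain loops.
# They deliberately share no code with the package internals.

# Neighbour-consistency loss by brute force: per-sample neighbour search,
# similarity normalization and divergence accumulation, all enumerated.
brute_ncr <- function(V, Z, k, divergence) {
  m <- nrow(V)
  p <- 1 / (1 + exp(-as.vector(Z)))
  eps <- 1e-7
  clamp <- function(x) pmin(pmax(x, eps), 1 - eps)
  total <- 0
  for (i in seq_len(m)) {
    sims <- numeric(m)
    for (j in seq_len(m)) {
      if (j == i) next
      ni <- sqrt(sum(V[i, ]^2))
      nj <- sqrt(sum(V[j, ]^2))
      sims[j] <- if (ni == 0 || nj == 0) 0 else {
        max(sum(V[i, ] * V[j, ]) / (ni * nj), 0)
      }
    }
    nn <- order(-sims, seq_len(m))[seq_len(k)]
    ssum <- sum(sims[nn])
    if (ssum == 0) next
    q <- c(0, 0)
    for (j in nn) q <- q + sims[j] / ssum * c(1 - p[j], p[j])
    pi <- c(1 - p[i], p[i])
    pc <- clamp(pi); qc <- clamp(q)
    total <- total + switch(divergence,
      kl = sum(pc * (log(pc) - log(qc))),
      js = {
        mm <- (pc + qc) / 2
        0.5 * sum(pc * log(pc / mm)) + 0.5 * sum(qc * log(qc / mm))
      },
      mae = mean(abs(pi - q)))
  }
  total / m
}

# AUROC by exhaustive enumeration of positive/negative pairs (ties = 1/2).
pairwise_auroc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  wins <- 0
  for (a in pos) for (b in neg) {
    wins <- wins + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  wins / (length(pos) * length(neg))
}

# Central finite differences of f at x (vector or matrix), step h.
finite_diff <- function(f, x, h = 1e-6) {
  g <- x
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- x[i] + h
    xm <- x; xm[i] <- x[i] - h
    g[i] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}

# Small fully observed cohort for fast model tests.
toy_cohort <- function(n = 400, separation = 2.5, prevalence = 0.3, seed = 1) {
  generate_cohort(cohort_spec(n_samples = n, n_features = 5,
                              prevalence = prevalence,
                              separation = separation, correlation = 0,
                              missing_rate = 0, seed = seed))
}

# A random post-ReLU-like representation batch and logits.
random_batch <- function(m, d, seed) {
  set.seed(seed)
  list(V = matrix(abs(rnorm(m * d)) + 0.05, m, d), Z = rnorm(m))
}
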