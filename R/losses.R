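#' Label-smoothing specification
#'
#' Replaces one-hot targets with `1 - epsilon` on the assigned class and
#' `epsilon / (C - 1)` on each other class. `mode = "fixed"` treats epsilon as
#' a tuned hyperparameter held constant through training; `mode = "resample"`
#' draws a fresh epsilon ~ U(0, 0.5) each epoch for users who want the
#' stochastic variant (capped below 0.5 so smoothing can never invert a
#' label).
#'
#' @param epsilon Smoothing mass moved off the assigned class, in [0, 1).
#' @param n_classes Number of classes C (>= 2).
#' @param mode `"fixed"` or `"resample"`.
#' @return A `smoothing_spec` list.
#' @export
smoothing_spec <- function(epsilon = 0.1, n_classes = 2,
                           mode = c("fixed", "resample")) {
  check_fraction(epsilon, "epsilon", hi_open = TRUE)
  n_classes <- check_count(n_classes, "n_classes", min = 2L)
  structure(list(epsilon = epsilon, n_classes = n_classes,
                 mode = match.arg(mode)),
            class = "smoothing_spec")
}

#' Smooth hard labels into target distributions
#'
#' @param labels Integer class labels in `0 ... C-1`.
#' @param spec A [smoothing_spec()].
#' @return Matrix of per-sample target distributions (`length(labels)` x C);
#'   each row sums to 1.
#' @examples
#' smooth_labels(c(0L, 1L), smoothing_spec(epsilon = 0.2))
#' @export
smooth_labels <- function(labels, spec) {
  stopifnot(inherits(spec, "smoothing_spec"))
  C <- spec$n_classes
  if (!all(labels %in% 0:(C - 1L))) {
    abort(sprintf("labels must lie in 0 ... %d", C - 1L))
  }
  out <- matrix(spec$epsilon / (C - 1L), nrow = length(labels), ncol = C)
  out[cbind(seq_along(labels), labels + 1L)] <- 1 - spec$epsilon
  out
}

#' Mix-up specification
#'
#' Mix-up augments a batch with convex combinations of sample pairs:
#' `x_mix = lambda * x1 + (1 - lambda) * x2` and likewise for targets, with a
#' single `lambda ~ Beta(alpha, alpha)` per batch. Each batch is mixed with
#' probability `p_apply` and otherwise passed through unchanged.
#'
#' @param alpha Beta shape parameter (> 0); small values concentrate lambda
#'   near 0/1 (mild mixing), `alpha = 1` is uniform.
#' @param p_apply Per-batch probability of applying mix-up, in [0, 1].
#' @param seed Optional integer seed; if `NULL` the current RNG stream is
#'   used (the training loop passes its own augmentation stream).
#' @return A `mixup_spec` list.
#' @export
mixup_spec <- function(alpha = 0.2, p_apply = 0.5, seed = NULL) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0) {
    abort("`alpha` must be a single positive number.")
  }
  check_fraction(p_apply, "p_apply")
  structure(list(alpha = alpha, p_apply = p_apply,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "mixup_spec")
}

#' Mix a batch by convex combination with a permuted copy of itself
#'
#' @param X Feature matrix (batch x features).
#' @param Y Targets: numeric vector in [0, 1] (soft binary targets) or a
#'   matrix of per-sample distributions.
#' @param spec A [mixup_spec()].
#' @return List with `X`, `Y`, `lambda` (the coefficient used; 1 when the
#'   batch was left unmixed) and `mixed` (logical).
#' @export
mixup_batch <- function(X, Y, spec) {
  stopifnot(inherits(spec, "mixup_spec"))
  X <- as.matrix(X)
  m <- nrow(X)
  if (m < 2L) {
    warn("mix-up skipped: batch has fewer than 2 samples")
    return(list(X = X, Y = Y, lambda = 1, mixed = FALSE))
  }
  run <- function() {
    if (runif(1) >= spec$p_apply) {
      return(list(X = X, Y = Y, lambda = 1, mixed = FALSE))
    }
    lam <- rbeta(1, spec$alpha, spec$alpha)
    perm <- sample.int(m)
    Xm <- lam * X + (1 - lam) * X[perm, , drop = FALSE]
    Ym <- if (is.matrix(Y)) {
      lam * Y + (1 - lam) * Y[perm, , drop = FALSE]
    } else {
      lam * Y + (1 - lam) * Y[perm]
    }
    list(X = Xm, Y = Ym, lambda = lam, mixed = TRUE)
  }
  if (is.null(spec$seed)) run() else with_seed(spec$seed, run)
}

#' Pairwise cosine similarity of representation rows
#'
#' `S[i, j] = v_i . v_j / (||v_i|| ||v_j||)`. A zero row has undefined cosine;
#' its similarity to everything is defined as 0. The diagonal is left at 1;
#' the NCR term zeroes self-similarity itself.
#'
#' @param V Matrix whose rows are feature representations.
#' @return Symmetric similarity matrix.
#' @export
cosine_similarity_matrix <- function(V) {
  V <- as.matrix(V)
  nrm <- sqrt(rowSums(V^2))
  Vn <- V / ifelse(nrm > 0, nrm, 1)
  S <- tcrossprod(Vn)
  if (any(nrm == 0)) {
    S[nrm == 0, ] <- 0
    S[, nrm == 0] <- 0
  }
  S
}

#' Neighbour-consistency specification
#'
#' The NCR term pushes each sample's predicted class distribution toward the
#' similarity-weighted mixture of its k nearest neighbours' predictions in a
#' hidden-layer representation space, discouraging the network from fitting
#' a label that disagrees with the sample's latent neighbourhood.
#'
#' @param k Number of nearest neighbours (>= 1; must be < batch size at use
#'   time). Around 10 works best in practice, with performance saturating
#'   beyond that.
#' @param weight Non-negative weight of the NCR term in the total objective.
#' @param warmup_epochs Number of initial epochs trained with cross-entropy
#'   only before the NCR term switches on (~30 is a good default; the early
#'   CE-only phase lets the network learn the broad class structure first).
#' @param divergence Divergence between the sample's prediction and the
#'   neighbour mixture: `"kl"` (Kullback-Leibler, as printed in the
#'   objective), `"js"` (Jensen-Shannon) or `"mae"` (mean absolute error).
#' @return An `ncr_spec` list.
#' @export
ncr_spec <- function(k = 10, weight = 1, warmup_epochs = 30,
                     divergence = c("kl", "js", "mae")) {
  k <- check_count(k, "k")
  if (!is.numeric(weight) || length(weight) != 1L || weight < 0) {
    abort("`weight` must be a single non-negative number.")
  }
  warmup_epochs <- check_count(warmup_epochs, "warmup_epochs", min = 0L)
  structure(list(k = k, weight = weight, warmup_epochs = warmup_epochs,
                 divergence = match.arg(divergence)),
            class = "ncr_spec")
}

# Probability clamp used before any log.
.ncr_eps <- 1e-7

# Divergence D(P || Q) row-wise between m x C distribution matrices, with
# analytic partials. Returns list(value = length-m, dP, dQ = m x C).
row_divergence <- function(P, Q, divergence) {
  Pc <- pmin(pmax(P, .ncr_eps), 1 - .ncr_eps)
  Qc <- pmin(pmax(Q, .ncr_eps), 1 - .ncr_eps)
  C <- ncol(P)
  switch(divergence,
    kl = {
      list(value = rowSums(Pc * (log(Pc) - log(Qc))),
           dP = log(Pc) - log(Qc) + 1,
           dQ = -Pc / Qc)
    },
    js = {
      M <- (Pc + Qc) / 2
      list(value = 0.5 * rowSums(Pc * log(Pc / M)) +
                   0.5 * rowSums(Qc * log(Qc / M)),
           dP = 0.5 * log(Pc / M),
           dQ = 0.5 * log(Qc / M))
    },
    mae = {
      list(value = rowMeans(abs(P - Q)),
           dP = sign(P - Q) / C,
           dQ = -sign(P - Q) / C)
    },
    abort(sprintf("unknown divergence '%s'", divergence))
  )
}

#' Neighbour consistency regularization loss
#'
#' For each sample i in a batch of m: zero the self-similarity, take the k
#' most similar samples by cosine similarity of the representations `V`
#' (ties broken toward the lower index), normalize their similarities to
#' weights summing to 1, form the weighted mixture of the neighbours'
#' predicted class distributions, and accumulate the divergence from sample
#' i's own predicted distribution to that mixture. The loss is the mean over
#' the batch. A sample whose neighbour similarities are all zero contributes
#' 0. Negative cosines cannot arise from post-ReLU representations but are
#' clamped to 0 defensively before normalization.
#'
#' With a single sigmoid output unit, the predicted class distribution of a
#' sample with logit z is `(1 - sigmoid(z), sigmoid(z))`.
#'
#' @param V Representation matrix (batch x rep-dim), post-ReLU.
#' @param Z Logit vector (or 1-column matrix), one per sample.
#' @param spec An [ncr_spec()]; `spec$k` must be < the batch size.
#' @param grad If `TRUE`, also return analytic gradients `dZ` (per-logit) and
#'   `dV` (per-representation-entry). Gradients flow into both the logits and
#'   the representations (through the similarity weights), so the term shapes
#'   the latent space as well as the predictions.
#' @return The scalar loss, or (with `grad = TRUE`) a list
#'   `(value, dZ, dV)`.
#' @export
ncr_loss <- function(V, Z, spec, grad = FALSE) {
  stopifnot(inherits(spec, "ncr_spec"))
  V <- as.matrix(V)
  z <- as.vector(Z)
  m <- nrow(V)
  if (length(z) != m) abort("V and Z disagree on batch size")
  if (spec$k >= m) {
    abort(sprintf("k (%d) must be smaller than the batch size (%d)", spec$k, m))
  }
  p <- plogis(z)
  P <- cbind(1 - p, p)
  S0 <- cosine_similarity_matrix(V)     # raw cosines
  S <- pmax(S0, 0)
  diag(S) <- 0
  # top-k neighbours per row, ties to the lower index
  W <- matrix(0, m, m)
  for (i in seq_len(m)) {
    nn <- order(-S[i, ], seq_len(m))[seq_len(spec$k)]
    W[i, nn] <- S[i, nn]
  }
  rs <- rowSums(W)
  active <- rs > 0
  Wn <- W
  Wn[active, ] <- Wn[active, , drop = FALSE] / rs[active]
  Wn[!active, ] <- 0
  Q <- Wn %*% P
  div <- row_divergence(P, Q, spec$divergence)
  per <- ifelse(active, div$value, 0)
  value <- sum(per) / m
  if (!grad) return(value)

  dP <- div$dP
  dQ <- div$dQ
  dP[!active, ] <- 0
  dQ[!active, ] <- 0
  dpdz <- p * (1 - p)
  # logits: direct term through sigma(z_i), neighbour term through the mixture
  dZ <- ((dP[, 2] - dP[, 1]) + drop(crossprod(Wn, dQ[, 2] - dQ[, 1]))) * dpdz / m
  # representations: through the normalized similarity weights
  G <- dQ %*% t(P)                      # dD_i / dWn[i, j]
  inner <- rowSums(Wn * G)
  A <- (G - inner) / ifelse(rs > 0, rs, 1)   # dD_i / dS[i, j] on neighbour set
  A[W == 0] <- 0                        # only selected, positive-sim pairs
  A[S0 < 0] <- 0                        # clamped cosines: zero subgradient
  Tm <- A + t(A)
  nrm <- sqrt(rowSums(V^2))
  nz <- nrm > 0
  nsafe <- ifelse(nz, nrm, 1)
  Tn <- Tm / outer(nsafe, nsafe)
  dV <- (Tn %*% V - (rowSums(Tm * S0) / nsafe^2) * V) / m
  dV[!nz, ] <- 0
  list(value = value, dZ = dZ, dV = dV)
}

# Binary cross-entropy with soft targets t in [0,1] on the positive class.
binary_cross_entropy <- function(p, targets) {
  pc <- pmin(pmax(p, .ncr_eps), 1 - .ncr_eps)
  mean(-(targets * log(pc) + (1 - targets) * log(1 - pc)))
}

#' Combined training objective: cross-entropy plus weighted NCR
#'
#' `L_total = L_CE + weight * L_NCR`, where the NCR term is exactly 0 during
#' warm-up (`epoch < warmup_epochs`; `epoch` counts completed epochs, so the
#' first epoch is 0). Cross-entropy supports soft targets produced by label
#' smoothing or mix-up.
#'
#' @param p Predicted positive-class probabilities.
#' @param targets Targets in [0, 1] (hard or soft), per sample.
#' @param V,Z Representations and logits of the batch (see [ncr_loss()]).
#' @param epoch Zero-based epoch counter.
#' @param spec An [ncr_spec()].
#' @return Scalar loss.
#' @export
total_loss <- function(p, targets, V, Z, epoch, spec) {
  ce <- binary_cross_entropy(p, targets)
  if (epoch < spec$warmup_epochs || spec$weight == 0) {
    return(ce)
  }
  ce + spec$weight * ncr_loss(V, Z, spec)
}
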