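#' Configure the fully connected baseline network
#'
#' A feed-forward network with ReLU hidden layers and a single sigmoid output
#' unit. One hidden layer's post-activation output serves as the
#' representation space for neighbour consistency (`ncr_layer`); by default
#' the last hidden layer. Weights use fan-in-scaled ("He") initialization
#' under the run seed and training uses the Adam optimizer.
#'
#' @param hidden_sizes Integer vector of hidden-layer widths.
#' @param learning_rate Adam step size.
#' @param batch_size Mini-batch size.
#' @param n_epochs Number of training epochs.
#' @param ncr_layer Index (into `hidden_sizes`) of the layer whose post-ReLU
#'   output is the NCR representation.
#' @param seed Integer seed for weight initialization.
#' @return An `mlp_config` list.
#' @export
mlp_config <- function(hidden_sizes = c(32, 32), learning_rate = 5e-3,
                       batch_size = 64, n_epochs = 60,
                       ncr_layer = length(hidden_sizes), seed = 1) {
  if (length(hidden_sizes) < 1L || any(hidden_sizes < 1)) {
    abort("`hidden_sizes` must be a vector of positive integers.")
  }
  if (learning_rate <= 0) abort("`learning_rate` must be positive.")
  batch_size <- check_count(batch_size, "batch_size")
  n_epochs <- check_count(n_epochs, "n_epochs")
  ncr_layer <- check_count(ncr_layer, "ncr_layer")
  if (ncr_layer > length(hidden_sizes)) {
    abort("`ncr_layer` must index into `hidden_sizes`.")
  }
  structure(list(hidden_sizes = as.integer(hidden_sizes),
                 learning_rate = learning_rate,
                 batch_size = batch_size, n_epochs = n_epochs,
                 ncr_layer = ncr_layer, seed = as.integer(seed)),
            class = "mlp_config")
}

#' Initialize network weights
#'
#' @param config An [mlp_config()].
#' @param n_features Input dimension.
#' @return An `mlp_model`: weight matrices `W` (one per layer plus the output
#'   unit), bias vectors `b`, and the architecture record.
#' @export
mlp_init <- function(config, n_features) {
  stopifnot(inherits(config, "mlp_config"))
  sizes <- c(n_features, config$hidden_sizes, 1L)
  with_seed(config$seed, function() {
    W <- list(); b <- list()
    for (l in seq_len(length(sizes) - 1L)) {
      fan_in <- sizes[l]
      W[[l]] <- matrix(rnorm(fan_in * sizes[l + 1L]) * sqrt(2 / fan_in),
                       fan_in, sizes[l + 1L])
      b[[l]] <- rep(0, sizes[l + 1L])
    }
    structure(list(W = W, b = b, sizes = sizes,
                   ncr_layer = config$ncr_layer),
              class = "mlp_model")
  })
}

#' Forward pass through the network
#'
#' Returns the predicted positive-class probability `p = sigmoid(z)`, the
#' logits `z`, and the post-ReLU representation `v` captured at the
#' configured NCR layer, plus the activation cache needed for
#' backpropagation.
#'
#' @param model An `mlp_model`.
#' @param features Numeric matrix (or cohort tibble, from which feature
#'   columns are taken) with no missing values, preprocessed.
#' @return List with `v`, `z`, `p` and the internal cache.
#' @export
mlp_forward <- function(model, features) {
  stopifnot(inherits(model, "mlp_model"))
  X <- if (is.data.frame(features)) feature_matrix(features) else as.matrix(features)
  if (ncol(X) != model$sizes[1L]) {
    abort(sprintf("expected %d features, got %d", model$sizes[1L], ncol(X)))
  }
  if (anyNA(X)) abort("features contain missing values; preprocess first")
  L <- length(model$W) - 1L          # hidden layers
  A <- vector("list", L + 1L)        # A[[1]] = input
  Zs <- vector("list", L)
  A[[1L]] <- X
  for (l in seq_len(L)) {
    Zl <- sweep(A[[l]] %*% model$W[[l]], 2, model$b[[l]], `+`)
    Zs[[l]] <- Zl
    A[[l + 1L]] <- pmax(Zl, 0)
  }
  z <- drop(A[[L + 1L]] %*% model$W[[L + 1L]]) + model$b[[L + 1L]]
  list(v = A[[model$ncr_layer + 1L]], z = z, p = plogis(z),
       cache = list(A = A, Zs = Zs))
}

# Backpropagate dL/dz (length m) and an optional injection dL/dV at the NCR
# layer's post-activation output; returns gradients for every W and b.
mlp_backward <- function(model, cache, dZout, dV = NULL) {
  L <- length(model$W) - 1L
  A <- cache$A
  Zs <- cache$Zs
  gW <- vector("list", L + 1L)
  gb <- vector("list", L + 1L)
  dzo <- matrix(dZout, ncol = 1L)
  gW[[L + 1L]] <- crossprod(A[[L + 1L]], dzo)
  gb[[L + 1L]] <- sum(dzo)
  dA <- dzo %*% t(model$W[[L + 1L]])
  for (l in rev(seq_len(L))) {
    if (!is.null(dV) && l == model$ncr_layer) dA <- dA + dV
    dZl <- dA * (Zs[[l]] > 0)
    gW[[l]] <- crossprod(A[[l]], dZl)
    gb[[l]] <- colSums(dZl)
    if (l > 1L) dA <- dZl %*% t(model$W[[l]])
  }
  list(W = gW, b = gb)
}

# Adam optimizer state and update (beta1 = 0.9, beta2 = 0.999, eps = 1e-8).
adam_init <- function(model) {
  list(t = 0L,
       mW = lapply(model$W, function(w) w * 0), vW = lapply(model$W, function(w) w * 0),
       mb = lapply(model$b, function(b) b * 0), vb = lapply(model$b, function(b) b * 0))
}

adam_step <- function(model, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (l in seq_along(model$W)) {
    state$mW[[l]] <- beta1 * state$mW[[l]] + (1 - beta1) * grads$W[[l]]
    state$vW[[l]] <- beta2 * state$vW[[l]] + (1 - beta2) * grads$W[[l]]^2
    model$W[[l]] <- model$W[[l]] -
      lr * (state$mW[[l]] / c1) / (sqrt(state$vW[[l]] / c2) + eps)
    state$mb[[l]] <- beta1 * state$mb[[l]] + (1 - beta1) * grads$b[[l]]
    state$vb[[l]] <- beta2 * state$vb[[l]] + (1 - beta2) * grads$b[[l]]^2
    model$b[[l]] <- model$b[[l]] -
      lr * (state$mb[[l]] / c1) / (sqrt(state$vb[[l]] / c2) + eps)
  }
  list(model = model, state = state)
}

#' Save / load a network checkpoint
#'
#' The architecture and all weights are written as plain JSON so a checkpoint
#' survives across sessions and platforms.
#'
#' @param model An `mlp_model`.
#' @param path File path.
#' @return `load_mlp()` returns the restored `mlp_model`.
#' @export
save_mlp <- function(model, path) {
  payload <- list(sizes = model$sizes, ncr_layer = model$ncr_layer,
                  W = lapply(model$W, function(w) as.vector(w)),
                  b = model$b)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = FALSE)
  invisible(model)
}

#' @rdname save_mlp
#' @export
load_mlp <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  sizes <- as.integer(payload$sizes)
  W <- lapply(seq_len(length(sizes) - 1L), function(l) {
    matrix(payload$W[[l]], sizes[l], sizes[l + 1L])
  })
  b <- lapply(payload$b, as.numeric)
  structure(list(W = W, b = b, sizes = sizes,
                 ncr_layer = as.integer(payload$ncr_layer)),
            class = "mlp_model")
}

#' Gradient-boosted tree baseline
#'
#' Thin adapter over xgboost for the tabular task: binary logistic objective,
#' single-threaded for reproducibility. Returns a probability scorer usable
#' everywhere the network is.
#'
#' @param train Preprocessed training-split cohort tibble.
#' @param params Named list of xgboost parameters; `max_depth`, `eta`,
#'   `nrounds` are the ones usually worth tuning.
#' @param seed Integer seed.
#' @return A `gbt_model`; score new data with `predict(model, newdata)`.
#' @export
train_gbt_baseline <- function(train, params = list(), seed = 1) {
  y <- check_binary(train$label, "label")
  if (length(unique(y)) < 2L) {
    abort("training labels contain a single class; cannot fit a classifier")
  }
  X <- feature_matrix(train)
  p <- utils::modifyList(list(max_depth = 4L, eta = 0.3, nrounds = 100L), params)
  nrounds <- p$nrounds
  p$nrounds <- NULL
  dtrain <- xgboost::xgb.DMatrix(X, label = y, nthread = 1L)
  booster <- with_seed(seed, function() {
    xgboost::xgb.train(params = c(list(objective = "binary:logistic",
                                       nthread = 1L, verbosity = 0L), p),
                       data = dtrain, nrounds = nrounds, verbose = 0)
  })
  structure(list(booster = booster, n_features = ncol(X)),
            class = "gbt_model")
}

#' @export
predict.gbt_model <- function(object, newdata, ...) {
  X <- if (is.data.frame(newdata)) feature_matrix(newdata) else as.matrix(newdata)
  if (ncol(X) != object$n_features) {
    abort(sprintf("expected %d features, got %d", object$n_features, ncol(X)))
  }
  predict(object$booster, xgboost::xgb.DMatrix(X, nthread = 1L))
}
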