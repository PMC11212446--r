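#' Assemble a full training configuration
#'
#' Bundles the network architecture with the noise-mitigation method and its
#' hyperparameters. Methods: `"baseline"` (plain cross-entropy),
#' `"smoothing"` (label smoothing), `"mixup"`, `"ncr"` (neighbour consistency
#' after warm-up), `"mixup+ncr"` (both).
#'
#' The run seed is split into independent streams for weight initialization,
#' epoch shuffling, and augmentation, so corruption, init and batching are
#' separately reproducible.
#'
#' @param mlp An [mlp_config()].
#' @param method One of `"baseline"`, `"smoothing"`, `"mixup"`, `"ncr"`,
#'   `"mixup+ncr"`.
#' @param smoothing A [smoothing_spec()] (used when `method = "smoothing"`).
#' @param mixup A [mixup_spec()] (used when mix-up is active).
#' @param ncr An [ncr_spec()] (used when NCR is active).
#' @param seed Run seed.
#' @param record_confidence If `TRUE`, record each training sample's
#'   predicted confidence in its assigned label at every epoch (needed for
#'   the memorization diagnostics; costs one extra forward pass per epoch).
#' @return A `train_config` list.
#' @export
train_config <- function(mlp = mlp_config(),
                         method = c("baseline", "smoothing", "mixup", "ncr",
                                    "mixup+ncr"),
                         smoothing = smoothing_spec(),
                         mixup = mixup_spec(),
                         ncr = ncr_spec(),
                         seed = 1,
                         record_confidence = FALSE) {
  method <- match.arg(method)
  stopifnot(inherits(mlp, "mlp_config"), inherits(smoothing, "smoothing_spec"),
            inherits(mixup, "mixup_spec"), inherits(ncr, "ncr_spec"))
  structure(list(mlp = mlp, method = method, smoothing = smoothing,
                 mixup = mixup, ncr = ncr, seed = as.integer(seed),
                 record_confidence = isTRUE(record_confidence)),
            class = "train_config")
}

uses_ncr <- function(config) config$method %in% c("ncr", "mixup+ncr")
uses_mixup <- function(config) config$method %in% c("mixup", "mixup+ncr")

#' Train the network on a preprocessed split
#'
#' Mini-batch Adam on the combined objective: cross-entropy (with soft
#' targets when smoothing or mix-up is active) plus, after the warm-up
#' epoch, the weighted NCR term. Both loss terms are recorded separately per
#' epoch, alongside the validation AUROC. The NCR term is skipped for a
#' trailing partial batch smaller than `k + 1`.
#'
#' @param train,val Preprocessed cohort tibbles (no missing features).
#' @param config A [train_config()].
#' @return An `mlp_fit`: the trained `mlp_model`, a `train_history` tibble
#'   (`epoch`, `ce`, `ncr`, `val_auroc`; epochs numbered from 1), and the
#'   config. When `record_confidence = TRUE` the history carries an
#'   `epoch x n_train` confidence matrix in `attr(history, "confidence")`
#'   plus the training labels and noise flags.
#' @export
train_model <- function(train, val, config) {
  stopifnot(inherits(config, "train_config"))
  mcfg <- config$mlp
  if (uses_ncr(config) && config$ncr$k >= mcfg$batch_size) {
    abort(sprintf("NCR requires k (%d) < batch_size (%d)",
                  config$ncr$k, mcfg$batch_size))
  }
  X <- feature_matrix(train)
  y <- check_binary(train$label, "label")
  Xv <- feature_matrix(val)
  yv <- check_binary(val$label, "label")
  n <- nrow(X)

  init_cfg <- mcfg
  init_cfg$seed <- derive_seed(config$seed, 1L)
  model <- mlp_init(init_cfg, ncol(X))
  opt <- adam_init(model)
  shuffle_stream <- new_rng_stream(derive_seed(config$seed, 2L))
  augment_stream <- new_rng_stream(derive_seed(config$seed, 3L))

  eps_epoch <- config$smoothing$epsilon
  hist <- vector("list", mcfg$n_epochs)
  conf <- if (config$record_confidence) {
    matrix(NA_real_, mcfg$n_epochs, n)
  }

  for (epoch in seq_len(mcfg$n_epochs)) {
    ncr_active <- uses_ncr(config) && (epoch - 1L) >= config$ncr$warmup_epochs &&
      config$ncr$weight > 0
    if (config$method == "smoothing" && config$smoothing$mode == "resample") {
      eps_epoch <- with_stream(augment_stream, function() runif(1, 0, 0.5))
    }
    perm <- with_stream(shuffle_stream, function() sample.int(n))
    ce_sum <- 0; ncr_sum <- 0
    for (start in seq(1L, n, by = mcfg$batch_size)) {
      idx <- perm[start:min(start + mcfg$batch_size - 1L, n)]
      m <- length(idx)
      Xb <- X[idx, , drop = FALSE]
      tb <- as.numeric(y[idx])
      if (config$method == "smoothing") {
        tb <- tb * (1 - eps_epoch) + (1 - tb) * eps_epoch  # C = 2
      }
      if (uses_mixup(config) && m >= 2L) {
        mixed <- with_stream(augment_stream, function() {
          mixup_batch(Xb, tb, config$mixup)
        })
        Xb <- mixed$X
        tb <- mixed$Y
      }
      fwd <- mlp_forward(model, Xb)
      ce <- binary_cross_entropy(fwd$p, tb)
      dz <- (fwd$p - tb) / m
      dV <- NULL
      ncr_val <- 0
      if (ncr_active && m > config$ncr$k) {
        nl <- ncr_loss(fwd$v, fwd$z, config$ncr, grad = TRUE)
        ncr_val <- nl$value
        dz <- dz + config$ncr$weight * nl$dZ
        dV <- config$ncr$weight * nl$dV
      }
      if (!is.finite(ce) || !is.finite(ncr_val) || !all(is.finite(fwd$z))) {
        abort(sprintf(
          "training diverged at epoch %d (CE = %g, NCR = %g); lower the learning rate",
          epoch, ce, ncr_val))
      }
      grads <- mlp_backward(model, fwd$cache, dz, dV)
      upd <- adam_step(model, grads, opt, mcfg$learning_rate)
      model <- upd$model
      opt <- upd$state
      ce_sum <- ce_sum + ce * m
      ncr_sum <- ncr_sum + ncr_val * m
    }
    p_val <- mlp_forward(model, Xv)$p
    hist[[epoch]] <- tibble::tibble(
      epoch = epoch,
      ce = ce_sum / n,
      ncr = ncr_sum / n,
      val_auroc = auroc(yv, p_val))
    if (config$record_confidence) {
      p_tr <- mlp_forward(model, X)$p
      conf[epoch, ] <- ifelse(y == 1L, p_tr, 1 - p_tr)
    }
  }

  history <- dplyr::bind_rows(hist)
  class(history) <- c("train_history", class(history))
  if (config$record_confidence) {
    attr(history, "confidence") <- conf
    attr(history, "labels") <- y
    attr(history, "noise_flags") <- if ("noise_flag" %in% names(train)) {
      as.integer(train$noise_flag)
    }
  }
  structure(list(model = model, history = history, config = config),
            class = "mlp_fit")
}

#' @export
predict.mlp_fit <- function(object, newdata, ...) {
  mlp_forward(object$model, newdata)$p
}

#' @export
print.mlp_fit <- function(x, ...) {
  h <- x$history
  cat(sprintf("<mlp_fit> method = %s, %d epochs, final val AUROC = %.3f\n",
              x$config$method, nrow(h), h$val_auroc[nrow(h)]))
  invisible(x)
}

#' Grid search with five-fold cross-validation
#'
#' Evaluates every row of `grid` by the mean held-fold AUROC over a k-fold
#' partition of the training split and returns the best configuration (ties
#' broken toward the earlier grid row). Grid columns override the matching
#' fields of `base_config`: `learning_rate`, `batch_size`, `n_epochs`,
#' `hidden_sizes` (list-column), `ncr_layer`, `method`, `epsilon`, `alpha`,
#' `p_apply`, `k`, `weight`, `warmup_epochs`, `divergence`.
#'
#' @param grid Data frame of candidate hyperparameter values, one row per
#'   grid point.
#' @param train Preprocessed training-split cohort tibble.
#' @param base_config A [train_config()] supplying every field the grid does
#'   not vary.
#' @param k_folds Number of folds (default 5).
#' @param seed Seed for the fold partition.
#' @return List: `best_config`, `best_row` (index into `grid`), and
#'   `results` (the grid with a `mean_auroc` column).
#' @export
grid_search_cv <- function(grid, train, base_config = train_config(),
                           k_folds = 5, seed = 1) {
  grid <- as.data.frame(grid)
  if (nrow(grid) == 0L) abort("`grid` must contain at least one row.")
  n <- nrow(train)
  folds <- with_seed(seed, function() sample(rep(seq_len(k_folds), length.out = n)))
  scores <- purrr::map_dbl(seq_len(nrow(grid)), function(r) {
    cfg <- apply_grid_row(base_config, grid[r, , drop = FALSE])
    mean(purrr::map_dbl(seq_len(k_folds), function(f) {
      fit <- train_model(train[folds != f, , drop = FALSE],
                         train[folds == f, , drop = FALSE], cfg)
      tail(fit$history$val_auroc, 1L)
    }))
  })
  best <- which.max(scores)   # which.max returns the first (earliest) maximum
  list(best_config = apply_grid_row(base_config, grid[best, , drop = FALSE]),
       best_row = best,
       results = tibble::as_tibble(cbind(grid, mean_auroc = scores)))
}

apply_grid_row <- function(config, row) {
  for (nm in names(row)) {
    val <- row[[nm]]
    if (is.list(val)) val <- val[[1L]]
    switch(nm,
      learning_rate = { config$mlp$learning_rate <- val },
      batch_size = { config$mlp$batch_size <- as.integer(val) },
      n_epochs = { config$mlp$n_epochs <- as.integer(val) },
      hidden_sizes = {
        config$mlp$hidden_sizes <- as.integer(val)
        config$mlp$ncr_layer <- min(config$mlp$ncr_layer, length(val))
      },
      ncr_layer = { config$mlp$ncr_layer <- as.integer(val) },
      method = { config$method <- val },
      epsilon = { config$smoothing$epsilon <- val },
      alpha = { config$mixup$alpha <- val },
      p_apply = { config$mixup$p_apply <- val },
      k = { config$ncr$k <- as.integer(val) },
      weight = { config$ncr$weight <- val },
      warmup_epochs = { config$ncr$warmup_epochs <- as.integer(val) },
      divergence = { config$ncr$divergence <- val },
      abort(sprintf("unknown grid column '%s'", nm))
    )
  }
  config
}
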