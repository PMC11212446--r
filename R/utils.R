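#' @importFrom rlang abort warn inform `%||%`
#' @importFrom stats median sd quantile rnorm runif rbeta plogis qnorm pnorm
#' @importFrom utils head tail
NULL

# Evaluate `fn` under a private RNG stream, leaving the caller's RNG untouched.
# Streams make weight init, batch shuffling and augmentation separately
# reproducible: each consumes its own sequence regardless of the others.
new_rng_stream <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- new.env(parent = emptyenv())
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  set.seed(as.integer(seed))
  env$state <- get(".Random.seed", envir = globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  env
}

with_stream <- function(stream, fn) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  assign(".Random.seed", stream$state, envir = globalenv())
  on.exit({
    stream$state <- get(".Random.seed", envir = globalenv())
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  fn()
}

# One-shot seeded evaluation (restores caller RNG afterwards).
with_seed <- function(seed, fn) with_stream(new_rng_stream(seed), fn)

# Derive a child seed from a base seed and integer offsets; stays < 2^31.
derive_seed <- function(seed, ...) {
  offs <- c(...)
  x <- as.double(seed) %% 2147483647
  for (o in offs) x <- (x * 7919 + as.double(o) * 104729 + 1) %% 2147483647
  as.integer(x)
}

#' Identify feature columns of a labeled cohort table
#'
#' A labeled cohort table stores one presentation per row: feature columns plus
#' the bookkeeping columns `label`, `clean_label` and `noise_flag`. Every
#' column that is not bookkeeping is treated as a feature.
#'
#' @param table A labeled cohort tibble (see [generate_cohort()]).
#' @return Character vector of feature column names, in table order.
#' @export
feature_cols <- function(table) {
  setdiff(names(table), c("label", "clean_label", "noise_flag"))
}

# Feature block of a labeled table as a numeric matrix.
feature_matrix <- function(table) {
  as.matrix(table[feature_cols(table)])
}

check_fraction <- function(x, name, lo = 0, hi = 1,
                           lo_open = FALSE, hi_open = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single number.", name))
  }
  ok <- (if (lo_open) x > lo else x >= lo) && (if (hi_open) x < hi else x <= hi)
  if (!ok) {
    abort(sprintf("`%s` must be in %s%g, %g%s (got %g).", name,
                  if (lo_open) "(" else "[", lo, hi,
                  if (hi_open) ")" else "]", x))
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != as.integer(x)) {
    abort(sprintf("`%s` must be an integer >= %d.", name, min))
  }
  invisible(as.integer(x))
}

check_binary <- function(labels, name = "labels") {
  if (!all(labels %in% c(0, 1))) {
    abort(sprintf("`%s` must be binary (0/1).", name))
  }
  invisible(as.integer(labels))
}
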