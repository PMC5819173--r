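# Internal helpers shared across modules.

# Run expr under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards so seeded generators do not perturb
# the global stream.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("seed: must be a single finite number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

stop_field <- function(field, msg) {
  stop(sprintf("%s: %s", field, msg), call. = FALSE)
}

check_fraction <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop_field(field, "must be a single number in [0, 1]")
  }
  invisible(x)
}

check_count <- function(x, field, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != round(x)) {
    stop_field(field, sprintf("must be a single integer >= %d", min))
  }
  invisible(as.integer(x))
}

check_positive <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    stop_field(field, "must be a single positive number")
  }
  invisible(x)
}

# Row means / variances without a matrixStats dependency.
row_vars <- function(x) {
  m <- rowMeans(x)
  rowSums((x - m)^2) / (ncol(x) - 1L)
}
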