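# shared argument validation helpers

stop_if_not_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("`%s` must be a single positive finite number", name),
      call. = FALSE
    )
  }
  invisible(x)
}

stop_if_not_nonnegative_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0) {
    stop(sprintf("`%s` must be a single non-negative finite number", name),
      call. = FALSE
    )
  }
  invisible(x)
}

stop_if_not_numeric <- function(x, name) {
  if (!is.numeric(x) || anyNA(x)) {
    stop(sprintf("`%s` must be numeric with no missing values", name),
      call. = FALSE
    )
  }
  invisible(x)
}

# evaluate expr with the RNG seeded from `seed`, restoring the caller's
# RNG state afterwards so generation never perturbs a user's session
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
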