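# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed` and restores the prior
#' RNG state afterwards, so seeded package functions never clobber the
#' caller's random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @noRd
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a stream-specific child seed from a run seed; kept below 2^31.
child_seed <- function(seed, stream) {
  (as.double(seed) * 48271 + stream * 1013) %% 2147483647
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_binary_labels <- function(labels, what = "labels") {
  if (length(labels) == 0 || !all(labels %in% c(0, 1))) {
    stop(sprintf("`%s` must be a non-empty vector of 0/1 values", what),
         call. = FALSE)
  }
  invisible(TRUE)
}
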