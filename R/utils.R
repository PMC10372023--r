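#' @keywords internal
"_PACKAGE"

# Run `expr` under a local RNG seeded with `seed`, restoring the caller's
# RNG state afterwards. All stochastic functions in the package route their
# randomness through this so no call disturbs the global stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

stop_ftgr <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "ftgr_error")))
}

warn_ftgr <- function(..., class) {
  warning(warningCondition(paste0(...), class = c(class, "ftgr_warning")))
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)
}

# Near-equality for grid arithmetic on integer-valued doubles.
near <- function(x, y, tol = 1e-8) abs(x - y) < tol
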