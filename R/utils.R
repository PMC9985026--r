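# internal helpers shared across the package

# Run `expr` with the RNG seeded to `seed`, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

# Indices of strict interior local maxima of x.
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  which(x[2:(n - 1L)] > x[1:(n - 2L)] & x[2:(n - 1L)] >= x[3:n]) + 1L
}

stop_arg <- function(msg, ...) stop(sprintf(msg, ...), call. = FALSE)

assert_scalar_num <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_arg("'%s' must be a single finite number", name)
  }
  if (x < lo || x > hi) {
    stop_arg("'%s' must be in [%g, %g], got %g", name, lo, hi, x)
  }
  invisible(x)
}
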