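# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Trapezoidal integral of y sampled on a uniform grid with spacing dx.
trapz_uniform <- function(y, dx) {
  n <- length(y)
  dx * (sum(y) - (y[1L] + y[n]) / 2)
}

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("empain_config_error", "error")))
}

stop_input <- function(...) {
  stop(errorCondition(paste0(...), class = c("empain_input_error", "error")))
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}
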