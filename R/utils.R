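# internal helpers shared across the package

# classed error so callers/tests can distinguish failure modes
snet_stop <- function(msg, class, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c(class, "saltnet_error", "error", "condition")))
}

snet_warn <- function(msg, ...) {
  warning(sprintf(msg, ...), call. = FALSE)
}

# run `code` under a temporary RNG seed, restoring the caller's RNG state,
# so the generators are pure functions of their configuration
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 1 && x == floor(x)

`%||%` <- function(a, b) if (is.null(a)) b else a
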