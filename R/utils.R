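# Internal helpers shared across modules.

# Run `expr` under a local RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so generators never clobber user RNG.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
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
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Deterministic per-frame sub-seed; stays below 2^31 - 1 so it is a valid
# integer seed (inputs are expected to be small user seeds).
frame_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 1000003 + as.numeric(index)) %% 2147483647)
}

stop_config <- function(msg, class = "drapewatch_config_error") {
  stop(errorCondition(msg, class = c(class, "error", "condition")))
}

stop_input <- function(msg, class = "drapewatch_input_error") {
  stop(errorCondition(msg, class = c(class, "error", "condition")))
}

is_rgb <- function(x) {
  is.numeric(x) && length(x) == 3 && all(is.finite(x)) && all(x >= 0) && all(x <= 255)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
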