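# Internal helpers shared across modules.

# Error constructors: user-facing functions distinguish invalid inputs from
# numerical failures so callers (and the CLI) can map them to exit codes.
br_invalid <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("bayesreanal_invalid_input", "error", "condition")))
}

br_numerical <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("bayesreanal_numerical_error", "error", "condition")))
}

# round half away from zero (R's round() is round-half-even); used only at
# the reporting layer, never inside computations
round_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == round(x)
}

is_num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

`%||%` <- function(a, b) if (is.null(a)) b else a

# run code with a private, restorable RNG state so simulators are pure
# functions of their seed and never disturb the caller's stream
with_seed <- function(seed, code) {
  if (!is_count(seed)) br_invalid("seed must be a single non-negative integer")
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

rng_id <- "Mersenne-Twister/Inversion"
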