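# Internal helpers shared across modules.

# Classed condition so callers can test error categories with
# expect_error(class = "cim_error_<kind>").
cim_stop <- function(msg, class, ...) {
  stop(errorCondition(msg, ..., class = c(class, "cim_error", "error", "condition")))
}

# Round half away from zero: 77.94 -> 78, 4.41 -> 4, 17.65 -> 18, -1.5 -> -2.
# base::round() rounds half to even, which is the wrong convention here.
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# Run `expr` under a fixed RNG seed without clobbering the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) {
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
  }
  force(expr)
}

# Scalar integer check tolerant of doubles holding whole numbers.
is_whole <- function(x) {
  is.numeric(x) & is.finite(x) & x == trunc(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
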