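# Internal helpers: seeded RNG scoping, sub-seed derivation, validation.

# Evaluate `expr` under `seed` without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Deterministically fold a base seed with integer tags into a new 31-bit seed.
# Uses a multiply-accumulate in double precision (all intermediates < 2^53).
derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  acc <- 0
  for (p in parts) {
    acc <- (acc * 69069 + (as.numeric(p) %% 2147483647) + 1) %% 2147483647
  }
  as.integer(acc %% 2147483629 + 1)
}

stop_if_not <- function(cond, msg, class = "emg_error") {
  if (!isTRUE(cond)) {
    stop(errorCondition(msg, class = c(class, "error", "condition")))
  }
  invisible(TRUE)
}

is_count <- function(x) {
  length(x) == 1 && is.numeric(x) && is.finite(x) && x >= 1 && x == round(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
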