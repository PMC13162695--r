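# Internal helpers shared across modules.

# Deterministically combine integer seeds into a value < 2^31 for the C++
# RNG and for R-side set.seed(); avoids collisions between nearby streams.
mix_seed <- function(seed, ...) {
  extra <- c(...)
  x <- as.double(seed) %% 2147483647
  for (e in extra) {
    x <- (x * 69069 + as.double(e) * 2654435761 + 1013904223) %% 2147483647
  }
  as.integer(x)
}

# Evaluate expr with a local R RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not <- function(cond, msg) {
  if (!isTRUE(cond)) rlang::abort(msg)
  invisible(TRUE)
}
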