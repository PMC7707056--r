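# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the
# caller's .Random.seed is restored afterwards so library code never
# perturbs user-level randomness.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Deterministic derived seed streams (keeps every stage independently
# reproducible from one user-facing seed; stays below .Machine$integer.max).
derive_seed <- function(seed, ...) {
  if (is.null(seed)) return(NULL)
  offsets <- c(...)
  x <- as.double(seed)
  for (k in offsets) x <- (x * 69069 + as.double(k) + 1) %% 2147483647
  as.integer(x)
}

# Linear interpolation with range checking; axis assumed strictly increasing.
interp_linear <- function(axis, values, xout, what = "axis") {
  if (any(xout < axis[1L] - 1e-9) || any(xout > axis[length(axis)] + 1e-9)) {
    stop(sprintf("requested %s value outside the spectrum range [%g, %g]",
                 what, axis[1L], axis[length(axis)]), call. = FALSE)
  }
  stats::approx(axis, values, xout = xout, rule = 1)$y
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
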