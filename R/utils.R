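# Internal helpers shared across modules.

# Derive a reproducible child seed from a parent seed and a stream label.
# Keeps every stochastic stage on its own stream while staying a function of
# the single user-facing seed. Result stays below 2^31 - 1.
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  bytes <- utf8ToInt(label)
  h <- (seed %% 2147483647)
  for (b in bytes) {
    h <- (h * 31 + b) %% 2147483647
  }
  as.integer(h)
}

# Evaluate an expression under a local RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
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
  force(expr)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (strict_lower && x <= lower) {
    abort(sprintf("`%s` must be > %s.", name, format(lower)))
  }
  if (!strict_lower && x < lower) {
    abort(sprintf("`%s` must be >= %s.", name, format(lower)))
  }
  if (x > upper) {
    abort(sprintf("`%s` must be <= %s.", name, format(upper)))
  }
  invisible(x)
}

# Next power of two at or above n.
next_pow2 <- function(n) {
  stopifnot(n >= 1)
  2^ceiling(log2(n))
}
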