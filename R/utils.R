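# Internal helpers shared across modules.

# Derive a reproducible sub-seed from a master seed and a stream label.
# Streams keep the generator, fold assignment, policy randomisation and
# Monte-Carlo oracles independent so modules can be tested in isolation.
sub_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((abs(seed) * 7919 + h * 104729 + 12345) %% 2147483647L)
}

# Evaluate expr under a local RNG state seeded with `seed`; global RNG untouched.
with_seed <- function(seed, expr) {
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
  set.seed(as.integer(seed %% 2147483647))
  expr
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

logit <- function(p) log(p / (1 - p))

# Reflect a random-walk value into [lo, hi] (preserves percentile semantics).
reflect <- function(x, lo, hi) {
  span <- hi - lo
  y <- (x - lo) %% (2 * span)
  lo + ifelse(y > span, 2 * span - y, y)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg), call. = FALSE)
}

check_prob_vector <- function(p, field) {
  if (any(!is.finite(p)) || any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    stop_config(field, "entries must be non-negative, finite and sum to 1")
  }
  invisible(p)
}
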