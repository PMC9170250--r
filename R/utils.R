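# internal helpers

# Evaluate `expr` under a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
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

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# log(exp(a) + exp(b)) elementwise, stable
logaddexp <- function(a, b) {
  m <- pmax(a, b)
  # both -Inf -> -Inf without NaN
  out <- m + log1p(exp(pmin(a, b) - m))
  out[is.infinite(m) & m < 0] <- -Inf
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("`%s` must be a probability in [0, 1]", name), call. = FALSE)
}
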