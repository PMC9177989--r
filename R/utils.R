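# Internal helpers: seeded evaluation, seed derivation, numeric guards.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive named per-stage seeds from one master seed. Stages get independent
# streams so that adding a stage never perturbs the draws of another.
derive_seeds <- function(master, stages) {
  s <- with_seed(master, sample.int(.Machine$integer.max - 1L, length(stages)))
  stats::setNames(as.integer(s), stages)
}

clip01 <- function(p, eps) pmin(pmax(p, eps), 1 - eps)

assert_scalar_number <- function(x, name, positive = FALSE, integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be strictly positive", name), call. = FALSE)
  }
  if (integerish && abs(x - round(x)) > 1e-8) {
    stop(sprintf("`%s` must be an integer", name), call. = FALSE)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
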