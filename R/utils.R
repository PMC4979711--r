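# internal helpers shared across modules

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched.  seed = NULL means: use (and advance) the global RNG.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1L)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Deterministic sub-seeds derived from one master seed (kept < 2^31).
spawn_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Validation errors carry a distinct condition class per violation code so
# callers can discriminate them; all inherit "commsar_validation_error".
stop_invalid <- function(code, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c(paste0("commsar_invalid_", code),
                                "commsar_validation_error")))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

is_count <- function(x) is.numeric(x) & is.finite(x) & x >= 0 & x == round(x)

logit <- function(p) stats::qlogis(p)
inv_logit <- function(x) stats::plogis(x)
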