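# internal helpers

# Evaluate `code` under a temporary RNG state seeded with `seed`;
# the caller's .Random.seed is restored afterwards.  seed = NULL runs
# the code under the ambient RNG.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  has_seed <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         integer = FALSE, open_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x))
    abort(sprintf("`%s` must be a single finite number", name))
  if (integer && x != round(x))
    abort(sprintf("`%s` must be an integer", name))
  lo_ok <- if (open_lower) x > lower else x >= lower
  if (!lo_ok || x > upper)
    abort(sprintf("`%s` must be in [%s, %s]", name, lower, upper))
  invisible(x)
}
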