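# internal validation and RNG helpers

check_probability <- function(x, name, allow_na = FALSE) {
  if (!is.numeric(x)) abort(sprintf("`%s` must be numeric.", name))
  bad <- !is.na(x) & (x < 0 | x > 1)
  if (any(bad)) abort(sprintf("`%s` must lie in [0, 1].", name))
  if (!allow_na && anyNA(x)) abort(sprintf("`%s` must not contain NA.", name))
  invisible(x)
}

check_nonneg <- function(x, name, allow_na = FALSE) {
  if (!is.numeric(x)) abort(sprintf("`%s` must be numeric.", name))
  if (any(!is.na(x) & x < 0)) abort(sprintf("`%s` must be non-negative.", name))
  if (!allow_na && anyNA(x)) abort(sprintf("`%s` must not contain NA.", name))
  invisible(x)
}

check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || anyNA(x) || any(x != round(x)) || any(x < min)) {
    abort(sprintf("`%s` must be an integer >= %d.", name, min))
  }
  invisible(as.integer(x))
}

# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
# seed = NULL means: use the current RNG state (and advance it).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

# recycle a scalar to length n, or validate length
recycle_to <- function(x, n, name) {
  if (length(x) == 1L) return(rep(x, n))
  if (length(x) != n) abort(sprintf("`%s` must have length 1 or %d.", name, n))
  x
}
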