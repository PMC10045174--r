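#' @importFrom rlang abort warn .data %||%
#' @importFrom stats median qbeta qt pt pnorm cor sd lm coef rnorm runif
#' @importFrom utils head modifyList
NULL

# round half away from zero to `digits` decimals; base round() rounds half to
# even, which does not reproduce conventionally printed R^2 values
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# integer percent by truncation toward zero (6/11 prints as 54, not 55)
trunc_percent <- function(k, n) trunc(100 * k / n)

# deterministic 32-bit sub-seed stream: one master seed fans out to any
# number of independent child seeds without consuming the global RNG state
derive_seeds <- function(seed, n) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  sample.int(.Machine$integer.max, n)
}

with_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort(sprintf("`%s` must be a single finite number", name))
  lo_ok <- if (strict_lower) x > lower else x >= lower
  if (!lo_ok || x > upper)
    abort(sprintf("`%s` must be in %s%s, %s]", name,
                  if (strict_lower) "(" else "[", lower, upper))
  invisible(x)
}

assert_columns <- function(df, cols, name) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    abort(sprintf("`%s` is missing required column(s): %s",
                  name, paste(missing, collapse = ", ")))
  invisible(df)
}
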