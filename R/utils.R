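#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor dbinom lm pbinom qbinom rnorm runif sd var coef
#' @importFrom utils read.csv write.csv head
NULL

# Stop with the calling function's name prefixed, keeping error messages
# uniform across the package.
abort <- function(...) stop(..., call. = FALSE)

assert_that <- function(cond, ...) {
  if (!isTRUE(cond)) abort(...)
  invisible(TRUE)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Derive a per-unit sub-seed from a master seed so per-subject streams are
# stable under cohort extension.  Kept inside 32-bit integer range.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(index) * 104729) %% 2147483647)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
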