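#' @importFrom methods new is validObject slot
#' @importFrom stats median pchisq pnorm quantile runif rbinom rnorm rexp
#'   setNames coef sd cor aggregate binom.test plogis qlogis
#' @importFrom utils head read.delim write.table combn
NULL

# Round half away from zero (half-up for positive values), as used for the
# integer c-index and percentage tables.
roundHalfUp <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# ceil(fraction * total), never 0 for a positive fraction and positive total
fractionCount <- function(fraction, total) {
  stopifnot(fraction > 0, fraction <= 1)
  as.integer(ceiling(fraction * total))
}

# Derive a child seed from a parent seed and a stream label. Keeps every
# derived seed inside the 32-bit integer range.
deriveSeed <- function(seed, ...) {
  labels <- paste(c(seed, ...), collapse = "/")
  bytes <- utf8ToInt(labels)
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483629
  as.integer(h + 1L)
}

# Evaluate an expression under a local RNG state seeded with `seed`,
# restoring the caller's RNG stream afterwards.
withSeed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

assertScalarCount <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 ||
      x != floor(x)) {
    stop(sprintf("'%s' must be a single positive integer", name),
         call. = FALSE)
  }
  invisible(as.integer(x))
}

assertFraction <- function(x, name, lo = 0, hi = 1,
                           lo_open = TRUE, hi_open = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (if (lo_open) x > lo else x >= lo) &&
    (if (hi_open) x < hi else x <= hi)
  if (!ok) {
    stop(sprintf("'%s' must be a fraction in %s%g, %g%s", name,
                 if (lo_open) "(" else "[", lo, hi,
                 if (hi_open) ")" else "]"), call. = FALSE)
  }
  invisible(as.numeric(x))
}
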