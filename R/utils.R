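`%||%` <- function(a, b) if (is.null(a)) b else a

## Evaluate expr under a temporary RNG state seeded with `seed`; the caller's
## RNG stream is untouched.
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## derive a secondary integer seed, kept within 32-bit range
.sub_seed <- function(seed, offset) {
  as.integer((as.double(seed) + 1000003 * offset) %% 2147483629)
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)

.assert_fraction <- function(x, field, open0 = TRUE, open1 = TRUE) {
  lo_ok <- if (open0) x > 0 else x >= 0
  hi_ok <- if (open1) x < 1 else x <= 1
  if (length(x) != 1 || !is.finite(x) || !lo_ok || !hi_ok)
    .stopf("field '%s' must be a fraction in %s0,1%s (got %s)",
           field, if (open0) "(" else "[", if (open1) ")" else "]",
           paste(format(x), collapse = ","))
  invisible(x)
}

.assert_count <- function(x, field, min = 0L) {
  if (length(x) != 1 || !is.finite(x) || x < min || x != round(x))
    .stopf("field '%s' must be an integer >= %d (got %s)", field, min,
           paste(format(x), collapse = ","))
  invisible(as.integer(x))
}

## rows of `pos` falling inside any [start, end] interval (1-based inclusive)
.in_intervals <- function(pos, starts, ends) {
  if (length(starts) == 0L || length(pos) == 0L)
    return(logical(length(pos)))
  hits <- IRanges::findOverlaps(
    IRanges::IRanges(start = pos, width = 1L),
    IRanges::IRanges(start = as.integer(starts), end = as.integer(ends))
  )
  out <- logical(length(pos))
  out[unique(S4Vectors::queryHits(hits))] <- TRUE
  out
}
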