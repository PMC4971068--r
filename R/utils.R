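#' Round half away from zero
#'
#' Fixed-precision rounding used when serializing rates and summaries:
#' exact halves round up (0.125 -> 0.13), unlike [base::round()]'s
#' round-half-even.  Published per-100-kbp rate tables follow this
#' convention.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded to `digits` decimals, halves away from zero.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# derive a reproducible sub-stream seed; kept inside 32-bit integer range
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + as.numeric(offset)) %% 2147483647)
}

# evaluate expr with a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

DNA_BASES <- c("A", "C", "G", "T")

# stop() wrapper with a condition class, so callers can distinguish
# configuration errors from data errors
fp_stop <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(structure(
    class = c(class, "filoplast_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}
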