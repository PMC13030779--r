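#' @useDynLib nmfdecode, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif sd aov TukeyHSD fft pnorm dnorm predict
#' @importFrom utils head tail
NULL

# Classed conditions so callers can distinguish argument misuse from I/O or
# format problems.
abort_argument <- function(msg) {
  stop(structure(class = c("nmfdecode_argument_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
abort_format <- function(msg) {
  stop(structure(class = c("nmfdecode_format_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
abort_io <- function(msg) {
  stop(structure(class = c("nmfdecode_io_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
abort_lookup <- function(msg) {
  stop(structure(class = c("nmfdecode_lookup_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# Run `code` with the RNG seeded to `seed`, restoring the caller's RNG state
# afterwards so library calls never disturb user-level reproducibility.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
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

# Derive a sub-seed from a master seed and stream indices, kept inside the
# 32-bit signed range R's set.seed() accepts.
derive_seed <- function(master, ...) {
  idx <- c(...)
  mult <- c(1000003, 10007, 101, 13)[seq_along(idx)]
  as.integer((as.numeric(master) + sum(as.numeric(idx) * mult)) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
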