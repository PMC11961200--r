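#' @useDynLib edame, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor dbinom median runif setNames
#' @importFrom utils combn read.table write.table
NULL

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's RNG
# state is restored afterwards. With seed = NULL the expression runs on the
# ambient RNG stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Derive a reproducible child seed from a base seed and a stream index,
# kept inside the 32-bit integer range.
derive_seed <- function(seed, index) {
  (as.numeric(seed) * 7919 + as.numeric(index) * 104729) %% 2147483647
}

`%||%` <- function(a, b) if (is.null(a)) b else a
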