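# Internal helpers shared across modules.

#' @useDynLib mmgp, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif rchisq var sd cor predict optim pnorm dnorm
#' @importFrom utils read.csv write.csv head
NULL

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards.  All stochastic entry points route through this
# so that a user-visible `seed` argument fully determines the result.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

# Derive a child seed from a base seed and a stream index, staying within the
# 32-bit integer range R requires.
derive_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 1103L + 7919L * as.double(k)) %% 2147483647)
}

stop_mmgp <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
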