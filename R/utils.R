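#' @importFrom rlang %||% .data
#' @importFrom stats rnorm runif sd var cov predict
#' @importFrom utils head tail
NULL

# Evaluate code under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a master seed and a stream label; keeps every
# stochastic stage independently reproducible from one master seed.
child_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

rms <- function(x) sqrt(mean(x^2))

stop_if_not <- function(cond, ...) if (!cond) stop(..., call. = FALSE)
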