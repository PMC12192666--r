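#' @importFrom stats rbinom rbeta runif rnorm integrate var sd predict
#' @importFrom utils head write.csv read.csv
NULL

# Numerically safe softmax along a vector.
softmax <- function(x) {
  x <- x - max(x)
  e <- exp(x)
  e / sum(e)
}

# Row-wise softmax for a matrix.
softmax_rows <- function(m) {
  m <- m - apply(m, 1L, max)
  e <- exp(m)
  e / rowSums(e)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Split a master seed into named per-component streams
#'
#' Deterministically derives distinct 32-bit seeds from a single master seed
#' so that each generator or training component consumes its own RNG stream.
#'
#' @param seed Integer master seed.
#' @param n Number of child seeds.
#' @return Integer vector of length `n`, each in `[0, 2^31 - 1)`.
#' @export
split_seed <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, n >= 1L)
  # LCG-style mixing keeps children reproducible and well below 2^31.
  a <- 1103515245; c <- 12345; m <- 2^31 - 1
  out <- integer(n)
  s <- (abs(as.numeric(seed)) %% m)
  for (i in seq_len(n)) {
    s <- (a * s + c + i * 97) %% m
    out[i] <- as.integer(s)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_shape <- function(msg) stop(msg, call. = FALSE)
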