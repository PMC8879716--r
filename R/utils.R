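#' Logistic sigmoid
#'
#' @param x numeric vector or matrix.
#' @return values in (0, 1).
#' @keywords internal
sigmoid <- function(x) 1 / (1 + exp(-x))

relu <- function(x) pmax(x, 0)

#' Derive a reproducible sub-seed from a stream of integers
#'
#' Folds its arguments through a Lehmer-style multiplicative hash so that
#' independent random draws (per entity, per hop, per epoch, ...) can each get
#' their own deterministic stream from one master seed. The result always lies
#' in [1, 2^31 - 2] so it is a valid argument to [set.seed()].
#'
#' @param ... integers (or values coercible to integer) identifying the stream.
#' @return a single integer seed.
#' @export
derive_seed <- function(...) {
  xs <- c(...)
  m <- 2147483647 # 2^31 - 1, prime
  h <- 17
  for (x in xs) {
    h <- (h * 48271) %% m
    h <- (h + (abs(as.numeric(x)) %% m)) %% m
  }
  as.integer(h %% (m - 1) + 1)
}

#' Evaluate code with a temporary RNG seed, restoring the caller's RNG state
#' @keywords internal
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Softmax over contiguous blocks of a fixed width. `x` has length
# block * n_blocks laid out block-major; returns weights summing to 1 within
# each block. Used for per-neighborhood attention normalisation.
softmax_blocks <- function(x, block) {
  n <- length(x) / block
  stopifnot(n == as.integer(n))
  m <- matrix(x, nrow = block)
  cmax <- m[1, ]
  if (block > 1) for (i in 2:block) cmax <- pmax(cmax, m[i, ])
  e <- exp(m - rep(cmax, each = block))
  tot <- .colSums(e, block, n)
  as.vector(e / rep(tot, each = block))
}

# Sum rows of `x` (N x d) over contiguous blocks of fixed width `block`,
# returning an (N / block) x d matrix. Faster than rowsum() for this layout.
sum_blocks <- function(x, block) {
  n <- nrow(x) / block
  d <- ncol(x)
  dim(x) <- c(block, n * d)
  out <- .colSums(x, block, n * d)
  dim(out) <- c(n, d)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_smilegnn <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
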