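# Internal helpers: reproducible RNG substreams and small numeric utilities.

#' Derive a deterministic sub-seed from a master seed and index labels
#'
#' Mixes a master seed with one or more integer indices (e.g. scenario number,
#' family-set number, replicate block) into a new seed below 2^31, so that
#' independent simulation substreams are reproducible and order-independent.
#'
#' @param seed master seed (single integer).
#' @param ... integer indices identifying the substream.
#' @return A single integer seed in `[1, 2^31 - 2]`.
#' @export
substream_seed <- function(seed, ...) {
  m <- 2147483647  # 2^31 - 1, Mersenne prime
  x <- as.numeric(seed) %% m
  for (k in as.numeric(c(...))) {
    # affine mix per index; constants are odd multipliers well below 2^31
    x <- (x * 48271 + (k + 1) * 16807 + 12345) %% m
  }
  as.integer(x %% (m - 1) + 1)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.
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

# round-half-up (0.5 always rounds up), unlike base round()'s banker's rounding
round_half_up <- function(x) floor(x + 0.5)

# Zero-truncated Poisson draws with Poisson rate lambda (not the mean of the
# truncated distribution); inversion on the truncated CDF.
rztpois <- function(n, lambda) {
  if (lambda <= 0) stop("lambda must be positive")
  u <- runif(n)
  p0 <- exp(-lambda)
  qpois(p0 + u * (1 - p0), lambda)
}

# Solve for the Poisson rate such that the zero-truncated mean equals `mean`.
ztpois_lambda <- function(mean) {
  if (mean <= 1) stop("zero-truncated Poisson mean must exceed 1")
  f <- function(l) l / (1 - exp(-l)) - mean
  uniroot(f, c(1e-8, mean))$root
}

`%||%` <- function(a, b) if (is.null(a)) b else a
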