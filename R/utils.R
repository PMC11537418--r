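#' Derive a reproducible sub-seed for a named module stream
#'
#' A single global seed fans out to per-module substreams so that module-level
#' reruns are independent yet reproducible. The mapping is a small fixed hash
#' of the stream name folded into the global seed, kept below 2^31.
#'
#' @param seed integer global seed.
#' @param stream character scalar naming the consumer (e.g. "placement").
#' @return integer seed.
#' @export
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((abs(as.numeric(seed)) * 69069 + h * 101) %% 2147483647)
}

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores \code{.Random.seed} so seeded helpers do not perturb the
#' caller's RNG stream.
#' @param seed integer seed, or NULL to leave the RNG untouched.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# unit-normalise rows of a matrix; zero rows left as-is
unit_rows <- function(m) {
  n <- sqrt(rowSums(m^2))
  n[n == 0] <- 1
  m / n
}

# clamp to [lo, hi]
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Largest-remainder integer allocation
#'
#' Rounds \code{total * fractions} to integers that sum exactly to
#' \code{total}, assigning leftover units to the largest fractional parts.
#'
#' @param total non-negative integer.
#' @param fractions non-negative weights (normalised internally).
#' @return integer vector summing to \code{total}.
#' @export
largest_remainder <- function(total, fractions) {
  stopifnot(total >= 0, all(fractions >= 0), sum(fractions) > 0)
  p <- fractions / sum(fractions)
  raw <- total * p
  base <- floor(raw)
  rem <- total - sum(base)
  if (rem > 0) {
    idx <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[idx] <- base[idx] + 1
  }
  as.integer(base)
}
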