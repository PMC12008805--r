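#' Derive a child seed from a parent seed
#'
#' Every stochastic operation in the package takes a single integer seed and,
#' where it needs several independent random streams (one per chromosome, per
#' replicate, per bootstrap draw ...), derives child seeds with this mixing
#' function rather than consuming a shared global stream. This keeps each
#' stage bit-reproducible and insensitive to the order in which sibling
#' stages run.
#'
#' The mixer is a multiplicative congruential step in the Lehmer/Park-Miller
#' group (modulus 2^31 - 1, multiplier 48271) offset by the stream index, so
#' results always fit in a 32-bit R integer and are never zero.
#'
#' @param seed parent integer seed.
#' @param stream non-negative integer stream index.
#' @return a positive integer seed, distinct for distinct streams.
#' @export
derive_seed <- function(seed, stream = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  m <- 2147483647               # 2^31 - 1, prime
  s <- (abs(as.numeric(seed)) %% m)
  # two mixing rounds; all arithmetic exact in doubles (< 2^53)
  s <- (s * 48271 + as.numeric(stream) + 1) %% m
  s <- (s * 69621 + 11) %% m
  as.integer(s + 1)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
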