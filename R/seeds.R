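# Deterministic seed derivation so every stochastic stage draws from its own
# stream: perturbing one stage's seed must not shift any other stage's draws.

#' Derive a child seed from a root seed and a stream label
#'
#' Hashes `(root, stream)` to an integer in `[1, 2^31 - 2]` with a fixed
#' multiplicative mixing scheme. The same `(root, stream)` always yields the
#' same child, and distinct streams decorrelate even for adjacent roots.
#'
#' @param root integer root seed.
#' @param stream character scalar naming the stream (e.g. `"rr/s03/high"`).
#' @return a single integer usable with [set.seed()].
#' @export
child_seed <- function(root, stream) {
  stopifnot(is.numeric(root), length(root) == 1L, is.character(stream),
            length(stream) == 1L)
  m <- 2147483647  # 2^31 - 1, prime
  h <- as.double(root %% m)
  for (b in utf8ToInt(stream)) {
    h <- (h * 48271 + b * 65537 + 12345) %% m
  }
  # extra scramble pass so short streams differing in one byte diverge fully
  for (i in 1:3) h <- (h * 69621 + 113) %% m
  as.integer(h %% (m - 2) + 1)
}

# run `expr` under a locally seeded RNG, restoring the caller's RNG state
with_stream <- function(root, stream, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(child_seed(root, stream))
  expr
}
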