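# Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a reproducible substream seed
#'
#' Deterministic seed-splitting: derives a seed below 2^31 from a base seed
#' and up to three indices (conventionally individual, stimulus, replicate),
#' so all randomness in a simulated experiment flows from one base seed.
#'
#' @param seed Base integer seed.
#' @param i,j,k Non-negative stream indices.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
split_seed <- function(seed, i = 0L, j = 0L, k = 0L) {
  m <- 2147483647
  s <- (as.numeric(seed) %% m)
  s <- (s * 48271 + as.numeric(i) * 1299709) %% m
  s <- (s + as.numeric(j) * 15485863) %% m
  s <- (s + as.numeric(k) * 32452843) %% m
  as.integer(s %% (m - 1) + 1)
}
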