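# Reproducible substreams: one master seed, per-subject streams derived by
# counter with L'Ecuyer-CMRG, so enlarging a cohort never reshuffles the
# subjects already generated. Responders and non-responders draw from
# disjoint counter ranges for the same reason.

rootStream <- function(seed) {
  old <- getRandomSeed()
  on.exit(setRandomSeed(old))
  suppressWarnings(set.seed(as.integer(seed %% 2147483647L),
                            kind = "L'Ecuyer-CMRG"))
  get(".Random.seed", envir = globalenv())
}

# k-th substream (k >= 0) of the master seed
streamAt <- function(seed, k) {
  s <- rootStream(seed)
  i <- 0L
  while (i < k) {
    s <- parallel::nextRNGStream(s)
    i <- i + 1L
  }
  s
}

getRandomSeed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

setRandomSeed <- function(seed) {
  if (is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", seed, envir = globalenv())
  }
  invisible(NULL)
}

# Evaluate expr with the RNG positioned at `stream`; the caller's RNG state
# is untouched. Returns list(value, stream = advanced stream state) so a
# stream can be consumed sequentially across calls.
withStream <- function(stream, expr) {
  old <- getRandomSeed()
  on.exit(setRandomSeed(old))
  setRandomSeed(stream)
  value <- force(expr)
  list(value = value, stream = getRandomSeed())
}
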