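# Self-contained RNG streams: every stochastic operation in the package
# draws from an explicit stream object seeded once, so cohorts are
# bit-reproducible from (config, seed) and independent of the caller's
# global RNG state.

new_rng <- function(seed) {
  e <- new.env(parent = emptyenv())
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed %% 2147483647L))
  e$state <- get(".Random.seed", envir = globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  e
}

with_rng <- function(rng, expr) {
  old <- get0(".Random.seed", envir = globalenv())
  assign(".Random.seed", rng$state, envir = globalenv())
  on.exit({
    rng$state <- get(".Random.seed", envir = globalenv())
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  eval.parent(substitute(expr))
}

rng_norm <- function(rng, n, mean = 0, sd = 1)
  with_rng(rng, stats::rnorm(n, mean, sd))
rng_unif <- function(rng, n, min = 0, max = 1)
  with_rng(rng, stats::runif(n, min, max))
rng_sample <- function(rng, n, size = n, replace = FALSE)
  with_rng(rng, sample.int(n, size, replace = replace))
rng_binom <- function(rng, n, prob)
  with_rng(rng, stats::rbinom(n, 1L, prob))

# derive a child seed (< 2^31) so sub-streams are decoupled
derive_seed <- function(seed, index)
  as.integer((as.double(seed) * 48271 + index * 8191) %% 2147483629)
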