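# A private, seedable RNG stream. All stochastic operations in the package
# draw from one of these so that results are deterministic given a seed and
# the caller's global RNG state is left untouched.

rng_local <- function(seed) {
  e <- new.env(parent = emptyenv())
  run <- function(f) {
    old <- get0(".Random.seed", globalenv(), inherits = FALSE)
    on.exit({
      e$state <- get(".Random.seed", globalenv(), inherits = FALSE)
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    if (is.null(e$state)) {
      set.seed(as.integer(seed %% .Machine$integer.max))
    } else {
      assign(".Random.seed", e$state, envir = globalenv())
    }
    f()
  }
  e$run <- run
  e$sample_n <- function(n, k) run(function() {
    if (k == 0L) integer(0) else sample.int(n, k)
  })
  e$shuffle <- function(n) run(function() sample.int(n, n))
  e$runif <- function(n, min = 0, max = 1) run(function() stats::runif(n, min, max))
  e$rnorm <- function(n) run(function() stats::rnorm(n))
  e$rbinom1 <- function(p) run(function() stats::rbinom(1L, 1L, p)) == 1L
  e$sample_vec <- function(x, k, replace = FALSE) run(function() {
    x[sample.int(length(x), k, replace = replace)]
  })
  e
}

# derive a well-separated child seed (kept below 2^31)
derive_seed <- function(seed, salt) {
  (as.double(seed) * 48271 + salt * 9973) %% 2147483629
}
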