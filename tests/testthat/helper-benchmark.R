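# The full synthetic benchmark trains three models and takes several
# minutes; compute it once per test run and share the result.

.benchmark_cache <- new.env(parent = emptyenv())

get_benchmark <- function() {
  if (is.null(.benchmark_cache$res)) {
    .benchmark_cache$res <- run_synthetic_benchmark(seed = 1)
  }
  .benchmark_cache$res
}
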