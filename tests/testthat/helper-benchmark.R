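# The phantom benchmark trains for about a minute on one CPU; several test
# files inspect the same trained model, so the run is cached per session.
.benchmark_cache <- new.env(parent = emptyenv())

get_benchmark <- function() {
  if (is.null(.benchmark_cache$bm)) {
    .benchmark_cache$bm <- run_phantom_benchmark(seed = 1L)
  }
  .benchmark_cache$bm
}
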