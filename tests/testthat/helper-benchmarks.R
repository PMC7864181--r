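# Shared, lazily computed phantom benchmarks for the acceptance tests.
# Sweeps are cached so several test blocks can reuse the same runs.

.bench_cache <- new.env(parent = emptyenv())

bench_seeds <- 1:20

bench_sweep <- function(key, ...) {
  if (is.null(.bench_cache[[key]])) {
    .bench_cache[[key]] <- phantom_accuracy_sweep(bench_seeds, ...)
  }
  .bench_cache[[key]]
}

bench_fcm_002 <- function() bench_sweep("fcm_002", noise = 0.02,
                                        method = "fcm")
bench_ifcm_002 <- function() bench_sweep("ifcm_002", noise = 0.02)
bench_ifcm_000 <- function() bench_sweep("ifcm_000", noise = 0)
bench_abl <- function(step) {
  switch(step,
    base = bench_sweep("abl_base", noise = 0.02, use_ifs = FALSE,
                       use_transfer = FALSE, use_similarity = FALSE),
    ifs = bench_sweep("abl_ifs", noise = 0.02, use_ifs = TRUE,
                      use_transfer = FALSE, use_similarity = FALSE),
    transfer = bench_sweep("abl_transfer", noise = 0.02, use_ifs = TRUE,
                           use_transfer = TRUE, use_similarity = FALSE),
    similarity = bench_ifcm_002()
  )
}
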