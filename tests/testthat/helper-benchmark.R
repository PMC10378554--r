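# Benchmark fixtures shared across acceptance tests. Built once per test
# run and cached in the session (the case-6 matrix takes ~10 s to build).
bench_cache <- new.env(parent = emptyenv())

get_benchmark6 <- function() {
  if (is.null(bench_cache$b6)) {
    bench_cache$b6 <- make_benchmark(benchmark_spec(6), seed = 1)
  }
  bench_cache$b6
}

# The 2-copula overlapping-tails matrix is the first 40 rows (Frank + Clayton
# non-rotated) of the case-6 build: the row constructions coincide.
get_benchmark2 <- function() {
  b6 <- get_benchmark6()
  sel <- b6$labels %in% c("frank(6)", "clayton(5)")
  list(X = b6$X[sel, ], V = b6$V[sel, ],
       truth = b6$truth[c("frank(6)", "clayton(5)")],
       labels = b6$labels[sel], G = b6$G)
}
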