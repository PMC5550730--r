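# shared cached simulations: the study conditions are expensive, so test
# files draw from one memoised store keyed by (condition, n, seed).
.run_cache <- new.env(parent = emptyenv())

cached_run <- function(condition, n_per_pop = 100, seed = 1L,
                       duration = 1500, transient = 500) {
  key <- paste(condition, n_per_pop, seed, duration, transient, sep = "|")
  if (is.null(.run_cache[[key]])) {
    .run_cache[[key]] <- run_condition(condition, n_per_pop = n_per_pop,
                                       seed = seed, duration = duration,
                                       transient = transient)
  }
  .run_cache[[key]]
}

# small synthetic Poisson spike trains (independence null for SL / MI)
poisson_trains <- function(n_neurons, rate_hz, duration_ms, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n_neurons), function(i) {
    n <- rpois(1, rate_hz * duration_ms / 1000)
    sort(runif(n, 0, duration_ms))
  })
}
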