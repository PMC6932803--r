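# Memoised virtual-trial runs shared between test files: each
# (population, seed) pair is simulated once per test session.
.trial_cache <- new.env(parent = emptyenv())

cached_trial <- function(pop, seed, n = 125) {
  key <- paste(pop, seed, n, sep = "_")
  if (is.null(.trial_cache[[key]]))
    .trial_cache[[key]] <- run_virtual_trial(
      population_spec(pop, n_patients = n, seed = seed))
  .trial_cache[[key]]
}

trial_accuracy <- function(pop, seeds, n = 125) {
  vapply(seeds, function(s) {
    res <- cached_trial(pop, s, n)
    weighted_accuracy(res$ratio, res$responder)$accuracy
  }, numeric(1))
}
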