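# Long training runs shared between acceptance tests (computed once per
# test session).

.run_cache <- new.env(parent = emptyenv())

cached_run <- function(key, fn) {
  if (is.null(.run_cache[[key]])) .run_cache[[key]] <- fn()
  .run_cache[[key]]
}

cached_taxi_runs <- function(seeds = 1:3) {
  cached_run(paste0("taxi", paste(seeds, collapse = "")), function() {
    lapply(seeds, function(s) run_experiment("taxi", seed = s))
  })
}

cached_voronoi_runs <- function(task = "voronoi", seeds = 1:3,
                                episodes = 600L) {
  cached_run(paste0(task, paste(seeds, collapse = ""), "_", episodes),
             function() {
    lapply(seeds, function(s) run_experiment(task, episodes = episodes,
                                             seed = s))
  })
}
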