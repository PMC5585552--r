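# Desk-scale configurations and lazily cached heavy simulation batches,
# shared across test files so each expensive batch is simulated once.

.np_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.np_cache[[key]])) assign(key, force(expr), envir = .np_cache)
  .np_cache[[key]]
}

# 30 runs x 2,000 women, 50-year burn-in + 30 measurement years
desk_sweep_batch <- function() {
  cached("sweep_batch", {
    p <- scenario_params(initial_population = 2000, horizon_years = 80,
                         burn_in_years = 50)
    simulate_sweep_batch(p, n_sims = 30, seed = 1L)
  })
}

# 30 runs x 2,000 women, 120-year horizon, h(t) scenario
desk_historical <- function(shape) {
  cached(paste0("hist_", shape), {
    p <- scenario_params(initial_population = 2000, horizon_years = 120,
                         burn_in_years = 50)
    run_historical_experiment(p, historical_scenario(shape), n_sims = 30,
                              seed = 2L)
  })
}

# mortality-free configuration (exact NPR_x back-projection)
no_mortality <- function(...) {
  scenario_params(mortality_by_age = data.frame(age = 0, value = 0), ...)
}
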