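test_that("scenario h(t) tables have the documented shapes", {
  sd <- scenario_h_table(historical_scenario("steady_decline"))
  p <- scenario_params(h_of_t = sd)
  expect_equal(h_lookup(p, c(0, 50, 55, 60, 100)), c(1, 1, 0.65, 0.3, 0.3))
  tr <- scenario_h_table(historical_scenario("transient_drop"))
  p2 <- scenario_params(h_of_t = tr)
  expect_equal(h_lookup(p2, c(0, 50, 52.5, 55, 57.5, 60, 100)),
               c(1, 1, 0.65, 0.3, 0.65, 1, 1))
  # floor = peak degenerates to a constant modifier
  cn <- scenario_h_table(historical_scenario("steady_decline", floor_level = 1))
  expect_equal(h_lookup(scenario_params(h_of_t = cn), c(0, 55, 90)),
               c(1, 1, 1))
  expect_error(historical_scenario("steady_decline", floor_level = 2),
               "floor_level")
})

test_that("fixture generator delivers the exact requested counts", {
  fx <- generate_fixture_registry(n_births = 8, n_nonpaternity = 2,
                                  sibships = list(c("A", "A", "B")),
                                  episodes = c(marital = 12, extramarital = 3))
  expect_equal(nrow(fx$registry), 11)
  expect_equal(sum(fx$registry$nonpaternity), 2)
  expect_equal(sum(fx$plog$class == "extramarital"), 3)
  expect_equal(sum(fx$plog$class == "marital"), 12)
  expect_error(generate_fixture_registry(n_births = 2, n_nonpaternity = 5),
               "cannot exceed")
  expect_error(generate_fixture_registry(episodes = c(extramarital = 1)),
               "married")
  expect_error(generate_fixture_registry(episodes = c(sororal = 1)),
               "unknown episode class")
})

test_that("a zero extramarital rate forces NPR and EPR to zero", {
  p <- scenario_params(initial_population = 500, horizon_years = 15,
                       burn_in_years = 5, extramarital_rate_mean = 0,
                       extramarital_rate_var = 0,
                       premarital_rate_mean = 0.4, premarital_rate_var = 0.1)
  sim <- run_simulation(p, seed = 70)
  s <- measure_series(sim, 6:15)
  expect_true(all(s$npr[!is.na(s$npr)] == 0))
  expect_true(all(s$epr[!is.na(s$epr)] == 0))
  expect_true(any(!is.na(s$epr)))
})

test_that("without marriage every measure needing married women is undefined", {
  p <- scenario_params(initial_population = 300, horizon_years = 6,
                       burn_in_years = 0, marriage_rate_alpha = 0,
                       premarital_rate_mean = 0.5, premarital_rate_var = 0)
  sim <- run_simulation(p, seed = 71)
  expect_true(all(is.na(vapply(1:6 * 365.25,
                               function(t) compute_epr(sim$plog, t),
                               numeric(1)))))
  expect_equal(sum(sim$registry$nonpaternity), 0)
})

test_that("age-specific ratios back-project the birth-year ratio exactly
           when nobody dies", {
  p <- no_mortality(initial_population = 800, horizon_years = 25,
                    burn_in_years = 0, extramarital_rate_mean = 0.25,
                    extramarital_rate_var = 0,
                    premarital_rate_mean = 0.4, premarital_rate_var = 0.1)
  sim <- run_simulation(p, seed = 72)
  for (x in c(0, 3, 7, 12)) {
    t <- 20 * 365.25
    expect_equal(compute_npr_x(sim$registry, t, x),
                 compute_npr(sim$registry, t - x * 365.25))
  }
})

test_that("correlation experiments are deterministic given a seed", {
  p <- scenario_params(initial_population = 250, horizon_years = 12,
                       burn_in_years = 5)
  e1 <- run_npr_epr_experiment(p, n_sims = 3, seed = 73)
  e2 <- run_npr_epr_experiment(p, n_sims = 3, seed = 73)
  expect_identical(e1$correlation$r, e2$correlation$r)
  expect_identical(e1$pairs, e2$pairs)
  h1 <- run_historical_experiment(p, historical_scenario("transient_drop",
                                                         decline_start_year = 5),
                                  n_sims = 2, seed = 74, ages = 0:6)
  h2 <- run_historical_experiment(p, historical_scenario("transient_drop",
                                                         decline_start_year = 5),
                                  n_sims = 2, seed = 74, ages = 0:6)
  expect_identical(h1$correlation_raw$r, h2$correlation_raw$r)
  expect_identical(h1$correlation_smoothed$r, h2$correlation_smoothed$r)
})

test_that("experiment reports expose per-run series behind pooled numbers", {
  p <- scenario_params(initial_population = 250, horizon_years = 12,
                       burn_in_years = 5)
  batch <- simulate_sweep_batch(p, n_sims = 3, seed = 75)
  e <- run_npr_epr_experiment(batch = batch)
  expect_length(e$series, 3)
  expect_equal(nrow(e$draws), 3)
  # the pooled correlation is recomputable from the stored series
  pr <- paired_lagged_series(e$series, 1, x = "epr", y = "npr")
  expect_identical(e$correlation$r, pearson_r(pr$x, pr$y))
  # and both correlation experiments can share one batch
  e2 <- run_hsr_epr_experiment(batch = batch)
  expect_identical(e2$n_sims, 3L)
})

test_that("phi sweep output is a well-formed mean/CI table", {
  p <- scenario_params(initial_population = 300, horizon_years = 14,
                       burn_in_years = 6, extramarital_rate_mean = 0.3,
                       extramarital_rate_var = 0)
  sw <- run_phi_sweep(p, phi_values = c(0.2, 0.8), n_sims = 3, seed = 76)
  tab <- sw$sweep_table
  expect_equal(tab$phi_m, c(0.2, 0.8))
  expect_true(all(tab$lo <= tab$mean_npr & tab$mean_npr <= tab$hi))
  expect_true(all(tab$n_runs == 3))
  sw2 <- run_phi_sweep(p, phi_values = c(0.2, 0.8), n_sims = 3, seed = 76)
  expect_identical(sw$sweep_table, sw2$sweep_table)
})
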