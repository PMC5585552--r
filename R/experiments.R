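#' Historical scenario for nonmarital sex rates
#'
#' Describes a time-dependent modifier h(t) on the nonmarital partnering
#' rates.  `"steady_decline"` falls linearly from `peak_level` to
#' `floor_level` over `decline_duration_years` starting at
#' `decline_start_year` and then plateaus — the shape of the apparent
#' fall in sexual risk behaviour after the onset of the HIV epidemic.
#' `"transient_drop"` falls the same way and then recovers linearly to
#' the peak over `recovery_duration_years`.  The floor defaults to 30%
#' of the peak.
#'
#' @param shape `"steady_decline"` or `"transient_drop"`.
#' @param peak_level,floor_level Relative levels (peak 1 by convention).
#' @param decline_start_year Year the decline begins (default: at the end
#'   of a 50-year burn-in).
#' @param decline_duration_years Length of the decline.
#' @param recovery_duration_years Length of the recovery (transient only).
#' @return An object of class `np_scenario`.
#' @export
historical_scenario <- function(shape = c("steady_decline", "transient_drop"),
                                peak_level = 1, floor_level = 0.3,
                                decline_start_year = 50,
                                decline_duration_years = if (match.arg(shape) ==
                                  "steady_decline") 10 else 5,
                                recovery_duration_years = 5) {
  shape <- match.arg(shape)
  stopifnot(floor_level >= 0, floor_level <= peak_level,
            decline_duration_years > 0, recovery_duration_years > 0)
  structure(list(shape = shape, peak_level = peak_level,
                 floor_level = floor_level,
                 decline_start_year = decline_start_year,
                 decline_duration_years = decline_duration_years,
                 recovery_duration_years = recovery_duration_years),
            class = "np_scenario")
}

#' @export
print.np_scenario <- function(x, ...) {
  cat(sprintf("Historical nonmarital-sex scenario: %s\n", x$shape))
  cat(sprintf("  h(t): %.3g until year %.4g, then to %.3g over %.4g years%s\n",
              x$peak_level, x$decline_start_year, x$floor_level,
              x$decline_duration_years,
              if (x$shape == "transient_drop")
                sprintf(", back to %.3g over %.4g years", x$peak_level,
                        x$recovery_duration_years) else " (plateau)"))
  invisible(x)
}

#' Piecewise-linear h(t) table for a historical scenario
#'
#' @param scenario An `np_scenario` object.
#' @return A data frame usable as the `h_of_t` field of
#'   [scenario_params()].
#' @export
scenario_h_table <- function(scenario) {
  stopifnot(inherits(scenario, "np_scenario"))
  t0 <- scenario$decline_start_year
  t1 <- t0 + scenario$decline_duration_years
  if (scenario$shape == "steady_decline") {
    data.frame(time = c(0, t0, t1),
               value = c(scenario$peak_level, scenario$peak_level,
                         scenario$floor_level))
  } else {
    data.frame(time = c(0, t0, t1, t1 + scenario$recovery_duration_years),
               value = c(scenario$peak_level, scenario$peak_level,
                         scenario$floor_level, scenario$peak_level))
  }
}

new_experiment <- function(type, ...) {
  structure(c(list(type = type), list(...)), class = "np_experiment")
}

#' @export
print.np_experiment <- function(x, ...) {
  cat(sprintf("Simulation experiment: %s (%d runs)\n", x$type, x$n_sims))
  for (f in c("correlation", "correlation_raw", "correlation_smoothed")) {
    if (!is.null(x[[f]])) { cat("  "); print(x[[f]]) }
  }
  if (!is.null(x$sweep_table)) {
    cat("  phi_m sweep (mean NPR with 95% CI across runs):\n")
    print(x$sweep_table, row.names = FALSE, digits = 4)
  }
  if (!is.null(x$n_undefined_runs) && x$n_undefined_runs > 0)
    cat(sprintf("  note: %d run(s) had no defined measure pairs\n",
                x$n_undefined_runs))
  invisible(x)
}

#' Simulate a batch of runs with rates drawn from the SSA ranges
#'
#' Each run draws the premarital/extramarital rate means and variances
#' via [sample_sweep_params()], simulates, and records the annual
#' NPR/EPR/HSR series from the end of the burn-in onward.  This is the
#' common engine behind [run_npr_epr_experiment()] and
#' [run_hsr_epr_experiment()]; building the batch once allows both
#' correlations to be computed from the same runs.
#'
#' @param base_params Base `np_params`; its `horizon_years` and
#'   `burn_in_years` set the measurement era (annual censuses from the
#'   end of burn-in to the horizon).
#' @param n_sims Number of simulation runs.
#' @param seed Integer seed making the whole batch reproducible.
#' @return An object of class `np_batch`: list with `series` (one data
#'   frame per run), `draws` (the sampled rate parameters) and `n_sims`.
#' @export
simulate_sweep_batch <- function(base_params = default_params(), n_sims = 100,
                                 seed = NULL) {
  n_sims <- as.integer(n_sims)
  if (!is.null(seed)) set.seed(seed)
  run_seeds <- sample.int(.Machine$integer.max - 1L, n_sims)
  draws <- sample_sweep_params(base_params, n_sims)
  years <- seq(floor(base_params$burn_in_years),
               floor(base_params$horizon_years))
  series <- vector("list", n_sims)
  for (i in seq_len(n_sims)) {
    sim <- run_simulation(draws[[i]], seed = run_seeds[i])
    series[[i]] <- measure_series(sim, years)
  }
  structure(list(series = series,
                 draws = data.frame(
                   premarital_rate_mean = vapply(draws, `[[`, 0, "premarital_rate_mean"),
                   premarital_rate_var = vapply(draws, `[[`, 0, "premarital_rate_var"),
                   extramarital_rate_mean = vapply(draws, `[[`, 0, "extramarital_rate_mean"),
                   extramarital_rate_var = vapply(draws, `[[`, 0, "extramarital_rate_var")),
                 run_seeds = run_seeds, n_sims = n_sims,
                 base_params = base_params),
            class = "np_batch")
}

correlation_from_batch <- function(batch, measure, label) {
  pairs <- paired_lagged_series(batch$series, lag_years = 1,
                                x = "epr", y = measure)
  n_undef <- batch$n_sims - length(unique(pairs$sim))
  cor <- correlate(pairs$x, pairs$y, ci_n = batch$n_sims, label = label)
  list(cor = cor, pairs = pairs, n_undef = n_undef)
}

#' Correlation experiment: nonpaternity ratio against extramarital sex
#'
#' Reproduces the reliability analysis for the nonpaternity ratio:
#' `n_sims` runs with nonmarital-rate means/variances drawn from the SSA
#' ranges, annual censuses after burn-in, pooled pairs of NPR(T) against
#' EPR(T-1) (the one-year shift accommodates gestation), Pearson
#' correlation with a Fisher z interval whose effective n is the number
#' of runs.
#'
#' @inheritParams simulate_sweep_batch
#' @param batch Optionally a precomputed [simulate_sweep_batch()] result
#'   (then `base_params`, `n_sims` and `seed` are ignored).
#' @return An `np_experiment` with the `correlation` (`np_cor`), the
#'   pooled `pairs`, the batch `series`, and run metadata.
#' @export
run_npr_epr_experiment <- function(base_params = default_params(),
                                   n_sims = 100, seed = NULL, batch = NULL) {
  if (is.null(batch))
    batch <- simulate_sweep_batch(base_params, n_sims, seed)
  res <- correlation_from_batch(batch, "npr", "NPR(T) ~ EPR(T-1)")
  new_experiment("npr_epr", n_sims = batch$n_sims,
                 correlation = res$cor, pairs = res$pairs,
                 series = batch$series, draws = batch$draws,
                 run_seeds = batch$run_seeds, seed = seed,
                 n_undefined_runs = res$n_undef)
}

#' Correlation experiment: half-siblings ratio against extramarital sex
#'
#' Same design as [run_npr_epr_experiment()] with the half-siblings
#' ratio HSR(T) in place of NPR(T).
#'
#' @inheritParams run_npr_epr_experiment
#' @return An `np_experiment`, as for [run_npr_epr_experiment()].
#' @export
run_hsr_epr_experiment <- function(base_params = default_params(),
                                   n_sims = 100, seed = NULL, batch = NULL) {
  if (is.null(batch))
    batch <- simulate_sweep_batch(base_params, n_sims, seed)
  res <- correlation_from_batch(batch, "hsr", "HSR(T) ~ EPR(T-1)")
  new_experiment("hsr_epr", n_sims = batch$n_sims,
                 correlation = res$cor, pairs = res$pairs,
                 series = batch$series, draws = batch$draws,
                 run_seeds = batch$run_seeds, seed = seed,
                 n_undefined_runs = res$n_undef)
}

#' Historical back-casting experiment with a time-varying h(t)
#'
#' Runs `n_sims` simulations under the scenario's h(t), then pairs the
#' age-specific nonpaternity ratio NPR_x(T), for integer ages `x` of
#' 0-50 at each census year `T`, with the extramarital partnership ratio
#' EPR(T - x - 1) of the year each cohort was conceived.  Reports the
#' pooled Pearson correlation of the raw pairs and of the pairs after a
#' 10-year moving average is applied both to each run's EPR history
#' (over time) and to each census's NPR_x profile (over age).
#'
#' @inheritParams simulate_sweep_batch
#' @param scenario An [historical_scenario()]; its h(t) replaces the base
#'   parameters' time modifier.
#' @param census_years Census times T; default every whole year from the
#'   end of the burn-in to the horizon (the full post-burn-in record, so
#'   the pooled pairs include both transition-spanning and flat-era
#'   lookbacks).
#' @param ages Age bands x (default 0-50).
#' @param smooth_window Moving-average window in years.
#' @param rates_at Whether `base_params`' nonmarital rate means describe
#'   the scenario's `"floor"` (the default: the lowest level is the
#'   self-reported, DHS-derived one, so the means are divided by
#'   `floor_level` to give the peak before h(t) is applied) or the
#'   `"peak"` (means used as given).
#' @return An `np_experiment` with `correlation_raw`,
#'   `correlation_smoothed`, the per-run EPR series and NPR_x profile
#'   matrices, and run metadata.
#' @export
run_historical_experiment <- function(base_params = default_params(),
                                      scenario = historical_scenario(),
                                      n_sims = 100, seed = NULL,
                                      census_years = NULL, ages = 0:50,
                                      smooth_window = 10,
                                      rates_at = c("floor", "peak")) {
  stopifnot(inherits(scenario, "np_scenario"))
  n_sims <- as.integer(n_sims)
  rates_at <- match.arg(rates_at)
  params <- base_params
  if (rates_at == "floor") {
    scale <- scenario$peak_level / scenario$floor_level
    params$premarital_rate_mean <- params$premarital_rate_mean * scale
    params$premarital_rate_var <- params$premarital_rate_var * scale^2
    params$extramarital_rate_mean <- params$extramarital_rate_mean * scale
    params$extramarital_rate_var <- params$extramarital_rate_var * scale^2
  }
  params$h_of_t <- as_time_table(scenario_h_table(scenario))
  validate_params(params)
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max - 1L, 1)
  set.seed(seed)
  run_seeds <- sample.int(.Machine$integer.max - 1L, n_sims)
  if (is.null(census_years))
    census_years <- seq(floor(params$burn_in_years) + 1,
                        floor(params$horizon_years))
  all_years <- seq_len(floor(params$horizon_years))

  raw_x <- raw_y <- sm_x <- sm_y <- numeric(0)
  epr_series <- vector("list", n_sims)
  profiles <- vector("list", n_sims)
  for (i in seq_len(n_sims)) {
    sim <- run_simulation(params, seed = run_seeds[i])
    epr <- vapply(all_years * DAYS_PER_YEAR,
                  function(t) compute_epr(sim$plog, t), numeric(1))
    prof <- npr_profiles(sim, census_years, ages)
    epr_s <- moving_average(epr, smooth_window)
    prof_s <- t(apply(prof, 1, moving_average, window = smooth_window))
    for (ti in seq_along(census_years)) {
      T <- census_years[ti]
      lagged <- T - ages - 1
      ok <- lagged >= 1
      raw_x <- c(raw_x, epr[lagged[ok]]); raw_y <- c(raw_y, prof[ti, ok])
      sm_x <- c(sm_x, epr_s[lagged[ok]]); sm_y <- c(sm_y, prof_s[ti, ok])
    }
    epr_series[[i]] <- epr
    profiles[[i]] <- prof
  }
  new_experiment(paste0("historical_", scenario$shape), n_sims = n_sims,
                 scenario = scenario,
                 correlation_raw = correlate(raw_x, raw_y, ci_n = n_sims,
                                             label = "NPR_x(T) ~ EPR(T-x-1), raw"),
                 correlation_smoothed = correlate(sm_x, sm_y, ci_n = n_sims,
                                                  label = sprintf(
                                                    "NPR_x(T) ~ EPR(T-x-1), %d-year MA",
                                                    smooth_window)),
                 census_years = census_years, ages = ages,
                 epr_series = epr_series, profiles = profiles,
                 run_seeds = run_seeds, seed = seed)
}

#' Sweep over the marital share of coital acts
#'
#' For each value of `phi_m`, runs `n_sims` simulations at the base
#' (self-reported, DHS-derived) nonmarital rates and summarises the mean
#' nonpaternity ratio across runs with a normal-theory 95% CI.  The
#' resulting table is the simulation side of the comparison between
#' self-reported extramarital sex and empirical nonpaternity levels.
#'
#' @inheritParams simulate_sweep_batch
#' @param phi_values Values of `phi_m` to simulate.
#' @return An `np_experiment` with `sweep_table` (`phi_m`, `mean_npr`,
#'   `lo`, `hi`, `n_runs`) and the per-run mean NPRs.
#' @export
run_phi_sweep <- function(base_params = default_params(),
                          phi_values = seq(0.1, 0.9, by = 0.1),
                          n_sims = 100, seed = NULL) {
  stopifnot(all(phi_values > 0 & phi_values < 1))
  n_sims <- as.integer(n_sims)
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max - 1L, 1)
  set.seed(seed)
  years <- seq(floor(base_params$burn_in_years) + 1,
               floor(base_params$horizon_years))
  per_run <- matrix(NA_real_, n_sims, length(phi_values))
  for (j in seq_along(phi_values)) {
    p <- base_params
    p$phi_m <- phi_values[j]
    run_seeds <- sample.int(.Machine$integer.max - 1L, n_sims)
    for (i in seq_len(n_sims)) {
      sim <- run_simulation(p, seed = run_seeds[i])
      npr <- vapply(years * DAYS_PER_YEAR,
                    function(t) compute_npr(sim$registry, t), numeric(1))
      per_run[i, j] <- if (all(is.na(npr))) NA_real_ else mean(npr, na.rm = TRUE)
    }
  }
  tab <- do.call(rbind, lapply(seq_along(phi_values), function(j) {
    v <- per_run[, j][!is.na(per_run[, j])]
    m <- mean(v); se <- stats::sd(v) / sqrt(length(v))
    data.frame(phi_m = phi_values[j], mean_npr = m,
               lo = m - stats::qnorm(0.975) * se,
               hi = m + stats::qnorm(0.975) * se, n_runs = length(v))
  }))
  new_experiment("phi_sweep", n_sims = n_sims, sweep_table = tab,
                 per_run_npr = per_run, phi_values = phi_values, seed = seed)
}
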