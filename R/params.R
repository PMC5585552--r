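#' Scenario parameters for the partnering-and-conception simulator
#'
#' Constructs and validates the full parameter set that defines one
#' simulation scenario: partnership formation/dissolution rates, the
#' conception model (fecundability, coital frequency, condom use), the
#' gestation model, mortality, population size and run length.  The
#' defaults are the Kenya 2008-2009 DHS-derived set used throughout the
#' package's experiments.
#'
#' Age-indexed schedules (`fecundability_by_age`, `coital_frequency_by_age`,
#' `mortality_by_age`, `nonmarital_age_multiplier`) are two-column data
#' frames (`age`, `value`) interpreted as step functions: `value[i]` applies
#' on `[age[i], age[i+1])`, the last value extends to all older ages, and
#' ages below the first row take value 0.  `h_of_t` is a two-column data
#' frame (`time` in years, `value`) interpreted as a piecewise-linear
#' time modifier on nonmarital partnering rates, constant beyond its ends.
#'
#' @param marriage_rate_alpha Per-year hazard of marriage formation for
#'   eligible (unmarried, age > 15) women.
#' @param marital_duration_mean_years Mean duration of a marital
#'   partnership in years (the dissolution hazard is its reciprocal).
#' @param casual_duration_months Mean duration of a nonmarital (casual)
#'   partnership in months.
#' @param gestation_mean_days,gestation_sd_days Normal gestation model.
#' @param premarital_rate_mean,premarital_rate_var Mean and variance of the
#'   individual-level rate (per year) at which unmarried women form new
#'   premarital partnerships.
#' @param extramarital_rate_mean,extramarital_rate_var Mean and variance of
#'   the individual-level rate (per year) at which married women form new
#'   extramarital partnerships.
#' @param phi_m Fraction of a married woman's coital acts that are with her
#'   spouse, as opposed to an extramarital partner.
#' @param condom_coverage Named numeric vector with elements `unmarried`,
#'   `marital` and `extramarital`: partnership-class condom use coverage.
#' @param condom_efficacy Proportional reduction of the per-act conception
#'   probability when a condom is used.
#' @param fecundability_by_age Step-function table of the per-coital-act
#'   conception probability by the woman's age.
#' @param coital_frequency_by_age Step-function table of coital acts per
#'   month by age.
#' @param mortality_by_age Step-function table of the per-year death hazard
#'   by age; must start at age 0.
#' @param nonmarital_age_multiplier Step-function table multiplying the
#'   nonmarital partnering rates by age (default 1 everywhere).
#' @param h_of_t Piecewise-linear time modifier on nonmarital partnering
#'   rates (default identically 1).
#' @param initial_population Number of women at time 0.
#' @param time_step_days Simulation step in days.
#' @param burn_in_years Initial years discarded by the experiment runners.
#' @param horizon_years Total simulated years (including burn-in).
#' @param min_partner_age Youngest age (years) at which partnerships form.
#' @param max_conception_age Age (years) after which conception no longer
#'   occurs (partnering itself continues).
#' @param hsr_method Half-siblings ratio definition: `"pair"` (fraction of
#'   same-mother child pairs with different biological fathers) or
#'   `"child"` (children with at least one maternal half-sibling over
#'   children with at least one maternal sibling).
#' @param hsr_scope Sibship scope for the half-siblings ratio:
#'   `"married_mothers"` (children born in wedlock; captures extramarital
#'   fathering and remarriage) or `"all_children"`; see [compute_hsr()].
#'
#' @return An object of class `np_params` (a validated named list).
#' @seealso [default_params()], [load_params()], [sample_sweep_params()]
#' @examples
#' p <- scenario_params(initial_population = 1000, horizon_years = 20)
#' p$marriage_rate_alpha
#' @export
scenario_params <- function(marriage_rate_alpha = 0.12,
                            marital_duration_mean_years = 20,
                            casual_duration_months = 6,
                            gestation_mean_days = 267,
                            gestation_sd_days = 10,
                            premarital_rate_mean = 0.32,
                            premarital_rate_var = 0.0087,
                            extramarital_rate_mean = 0.0088,
                            extramarital_rate_var = 0.0,
                            phi_m = 0.7,
                            condom_coverage = c(unmarried = 0.23,
                                                marital = 0.019,
                                                extramarital = 0.074),
                            condom_efficacy = 0.90,
                            fecundability_by_age = default_fecundability(),
                            coital_frequency_by_age = default_coital_frequency(),
                            mortality_by_age = default_mortality(),
                            nonmarital_age_multiplier = data.frame(age = 0, value = 1),
                            h_of_t = data.frame(time = 0, value = 1),
                            initial_population = 20000,
                            time_step_days = 7,
                            burn_in_years = 50,
                            horizon_years = 150,
                            min_partner_age = 15,
                            max_conception_age = 50,
                            hsr_method = c("pair", "child"),
                            hsr_scope = c("married_mothers", "all_children")) {
  p <- list(
    marriage_rate_alpha = marriage_rate_alpha,
    marital_duration_mean_years = marital_duration_mean_years,
    casual_duration_months = casual_duration_months,
    gestation_mean_days = gestation_mean_days,
    gestation_sd_days = gestation_sd_days,
    premarital_rate_mean = premarital_rate_mean,
    premarital_rate_var = premarital_rate_var,
    extramarital_rate_mean = extramarital_rate_mean,
    extramarital_rate_var = extramarital_rate_var,
    phi_m = phi_m,
    condom_coverage = condom_coverage,
    condom_efficacy = condom_efficacy,
    fecundability_by_age = as_age_table(fecundability_by_age, "fecundability_by_age"),
    coital_frequency_by_age = as_age_table(coital_frequency_by_age, "coital_frequency_by_age"),
    mortality_by_age = as_age_table(mortality_by_age, "mortality_by_age"),
    nonmarital_age_multiplier = as_age_table(nonmarital_age_multiplier,
                                             "nonmarital_age_multiplier"),
    h_of_t = as_time_table(h_of_t),
    initial_population = initial_population,
    time_step_days = time_step_days,
    burn_in_years = burn_in_years,
    horizon_years = horizon_years,
    min_partner_age = min_partner_age,
    max_conception_age = max_conception_age,
    hsr_method = match.arg(hsr_method),
    hsr_scope = match.arg(hsr_scope)
  )
  class(p) <- "np_params"
  validate_params(p)
}

#' The default (Kenya DHS-derived) scenario parameter set
#'
#' Equivalent to `scenario_params()` with no arguments: marriage rate
#' 0.12/year, mean marital duration 20 years, mean casual-partnership
#' duration 6 months, gestation N(267, 10^2) days, premarital partnership
#' rate mean 0.32 / variance 0.0087 per year, extramarital rate mean
#' 0.0088 / variance 0, phi_m = 0.7, condom coverage 0.23 (unmarried),
#' 0.019 (marital), 0.074 (extramarital), condom efficacy 0.90,
#' 20,000 women, 50-year burn-in.
#'
#' @return An `np_params` object.
#' @export
default_params <- function() scenario_params()

# stand-in age schedules; the sources behind the scenario are not published
# as tables, so these are editable defaults calibrated for a Kenya-like
# demographic regime (TFR ~ 5, e0 ~ 55-60, slow population growth).
default_fecundability <- function() {
  data.frame(age   = c(15, 20, 25, 30, 35, 40, 45, 50),
             value = c(0.0038, 0.0048, 0.0045, 0.0038, 0.0027,
                       0.0012, 0.00045, 0))
}

default_coital_frequency <- function() {
  data.frame(age   = c(15, 20, 25, 30, 35, 40, 45, 50),
             value = c(7, 8, 7.5, 6.5, 5.5, 4.5, 3.5, 3))
}

default_mortality <- function() {
  data.frame(age   = c(0, 1, 5, 15, 30, 45, 55, 65, 75, 85),
             value = c(0.07, 0.012, 0.003, 0.005, 0.007, 0.012,
                       0.025, 0.06, 0.13, 0.30))
}

as_age_table <- function(x, what) {
  if (!is.data.frame(x) || !all(c("age", "value") %in% names(x)))
    stop(sprintf("%s must be a data frame with columns 'age' and 'value'", what),
         call. = FALSE)
  x <- data.frame(age = as.numeric(x$age), value = as.numeric(x$value))
  x[order(x$age), , drop = FALSE]
}

as_time_table <- function(x) {
  if (!is.data.frame(x) || !all(c("time", "value") %in% names(x)))
    stop("h_of_t must be a data frame with columns 'time' and 'value'",
         call. = FALSE)
  x <- data.frame(time = as.numeric(x$time), value = as.numeric(x$value))
  x[order(x$time), , drop = FALSE]
}

#' Evaluate a step-function age schedule
#'
#' @param table A two-column (`age`, `value`) data frame as held in
#'   [scenario_params()].
#' @param age Numeric vector of ages in years.
#' @return Values of the step function; 0 below the first tabulated age,
#'   last value carried forward above the last.
#' @export
age_lookup <- function(table, age) {
  i <- findInterval(age, table$age)
  out <- numeric(length(age))
  ok <- i >= 1L
  out[ok] <- table$value[i[ok]]
  out
}

#' Evaluate the piecewise-linear time modifier h(t)
#'
#' @param params An `np_params` object (or its `h_of_t` table).
#' @param t_years Time(s) in years since the start of the simulation.
#' @return Values of h(t); constant extrapolation beyond the table's ends.
#' @export
h_lookup <- function(params, t_years) {
  tab <- if (inherits(params, "np_params")) params$h_of_t else params
  if (nrow(tab) == 1L) return(rep(tab$value, length(t_years)))
  stats::approx(tab$time, tab$value, xout = t_years, rule = 2)$y
}

#' Validate a scenario parameter set
#'
#' Checks nonnegativity of rates and durations, probability bounds,
#' coverage of the age schedules (fecundability/coital frequency over at
#' least ages 15-49, mortality from age 0), and nonnegativity of h(t).
#'
#' @param p An `np_params` object.
#' @return `p`, invisibly unchanged, if valid; otherwise an error naming
#'   the offending field.
#' @export
validate_params <- function(p) {
  chk <- function(cond, field, msg) {
    if (!isTRUE(cond))
      stop(sprintf("invalid parameter '%s': %s", field, msg), call. = FALSE)
  }
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  nn <- function(field) {
    chk(num1(p[[field]]) && p[[field]] >= 0, field, "must be a nonnegative number")
  }
  for (f in c("marriage_rate_alpha", "gestation_sd_days",
              "premarital_rate_mean", "premarital_rate_var",
              "extramarital_rate_mean", "extramarital_rate_var"))
    nn(f)
  for (f in c("marital_duration_mean_years", "casual_duration_months",
              "gestation_mean_days", "time_step_days"))
    chk(num1(p[[f]]) && p[[f]] > 0, f, "must be a positive number")
  chk(num1(p$phi_m) && p$phi_m > 0 && p$phi_m <= 1, "phi_m",
      "must lie in (0, 1]")
  chk(is.numeric(p$condom_coverage) &&
        all(c("unmarried", "marital", "extramarital") %in% names(p$condom_coverage)) &&
        all(p$condom_coverage >= 0 & p$condom_coverage <= 1),
      "condom_coverage",
      "must be a named vector (unmarried, marital, extramarital) with values in [0, 1]")
  chk(num1(p$condom_efficacy) && p$condom_efficacy >= 0 && p$condom_efficacy <= 1,
      "condom_efficacy", "must lie in [0, 1]")
  chk(all(p$fecundability_by_age$value >= 0 & p$fecundability_by_age$value <= 1),
      "fecundability_by_age", "per-act probabilities must lie in [0, 1]")
  chk(min(p$fecundability_by_age$age) <= 15, "fecundability_by_age",
      "must cover ages from 15 (values carry forward to older ages)")
  chk(all(p$coital_frequency_by_age$value >= 0), "coital_frequency_by_age",
      "acts per month must be nonnegative")
  chk(min(p$coital_frequency_by_age$age) <= 15, "coital_frequency_by_age",
      "must cover ages from 15")
  chk(all(p$mortality_by_age$value >= 0), "mortality_by_age",
      "hazards must be nonnegative")
  chk(min(p$mortality_by_age$age) <= 0, "mortality_by_age",
      "must cover ages from 0")
  chk(all(p$nonmarital_age_multiplier$value >= 0), "nonmarital_age_multiplier",
      "multipliers must be nonnegative")
  chk(all(p$h_of_t$value >= 0), "h_of_t", "h(t) must be nonnegative")
  chk(num1(p$initial_population) && p$initial_population >= 0 &&
        p$initial_population == round(p$initial_population),
      "initial_population", "must be a nonnegative integer")
  chk(num1(p$burn_in_years) && p$burn_in_years >= 0, "burn_in_years",
      "must be nonnegative")
  chk(num1(p$horizon_years) && p$horizon_years > 0, "horizon_years",
      "must be positive")
  chk(p$horizon_years >= p$burn_in_years, "horizon_years",
      "must be at least burn_in_years")
  invisible(p)
}

#' @export
print.np_params <- function(x, ...) {
  cat("Scenario parameters (np_params)\n")
  cat(sprintf("  marriage rate alpha      : %.4g /year\n", x$marriage_rate_alpha))
  cat(sprintf("  marital duration         : %.4g years\n", x$marital_duration_mean_years))
  cat(sprintf("  casual duration          : %.4g months\n", x$casual_duration_months))
  cat(sprintf("  premarital rate (mean,var): %.4g, %.4g /year\n",
              x$premarital_rate_mean, x$premarital_rate_var))
  cat(sprintf("  extramarital rate (mean,var): %.4g, %.4g /year\n",
              x$extramarital_rate_mean, x$extramarital_rate_var))
  cat(sprintf("  phi_m (marital act share): %.3g\n", x$phi_m))
  cat(sprintf("  gestation                : N(%.4g, %.4g^2) days\n",
              x$gestation_mean_days, x$gestation_sd_days))
  cat(sprintf("  condom coverage          : unmarried %.3g, marital %.3g, extramarital %.3g (Eff %.3g)\n",
              x$condom_coverage[["unmarried"]], x$condom_coverage[["marital"]],
              x$condom_coverage[["extramarital"]], x$condom_efficacy))
  cat(sprintf("  population / step        : %d women, %.3g-day steps\n",
              as.integer(x$initial_population), x$time_step_days))
  cat(sprintf("  horizon                  : %.4g years (%.4g burn-in)\n",
              x$horizon_years, x$burn_in_years))
  invisible(x)
}

#' Save and load scenario parameters (YAML)
#'
#' `save_params()` writes an `np_params` object to a YAML file;
#' `load_params()` reads one back, filling omitted optional fields
#' (`nonmarital_age_multiplier`, `h_of_t`) with their defaults and
#' validating the result.  `load_params(save_params(p))` reproduces `p`.
#'
#' @param params An `np_params` object.
#' @param path File path.
#' @return `load_params()` returns an `np_params` object; `save_params()`
#'   returns `path` invisibly.
#' @export
save_params <- function(params, path) {
  stopifnot(inherits(params, "np_params"))
  x <- unclass(params)
  x$condom_coverage <- as.list(x$condom_coverage)
  for (f in c("fecundability_by_age", "coital_frequency_by_age",
              "mortality_by_age", "nonmarital_age_multiplier"))
    x[[f]] <- list(age = x[[f]]$age, value = x[[f]]$value)
  x$h_of_t <- list(time = x$h_of_t$time, value = x$h_of_t$value)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname save_params
#' @export
load_params <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  x <- tryCatch(yaml::read_yaml(path),
                error = function(e) stop("cannot parse '", path, "': ",
                                         conditionMessage(e), call. = FALSE))
  if (!is.list(x)) stop("cannot parse '", path, "': not a mapping", call. = FALSE)
  args <- list()
  scalar_fields <- c("marriage_rate_alpha", "marital_duration_mean_years",
                     "casual_duration_months", "gestation_mean_days",
                     "gestation_sd_days", "premarital_rate_mean",
                     "premarital_rate_var", "extramarital_rate_mean",
                     "extramarital_rate_var", "phi_m", "condom_efficacy",
                     "initial_population", "time_step_days", "burn_in_years",
                     "horizon_years", "min_partner_age", "max_conception_age",
                     "hsr_method", "hsr_scope")
  for (f in scalar_fields) if (!is.null(x[[f]])) args[[f]] <- x[[f]]
  if (!is.null(x$condom_coverage))
    args$condom_coverage <- unlist(x$condom_coverage)
  for (f in c("fecundability_by_age", "coital_frequency_by_age",
              "mortality_by_age", "nonmarital_age_multiplier")) {
    if (!is.null(x[[f]])) {
      if (is.null(x[[f]]$age) || is.null(x[[f]]$value))
        stop("malformed field '", f, "' in '", path,
             "': needs 'age' and 'value' lists", call. = FALSE)
      args[[f]] <- data.frame(age = unlist(x[[f]]$age),
                              value = unlist(x[[f]]$value))
    }
  }
  if (!is.null(x$h_of_t)) {
    if (is.null(x$h_of_t$time) || is.null(x$h_of_t$value))
      stop("malformed field 'h_of_t' in '", path,
           "': needs 'time' and 'value' lists", call. = FALSE)
    args$h_of_t <- data.frame(time = unlist(x$h_of_t$time),
                              value = unlist(x$h_of_t$value))
  }
  do.call(scenario_params, args)
}

#' Draw scenario parameter sets across the Sub-Saharan Africa rate ranges
#'
#' For each draw, the means and variances of the premarital and
#' extramarital partnership rates are sampled uniformly and independently
#' from their cross-country ranges: premarital mean in \[0, 1\], premarital
#' variance in \[0, 2\], extramarital mean in \[0, 0.5\], extramarital
#' variance in \[0, 1\].  All other fields are copied from `base`.  Uses
#' R's global random number stream; call `set.seed()` for reproducibility.
#'
#' @param base An `np_params` object supplying every non-sampled field.
#' @param n Number of parameter sets to draw.
#' @return A list of `n` `np_params` objects.
#' @export
sample_sweep_params <- function(base = default_params(), n = 100) {
  stopifnot(inherits(base, "np_params"), n >= 1)
  lapply(seq_len(n), function(i) {
    b <- base
    b$premarital_rate_mean <- stats::runif(1, 0, 1)
    b$premarital_rate_var <- stats::runif(1, 0, 2)
    b$extramarital_rate_mean <- stats::runif(1, 0, 0.5)
    b$extramarital_rate_var <- stats::runif(1, 0, 1)
    b
  })
}
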