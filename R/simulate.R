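#' Run the individual-based partnering-and-conception simulation
#'
#' Simulates the female population forward from time 0 over
#' `params$horizon_years`: aging, death, marriage formation/dissolution,
#' premarital and extramarital partnership dynamics with
#' gamma-distributed individual rates, coital act allocation (a married
#' woman gives a fraction `phi_m` of acts to her spouse), conception with
#' age-specific fecundability and condom adjustment, normally distributed
#' gestation, and birth registration with putative/biological father
#' bookkeeping.  Newborn girls enter the population at birth, which makes
#' long scenario runs self-sustaining.
#'
#' Two engines implement identical per-step logic: `"compiled"` (C++, the
#' default; used for all experiment-scale runs) and `"r"` (the readable
#' reference implementation in [step_population()], practical only for
#' small populations).  Given the same seed a given engine is exactly
#' reproducible; the two engines agree statistically but draw random
#' numbers in different orders.
#'
#' @param params An `np_params` object, see [scenario_params()].
#' @param seed Integer seed (`set.seed`) applied before initialisation;
#'   `NULL` continues the current RNG stream.
#' @param engine `"compiled"` or `"r"`.
#' @return An object of class `np_sim` with components:
#'   \describe{
#'     \item{registry}{Birth registry data frame: `child_id`, `mother_id`,
#'       `bio_father_id`, `putative_father_id` (`NA` when the mother was
#'       unmarried at conception), `birth_day`, `gestation_days`,
#'       `nonpaternity`, `sex` (`"F"`/`"M"`), `death_day` (`NA` if alive at
#'       the end), `woman_idx`.}
#'     \item{plog}{Partnership log: `woman_id`, `partner_id`, `class`,
#'       `start_day`, `end_day` (`NA` if open at the end).}
#'     \item{women}{Per-woman summary: `birth_day`, `death_day`,
#'       `married` (at the end), `lam_p`, `lam_e`.}
#'     \item{params, seed, engine, final_day}{Run metadata.}
#'   }
#' @export
run_simulation <- function(params = default_params(), seed = NULL,
                           engine = c("compiled", "r")) {
  validate_params(params)
  engine <- match.arg(engine)
  if (!is.null(seed)) set.seed(seed)
  st <- init_population(params)
  if (engine == "r") {
    steps <- ceiling(params$horizon_years * DAYS_PER_YEAR / params$time_step_days)
    for (s in seq_len(steps)) st <- step_population(st, params)
    registry <- registry_as_df(st$registry)
    plog <- plog_as_df(st$plog)
    women <- data.frame(birth_day = st$women$birth_day,
                        death_day = st$women$death_day,
                        married = st$women$married,
                        lam_p = st$women$lam_p, lam_e = st$women$lam_e)
    final_day <- st$t
  } else {
    res <- sim_core(pack_params(params),
                    st$women$birth_day, st$women$married,
                    st$women$husband, st$women$lam_p, st$women$lam_e,
                    st$next_male)
    reg <- res$registry
    registry <- registry_as_df(list(
      mother_id = reg$mother_id, bio_father_id = reg$bio_father_id,
      putative_father_id = reg$putative_father_id, birth_day = reg$birth_day,
      gestation_days = reg$gestation_days, nonpaternity = reg$nonpaternity,
      sex = ifelse(reg$female, "F", "M"), death_day = reg$death_day,
      woman_idx = reg$woman_idx))
    plog <- plog_as_df(res$plog)
    women <- data.frame(birth_day = res$women$birth_day,
                        death_day = res$women$death_day,
                        married = res$women$married,
                        lam_p = res$women$lam_p, lam_e = res$women$lam_e)
    final_day <- res$final_day
  }
  structure(list(registry = registry, plog = plog, women = women,
                 params = params, seed = seed, engine = engine,
                 final_day = final_day),
            class = "np_sim")
}

pack_params <- function(p) {
  list(time_step_days = p$time_step_days,
       horizon_years = p$horizon_years,
       alpha = p$marriage_rate_alpha,
       mu_marital = 1 / p$marital_duration_mean_years,
       mu_casual = 12 / p$casual_duration_months,
       gest_mean = p$gestation_mean_days,
       gest_sd = p$gestation_sd_days,
       phi_m = p$phi_m,
       eff = p$condom_efficacy,
       cv_unmarried = p$condom_coverage[["unmarried"]],
       cv_marital = p$condom_coverage[["marital"]],
       cv_extramarital = p$condom_coverage[["extramarital"]],
       min_partner_age = p$min_partner_age,
       max_conception_age = p$max_conception_age,
       lam_p_mean = p$premarital_rate_mean,
       lam_p_var = p$premarital_rate_var,
       lam_e_mean = p$extramarital_rate_mean,
       lam_e_var = p$extramarital_rate_var,
       fecundability = p$fecundability_by_age,
       coital_frequency = p$coital_frequency_by_age,
       mortality = p$mortality_by_age,
       age_multiplier = p$nonmarital_age_multiplier,
       h_of_t = p$h_of_t)
}

registry_as_df <- function(r) {
  n <- length(r$mother_id)
  data.frame(child_id = seq_len(n),
             mother_id = r$mother_id,
             bio_father_id = r$bio_father_id,
             putative_father_id = r$putative_father_id,
             birth_day = r$birth_day,
             gestation_days = r$gestation_days,
             nonpaternity = r$nonpaternity,
             sex = as.character(r$sex),
             death_day = r$death_day,
             woman_idx = r$woman_idx)
}

plog_as_df <- function(l) {
  data.frame(woman_id = l$woman_id,
             partner_id = l$partner_id,
             class = CLASS_LEVELS[l$class],
             start_day = l$start_day,
             end_day = l$end_day)
}

#' Annual measure series from a simulation
#'
#' Evaluates NPR(t), EPR(t) and HSR(t) on the annual census grid
#' (t = 1, 2, ... years).  Undefined ratios (empty denominators) are
#' `NA`.
#'
#' @param sim An `np_sim` object.
#' @param years Census years; default every full year of the run.
#' @return Data frame with columns `year`, `npr`, `epr`, `hsr`.
#' @export
measure_series <- function(sim, years = NULL) {
  stopifnot(inherits(sim, "np_sim"))
  if (is.null(years)) years <- seq_len(floor(sim$params$horizon_years))
  td <- years * DAYS_PER_YEAR
  data.frame(
    year = years,
    npr = vapply(td, function(t) compute_npr(sim$registry, t), numeric(1)),
    epr = vapply(td, function(t) compute_epr(sim$plog, t), numeric(1)),
    hsr = vapply(td, function(t) compute_hsr(sim$registry, t,
                                             sim$params$hsr_method,
                                             sim$params$hsr_scope),
                 numeric(1)))
}

#' Age-specific nonpaternity profiles at census times
#'
#' @param sim An `np_sim` object.
#' @param years Census years at which to take the cross-sectional
#'   NPR_x profile.
#' @param ages Integer age bands (default 0-50).
#' @return Matrix of NPR_x values, one row per census year, one column
#'   per age band.
#' @export
npr_profiles <- function(sim, years, ages = 0:50) {
  stopifnot(inherits(sim, "np_sim"))
  out <- t(vapply(years,
                  function(y) compute_npr_profile(sim$registry,
                                                  y * DAYS_PER_YEAR, ages),
                  numeric(length(ages))))
  rownames(out) <- years
  out
}

#' @export
print.np_sim <- function(x, ...) {
  cat("Individual-based partnering/conception simulation (np_sim)\n")
  cat(sprintf("  engine %s, %.4g years simulated, seed %s\n", x$engine,
              x$final_day / DAYS_PER_YEAR,
              if (is.null(x$seed)) "<none>" else format(x$seed)))
  cat(sprintf("  women: %d total, %d alive at end\n",
              nrow(x$women), sum(is.na(x$women$death_day))))
  cat(sprintf("  births: %d (%d nonpaternity events)\n",
              nrow(x$registry), sum(x$registry$nonpaternity)))
  cat(sprintf("  partnership episodes: %d\n", nrow(x$plog)))
  invisible(x)
}

#' @export
summary.np_sim <- function(object, ...) {
  s <- measure_series(object)
  end <- utils::tail(stats::na.omit(s), 1)
  out <- list(sim = object, series = s, end = end)
  class(out) <- "summary.np_sim"
  out
}

#' @export
print.summary.np_sim <- function(x, ...) {
  print(x$sim)
  if (nrow(x$end)) {
    cat(sprintf("  final census (year %d): NPR %.4f, EPR %.4f, HSR %.4f\n",
                as.integer(x$end$year), x$end$npr, x$end$epr, x$end$hsr))
  }
  invisible(x)
}

#' @export
plot.np_sim <- function(x, which = c("npr", "epr", "hsr"), ...) {
  s <- measure_series(x)
  which <- match.arg(which, several.ok = TRUE)
  cols <- c(npr = "firebrick", epr = "steelblue", hsr = "darkgreen")
  graphics::matplot(s$year, as.matrix(s[which]), type = "l", lty = 1,
                    col = cols[which], xlab = "year", ylab = "ratio", ...)
  graphics::legend("topleft", legend = toupper(which), col = cols[which],
                   lty = 1, bty = "n")
  invisible(s)
}

#' Export the birth registry / partnership log as CSV
#'
#' The registry CSV carries the standalone-analysis schema (`child_id`,
#' `mother_id`, `bio_father_id`, `putative_father_id`, `birth_day`,
#' `nonpaternity`, `alive`) plus `death_day`, `gestation_days` and `sex`;
#' files written here can be read back with `read.csv()` and fed directly
#' to [compute_npr()], [compute_npr_x()], [compute_hsr()] and
#' [compute_epr()].
#'
#' @param sim An `np_sim` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_registry <- function(sim, path) {
  r <- sim$registry
  r$alive <- is.na(r$death_day)
  utils::write.csv(r[c("child_id", "mother_id", "bio_father_id",
                       "putative_father_id", "birth_day", "nonpaternity",
                       "alive", "death_day", "gestation_days", "sex")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname export_registry
#' @export
export_plog <- function(sim, path) {
  utils::write.csv(sim$plog, path, row.names = FALSE)
  invisible(path)
}
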