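# ---------------------------------------------------------------------------
# Reference (pure-R) engine: population state and per-step demographic and
# partnership dynamics.  The compiled engine in src/sim_core.cpp implements
# the same per-step logic; this version is the readable specification of it
# and is used directly by the unit tests (engine = "r" in run_simulation()).
#
# State layout (class "np_state"): parallel vectors inside three lists --
#   women : birth_day, death_day (NA while alive), married, husband,
#           mar_row (open marital log row), gestating, due, gest_start,
#           gf (biological father token), gf_husband (husband at conception,
#           NA if unmarried then), lam_p, lam_e, reg_row (registry row for
#           simulation-born girls)
#   registry : one row per birth (both sexes), columns as documented in
#           run_simulation()
#   plog  : partnership episodes; class codes 1 = marital, 2 = premarital,
#           3 = extramarital (frozen at formation)
# Male partners are identity tokens only (counter starting at 10^7), fresh
# per nonmarital partnership; a husband token persists for the marriage.
# ---------------------------------------------------------------------------

MALE_TOKEN_BASE <- 10000000L
CLASS_LEVELS <- c("marital", "premarital", "extramarital")

#' Initialise a population state
#'
#' Creates `initial_population` women with ages drawn from the stationary
#' age distribution implied by the mortality schedule, marital status
#' seeded from the closed-form two-state marriage prevalence at each age
#' (so the burn-in converges quickly), and individual nonmarital
#' partnering rates drawn via [draw_rate()].  Pre-existing marriages are
#' logged as episodes starting at day 0.
#'
#' @param params An `np_params` object.
#' @return An object of class `np_state` (see source for layout).
#' @export
init_population <- function(params) {
  n <- as.integer(params$initial_population)
  ages <- if (n > 0) sample_stationary_ages(params, n) else numeric(0)
  mu <- 1 / params$marital_duration_mean_years
  pmar <- married_prevalence(params$marriage_rate_alpha, mu, ages,
                             params$min_partner_age)
  married <- stats::runif(n) < pmar
  husband <- rep(NA_integer_, n)
  n_mar <- sum(married)
  if (n_mar > 0) husband[married] <- MALE_TOKEN_BASE + seq_len(n_mar)
  st <- list(
    t = 0,
    women = list(
      birth_day = -ages * DAYS_PER_YEAR,
      death_day = rep(NA_real_, n),
      married = married,
      husband = husband,
      mar_row = rep(NA_integer_, n),
      gestating = rep(FALSE, n),
      due = rep(NA_real_, n),
      gest_start = rep(NA_real_, n),
      gf = rep(NA_integer_, n),
      gf_husband = rep(NA_integer_, n),
      lam_p = draw_rate(n, params$premarital_rate_mean, params$premarital_rate_var),
      lam_e = draw_rate(n, params$extramarital_rate_mean, params$extramarital_rate_var),
      reg_row = rep(NA_integer_, n)
    ),
    registry = list(
      mother_id = integer(0), bio_father_id = integer(0),
      putative_father_id = integer(0), birth_day = numeric(0),
      gestation_days = numeric(0), nonpaternity = logical(0),
      sex = character(0), death_day = numeric(0), woman_idx = integer(0)
    ),
    plog = list(
      woman_id = integer(0), partner_id = integer(0), class = integer(0),
      start_day = numeric(0), end_day = numeric(0)
    ),
    active = integer(0),                     # open nonmarital plog rows
    next_male = MALE_TOKEN_BASE + n_mar + 1L
  )
  if (n_mar > 0) {
    w <- which(married)
    st$plog <- list(woman_id = w, partner_id = husband[w],
                    class = rep(1L, n_mar), start_day = rep(0, n_mar),
                    end_day = rep(NA_real_, n_mar))
    st$women$mar_row[w] <- seq_len(n_mar)
  }
  class(st) <- "np_state"
  st
}

# stationary (mortality-only) age distribution: density proportional to the
# survivorship curve l(a) on a quarter-year grid up to age 90
sample_stationary_ages <- function(params, n) {
  grid <- seq(0, 90, by = 0.25)
  haz <- age_lookup(params$mortality_by_age, grid)
  surv <- exp(-cumsum(haz * 0.25))
  grid[sample.int(length(grid), n, replace = TRUE, prob = surv)] +
    stats::runif(n, 0, 0.25)
}

women_age <- function(state, params) {
  (state$t - state$women$birth_day) / DAYS_PER_YEAR
}

n_alive <- function(state) sum(is.na(state$women$death_day))

append_plog <- function(state, woman, partner, class, start) {
  k <- length(woman)
  state$plog$woman_id <- c(state$plog$woman_id, woman)
  state$plog$partner_id <- c(state$plog$partner_id, partner)
  state$plog$class <- c(state$plog$class, rep(class, k))
  state$plog$start_day <- c(state$plog$start_day, rep(start, k))
  state$plog$end_day <- c(state$plog$end_day, rep(NA_real_, k))
  state
}

close_marriage <- function(state, w, t) {
  r <- state$women$mar_row[w]
  state$plog$end_day[r] <- t
  state$women$married[w] <- FALSE
  state$women$husband[w] <- NA_integer_
  state$women$mar_row[w] <- NA_integer_
  state
}

#' Advance deaths by one time step (reference engine)
#'
#' Every woman and every registered child dies over the step with
#' probability `1 - exp(-d(age) * dt)`.  A woman's death closes her open
#' marital and nonmarital episodes in the partnership log at the current
#' time and cancels any ongoing gestation.
#'
#' @param state An `np_state` object.
#' @param params An `np_params` object.
#' @return The updated state.
#' @export
step_demography <- function(state, params) {
  dtY <- params$time_step_days / DAYS_PER_YEAR
  t <- state$t
  alive <- is.na(state$women$death_day)
  idx <- which(alive)
  if (length(idx)) {
    age <- (t - state$women$birth_day[idx]) / DAYS_PER_YEAR
    p <- 1 - exp(-age_lookup(params$mortality_by_age, age) * dtY)
    dead <- idx[stats::runif(length(idx)) < p]
    for (w in dead) {
      state$women$death_day[w] <- t
      if (state$women$married[w]) state <- close_marriage(state, w, t)
      if (length(state$active)) {
        mine <- state$active[state$plog$woman_id[state$active] == w]
        if (length(mine)) {
          state$plog$end_day[mine] <- t
          state$active <- setdiff(state$active, mine)
        }
      }
      state$women$gestating[w] <- FALSE
      if (!is.na(state$women$reg_row[w]))
        state$registry$death_day[state$women$reg_row[w]] <- t
    }
  }
  # boys live only in the registry
  boys <- which(state$registry$sex == "M" & is.na(state$registry$death_day))
  if (length(boys)) {
    age <- (t - state$registry$birth_day[boys]) / DAYS_PER_YEAR
    p <- 1 - exp(-age_lookup(params$mortality_by_age, age) * dtY)
    state$registry$death_day[boys[stats::runif(length(boys)) < p]] <- t
  }
  state
}

#' Advance partnership dynamics by one time step (reference engine)
#'
#' In order: (1) existing marriages dissolve with probability
#' `1 - exp(-mu_marital * dt)`; (2) eligible unmarried women (age >
#' `min_partner_age`) marry with probability `1 - exp(-alpha * dt)`
#' (remarriage uses the same rate), and marriage closes the bride's open
#' nonmarital partnerships, so a married woman's active partners are
#' exactly her extramarital ones; (3) open nonmarital partnerships
#' dissolve with probability `1 - exp(-mu_casual * dt)`; (4) women above
#' the eligibility age form new nonmarital partnerships with per-step
#' probability derived from their individual rate (`lam_p` if unmarried,
#' `lam_e` if married) times `h(t)` and the age multiplier.  Every episode
#' is logged; new partners get fresh identity tokens; episode class is
#' frozen at formation.
#'
#' @inheritParams step_demography
#' @return The updated state.
#' @export
step_partnerships <- function(state, params) {
  dtY <- params$time_step_days / DAYS_PER_YEAR
  t <- state$t
  alive <- is.na(state$women$death_day)
  age <- women_age(state, params)

  # (1) marital dissolution
  mu_m <- 1 / params$marital_duration_mean_years
  mar <- which(alive & state$women$married)
  if (length(mar)) {
    div <- mar[stats::runif(length(mar)) < 1 - exp(-mu_m * dtY)]
    for (w in div) state <- close_marriage(state, w, t)
  }

  # (2) marriage formation
  elig <- which(alive & !state$women$married & age > params$min_partner_age)
  if (length(elig)) {
    wed <- elig[stats::runif(length(elig)) <
                  1 - exp(-params$marriage_rate_alpha * dtY)]
    if (length(wed)) {
      hus <- state$next_male + seq_along(wed) - 1L
      state$next_male <- state$next_male + length(wed)
      state$women$married[wed] <- TRUE
      state$women$husband[wed] <- hus
      state <- append_plog(state, wed, hus, 1L, t)
      state$women$mar_row[wed] <-
        length(state$plog$woman_id) - length(wed) + seq_along(wed)
      # marriage closes the bride's open nonmarital partnerships
      gone <- state$active[state$plog$woman_id[state$active] %in% wed]
      if (length(gone)) {
        state$plog$end_day[gone] <- t
        state$active <- setdiff(state$active, gone)
      }
    }
  }

  # (3) nonmarital dissolution
  mu_c <- 12 / params$casual_duration_months
  if (length(state$active)) {
    gone <- stats::runif(length(state$active)) < 1 - exp(-mu_c * dtY)
    state$plog$end_day[state$active[gone]] <- t
    state$active <- state$active[!gone]
  }

  # (4) nonmarital formation
  ht <- h_lookup(params, t / DAYS_PER_YEAR)
  adult <- which(alive & age > params$min_partner_age)
  if (length(adult) && ht > 0) {
    lam <- ifelse(state$women$married[adult],
                  state$women$lam_e[adult], state$women$lam_p[adult])
    lam <- lam * ht * age_lookup(params$nonmarital_age_multiplier, age[adult])
    form <- adult[stats::runif(length(adult)) < 1 - exp(-lam * dtY)]
    if (length(form)) {
      pid <- state$next_male + seq_along(form) - 1L
      state$next_male <- state$next_male + length(form)
      cls <- ifelse(state$women$married[form], 3L, 2L)
      r0 <- length(state$plog$woman_id)
      state$plog$woman_id <- c(state$plog$woman_id, form)
      state$plog$partner_id <- c(state$plog$partner_id, pid)
      state$plog$class <- c(state$plog$class, cls)
      state$plog$start_day <- c(state$plog$start_day, rep(t, length(form)))
      state$plog$end_day <- c(state$plog$end_day, rep(NA_real_, length(form)))
      state$active <- c(state$active, r0 + seq_along(form))
    }
  }
  state
}
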