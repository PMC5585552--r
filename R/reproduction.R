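#' Per-coital-act conception probability
#'
#' `f(age) * (1 - Eff * Cv(class))`: the age-specific fecundability
#' reduced proportionally by condom efficacy times the partnership-class
#' condom use coverage.  Ages outside the fecundability table (or at/after
#' `max_conception_age`) give 0.
#'
#' @param age Woman's age in years.
#' @param class Partnership class: `"marital"`, `"premarital"` or
#'   `"extramarital"` (the coverage class follows the woman's current
#'   marital status, `"unmarried"` coverage applying to premarital acts).
#' @param params An `np_params` object.
#' @return Probability in \[0, 1\].
#' @export
conception_prob_per_act <- function(age, class, params) {
  cv <- switch(class,
               marital = params$condom_coverage[["marital"]],
               premarital = params$condom_coverage[["unmarried"]],
               extramarital = params$condom_coverage[["extramarital"]],
               stop("unknown partnership class: ", class, call. = FALSE))
  if (age >= params$max_conception_age) return(0)
  f <- age_lookup(params$fecundability_by_age, age)
  f * (1 - params$condom_efficacy * cv)
}

#' Allocate one step's coital acts across a woman's partners
#'
#' The total number of acts is Poisson with mean `c(age) * dt` (coital
#' frequency per month scaled to the step).  A married woman with at
#' least one active extramarital partner gives each act to her spouse
#' with probability `phi_m`, the remainder split uniformly among the
#' extramarital partners; with no extramarital partner all acts are
#' marital.  An unmarried woman splits acts uniformly among her active
#' premarital partners; with no partner the allocation is empty.
#'
#' @param age Woman's age in years.
#' @param married Logical: currently married?
#' @param husband Husband token (ignored unless married).
#' @param partners Integer vector of active nonmarital partner tokens.
#' @param params An `np_params` object.
#' @param dt_days Step length in days.
#' @return Data frame with columns `partner_id`, `n_acts`, `class`.
#' @export
allocate_acts <- function(age, married, husband, partners, params,
                          dt_days = params$time_step_days) {
  k <- length(partners)
  if (!married && k == 0L)
    return(data.frame(partner_id = integer(0), n_acts = integer(0),
                      class = character(0)))
  n <- stats::rpois(1, age_lookup(params$coital_frequency_by_age, age) *
                      dt_days / 30.4375)
  if (married) {
    if (k == 0L)
      return(data.frame(partner_id = husband, n_acts = n, class = "marital"))
    n_sp <- stats::rbinom(1, n, params$phi_m)
    n_em <- as.integer(stats::rmultinom(1, n - n_sp, rep(1, k)))
    data.frame(partner_id = c(husband, partners),
               n_acts = c(n_sp, n_em),
               class = c("marital", rep("extramarital", k)))
  } else {
    n_pm <- as.integer(stats::rmultinom(1, n, rep(1, k)))
    data.frame(partner_id = partners, n_acts = n_pm,
               class = rep("premarital", k))
  }
}

#' Attempt conceptions for one time step (reference engine)
#'
#' For every alive, non-gestating woman of reproductive age, acts are
#' allocated with [allocate_acts()] and each partner contributes a
#' conception chance `1 - (1 - p)^n` with `p` from
#' [conception_prob_per_act()].  Partners are tried in randomised order
#' and the first success sets the gestation state (at most one conception
#' per woman per step): the conceiving partner becomes the biological
#' father, the husband at conception (if any) the putative father, and
#' the due date is the conception day plus `max(1, round(N(mean, sd)))`
#' gestation days.
#'
#' @inheritParams step_demography
#' @return The updated state.
#' @export
attempt_conceptions <- function(state, params) {
  t <- state$t
  age <- women_age(state, params)
  cand <- which(is.na(state$women$death_day) & !state$women$gestating &
                  age >= params$min_partner_age &
                  age < params$max_conception_age)
  if (!length(cand)) return(state)
  part_of <- split(state$plog$partner_id[state$active],
                   state$plog$woman_id[state$active])
  for (w in cand) {
    partners <- part_of[[as.character(w)]]
    if (is.null(partners)) partners <- integer(0)
    acts <- allocate_acts(age[w], state$women$married[w],
                          state$women$husband[w], partners, params)
    acts <- acts[acts$n_acts > 0, , drop = FALSE]
    if (!nrow(acts)) next
    for (i in sample.int(nrow(acts))) {
      p <- conception_prob_per_act(age[w], acts$class[i], params)
      if (stats::runif(1) < 1 - (1 - p)^acts$n_acts[i]) {
        gest <- max(1, round(stats::rnorm(1, params$gestation_mean_days,
                                          params$gestation_sd_days)))
        state$women$gestating[w] <- TRUE
        state$women$gest_start[w] <- t
        state$women$due[w] <- t + gest
        state$women$gf[w] <- acts$partner_id[i]
        state$women$gf_husband[w] <-
          if (state$women$married[w]) state$women$husband[w] else NA_integer_
        break
      }
    }
  }
  state
}

#' Deliver due births for one time step (reference engine)
#'
#' Women whose due date has been reached produce one birth record, dated
#' at the exact due day.  The nonpaternity flag is true iff the mother
#' was married at conception and the biological father differs from her
#' husband at conception (marital status at conception, not at birth,
#' governs).  Sex is assigned 1:1; girls enter the female population at
#' birth with freshly drawn individual partnering rates and become
#' eligible to partner at the minimum partnering age.
#'
#' @inheritParams step_demography
#' @return The updated state.
#' @export
deliver_births <- function(state, params) {
  due <- which(is.na(state$women$death_day) & state$women$gestating &
                 state$women$due <= state$t)
  for (w in due) {
    bday <- state$women$due[w]
    bio <- state$women$gf[w]
    put <- state$women$gf_husband[w]
    nonpat <- !is.na(put) && bio != put
    female <- stats::runif(1) < 0.5
    r <- length(state$registry$mother_id) + 1L
    state$registry$mother_id[r] <- w
    state$registry$bio_father_id[r] <- bio
    state$registry$putative_father_id[r] <- put
    state$registry$birth_day[r] <- bday
    state$registry$gestation_days[r] <- bday - state$women$gest_start[w]
    state$registry$nonpaternity[r] <- nonpat
    state$registry$sex[r] <- if (female) "F" else "M"
    state$registry$death_day[r] <- NA_real_
    state$registry$woman_idx[r] <- NA_integer_
    if (female) {
      g <- length(state$women$birth_day) + 1L
      state$women$birth_day[g] <- bday
      state$women$death_day[g] <- NA_real_
      state$women$married[g] <- FALSE
      state$women$husband[g] <- NA_integer_
      state$women$mar_row[g] <- NA_integer_
      state$women$gestating[g] <- FALSE
      state$women$due[g] <- NA_real_
      state$women$gest_start[g] <- NA_real_
      state$women$gf[g] <- NA_integer_
      state$women$gf_husband[g] <- NA_integer_
      state$women$lam_p[g] <- draw_rate(1, params$premarital_rate_mean,
                                        params$premarital_rate_var)
      state$women$lam_e[g] <- draw_rate(1, params$extramarital_rate_mean,
                                        params$extramarital_rate_var)
      state$women$reg_row[g] <- r
      state$registry$woman_idx[r] <- g
    }
    state$women$gestating[w] <- FALSE
    state$women$due[w] <- NA_real_
    state$women$gest_start[w] <- NA_real_
    state$women$gf[w] <- NA_integer_
    state$women$gf_husband[w] <- NA_integer_
  }
  state
}

#' Advance the reference engine by one full time step
#'
#' Applies, in order, [step_demography()], [step_partnerships()],
#' [attempt_conceptions()] and [deliver_births()], then advances the
#' clock by one step.
#'
#' @inheritParams step_demography
#' @return The updated state.
#' @export
step_population <- function(state, params) {
  state <- step_demography(state, params)
  state <- step_partnerships(state, params)
  state <- attempt_conceptions(state, params)
  state$t <- state$t + params$time_step_days
  state <- deliver_births(state, params)
  state
}
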