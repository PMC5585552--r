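test_that("per-act conception probability composes fecundability and condoms", {
  p <- scenario_params(fecundability_by_age = data.frame(age = c(15, 50),
                                                         value = c(0.03, 0)))
  expect_equal(conception_prob_per_act(25, "marital", p),
               0.03 * (1 - 0.9 * 0.019))          # = 0.029487
  expect_equal(conception_prob_per_act(25, "marital", p), 0.029487)
  expect_equal(conception_prob_per_act(25, "premarital", p),
               0.03 * (1 - 0.9 * 0.23))
  expect_equal(conception_prob_per_act(25, "extramarital", p),
               0.03 * (1 - 0.9 * 0.074))
  # no condom effect when either efficacy or coverage is zero
  p0 <- scenario_params(condom_efficacy = 0,
                        fecundability_by_age = data.frame(age = c(15, 50),
                                                          value = c(0.03, 0)))
  expect_equal(conception_prob_per_act(25, "marital", p0), 0.03)
  # full coverage at full efficacy blocks conception entirely
  p1 <- scenario_params(condom_efficacy = 1,
                        condom_coverage = c(unmarried = 1, marital = 1,
                                            extramarital = 1),
                        fecundability_by_age = data.frame(age = c(15, 50),
                                                          value = c(0.03, 0)))
  expect_equal(conception_prob_per_act(25, "marital", p1), 0)
  # outside the fertile ages the probability is zero
  expect_equal(conception_prob_per_act(55, "marital", p), 0)
  expect_equal(conception_prob_per_act(10, "marital", p), 0)
  expect_error(conception_prob_per_act(25, "platonic", p), "unknown")
})

test_that("act allocation honors marital status and phi_m", {
  p <- default_params()
  set.seed(60)
  # married, no extramarital partner: every act is marital
  a <- allocate_acts(25, TRUE, 7L, integer(0), p)
  expect_equal(a$class, "marital")
  # unmarried with no partner: no allocation
  expect_equal(nrow(allocate_acts(25, FALSE, NA, integer(0), p)), 0)
  # married + 1 extramarital partner: spouse share converges to phi_m
  sp <- em <- 0
  for (i in 1:4000) {
    a <- allocate_acts(25, TRUE, 7L, 101L, p)
    sp <- sp + a$n_acts[a$class == "marital"]
    em <- em + sum(a$n_acts[a$class == "extramarital"])
  }
  share <- sp / (sp + em)
  expect_lt(abs(share - 0.7), 3 * sqrt(0.7 * 0.3 / (sp + em)))
  # unmarried with partners: acts split among them, premarital class
  a <- allocate_acts(25, FALSE, NA, c(101L, 102L), p)
  expect_setequal(a$class, "premarital")
  expect_setequal(a$partner_id, c(101L, 102L))
})

test_that("step conception probability matches the Poisson-thinned closed form", {
  # acts N ~ Poisson(mu), per-act probability q: P(conceive) = 1 - e^(-mu q)
  p <- scenario_params(
    fecundability_by_age = data.frame(age = c(15, 50), value = c(0.02, 0)),
    condom_efficacy = 0,
    coital_frequency_by_age = flat_table(7.5, age = 15))
  set.seed(61)
  st <- make_state(ages = rep(25, 3000), married = rep(TRUE, 3000))
  st <- attempt_conceptions(st, p)
  mu <- 7.5 * 7 / 30.4375
  q_exp <- 1 - exp(-mu * 0.02)
  q_obs <- mean(st$women$gestating)
  expect_lt(abs(q_obs - q_exp), 3 * sqrt(q_exp * (1 - q_exp) / 3000))
  # conceiving partner is the spouse; putative father recorded
  g <- which(st$women$gestating)
  expect_equal(st$women$gf[g], st$women$husband[g])
  expect_equal(st$women$gf_husband[g], st$women$husband[g])
})

test_that("gestating women cannot conceive again", {
  p <- scenario_params(fecundability_by_age = data.frame(age = c(15, 50),
                                                         value = c(1, 0)),
                       condom_efficacy = 0)
  set.seed(62)
  st <- make_state(ages = rep(30, 50), married = rep(TRUE, 50))
  st$women$gestating[] <- TRUE
  st$women$due[] <- 1000
  st$women$gest_start[] <- -10
  st$women$gf[] <- 999L
  before <- st$women
  st <- attempt_conceptions(st, p)
  expect_identical(st$women$gf, before$gf)
  expect_identical(st$women$due, before$due)
})

test_that("nonpaternity is fixed by marital status at conception", {
  p <- scenario_params(fecundability_by_age = data.frame(age = c(15, 50),
                                                         value = c(1, 0)),
                       condom_efficacy = 0,
                       coital_frequency_by_age = flat_table(500, age = 15))
  set.seed(63)
  # spouse conception: not a nonpaternity event
  st <- make_state(ages = 25, married = TRUE)
  st <- attempt_conceptions(st, p)
  expect_true(st$women$gestating[1])
  st$t <- st$women$due[1] + 1
  st <- deliver_births(st, p)
  expect_false(st$registry$nonpaternity[1])
  expect_equal(st$registry$putative_father_id[1], st$registry$bio_father_id[1])
  # extramarital conception while married: nonpaternity
  st <- make_state(ages = 25, married = TRUE)
  st$women$lam_e[1] <- 0
  st <- add_partner(st, 1L)
  # force all acts to the extramarital partner
  p_em <- p; p_em$phi_m <- 1e-12
  st <- attempt_conceptions(st, p_em)
  expect_true(st$women$gestating[1])
  expect_false(st$women$gf[1] == st$women$husband[1])
  st$t <- st$women$due[1] + 1
  st <- deliver_births(st, p_em)
  expect_true(st$registry$nonpaternity[1])
  # premarital conception, marriage during gestation: status at conception
  # governs, so not a nonpaternity event and no putative father
  st <- make_state(ages = 25, married = FALSE)
  st <- add_partner(st, 1L)
  st <- attempt_conceptions(st, p)
  expect_true(st$women$gestating[1])
  st$women$married[1] <- TRUE          # marries while pregnant
  st$women$husband[1] <- 424242L
  st$t <- st$women$due[1] + 1
  st <- deliver_births(st, p)
  expect_false(st$registry$nonpaternity[1])
  expect_true(is.na(st$registry$putative_father_id[1]))
})

test_that("registry bookkeeping is internally consistent in a full run", {
  p <- scenario_params(initial_population = 800, horizon_years = 25,
                       burn_in_years = 0, extramarital_rate_mean = 0.3,
                       extramarital_rate_var = 0.3,
                       premarital_rate_mean = 0.5, premarital_rate_var = 0.2)
  sim <- run_simulation(p, seed = 64)
  reg <- sim$registry
  expect_gt(nrow(reg), 500)
  # nonpaternity iff a putative father exists and differs from the
  # biological father; unmarried conceptions are never nonpaternity
  expect_identical(reg$nonpaternity,
                   !is.na(reg$putative_father_id) &
                     reg$putative_father_id != reg$bio_father_id)
  # some of each: marital, extramarital and premarital conceptions
  expect_gt(sum(reg$nonpaternity), 0)
  expect_gt(sum(is.na(reg$putative_father_id)), 0)
  expect_gt(sum(!is.na(reg$putative_father_id) & !reg$nonpaternity), 0)
  # biological fathers of in-wedlock non-events are the husbands
  ok <- !is.na(reg$putative_father_id) & !reg$nonpaternity
  expect_true(all(reg$bio_father_id[ok] == reg$putative_father_id[ok]))
})

test_that("phi_m = 1 means married women never bear nonpaternity children", {
  p <- scenario_params(initial_population = 600, horizon_years = 20,
                       burn_in_years = 0, phi_m = 1,
                       extramarital_rate_mean = 2, extramarital_rate_var = 0)
  sim <- run_simulation(p, seed = 65)
  expect_gt(nrow(sim$registry), 100)
  expect_equal(sum(sim$registry$nonpaternity), 0)
})

test_that("realized gestation lengths match the normal model", {
  p <- scenario_params(initial_population = 2000, horizon_years = 30,
                       burn_in_years = 0)
  sim <- run_simulation(p, seed = 66)
  g <- sim$registry$gestation_days
  expect_gt(length(g), 2000)
  expect_lt(abs(mean(g) - 267), 3 * 10 / sqrt(length(g)))
  expect_lt(abs(sd(g) - 10) / 10, 0.05)
})
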