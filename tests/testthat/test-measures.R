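YEAR <- 365.25

test_that("nonpaternity ratio counts births in the trailing 12 months", {
  fx <- generate_fixture_registry(n_births = 8, n_nonpaternity = 2)
  expect_equal(compute_npr(fx$registry, YEAR), 0.25)
  # nothing born in the window: undefined, not zero
  expect_true(is.na(compute_npr(fx$registry, 5 * YEAR)))
  expect_true(is.na(compute_npr(fx$registry[0, ], YEAR)))
})

test_that("age-specific ratio equals the ratio of its birth cohort", {
  fx <- generate_fixture_registry(n_births = 8, n_nonpaternity = 2)
  reg <- fx$registry
  expect_equal(compute_npr_x(reg, YEAR, 0), 0.25)
  # shift the census 3 years: the cohort is now the 3-year-olds
  expect_equal(compute_npr_x(reg, 4 * YEAR, 3), 0.25)
  expect_true(is.na(compute_npr_x(reg, 4 * YEAR, 0)))
  # deaths remove children from the band
  reg$death_day <- c(200, rep(NA, 7))   # one nonpaternity child dies
  expect_equal(compute_npr_x(reg, YEAR, 0),
               sum(reg$nonpaternity[-1]) / 7)
})

test_that("half-siblings ratio enumerates same-mother pairs", {
  fx <- generate_fixture_registry(sibships = list(c("A", "A", "B")))
  expect_equal(compute_hsr(fx$registry), 2 / 3)
  # all single-father sibships: 0, not NA
  fx2 <- generate_fixture_registry(sibships = list(c("A", "A"), c("B", "B", "B")))
  expect_equal(compute_hsr(fx2$registry), 0)
  # no mother with two children: undefined
  fx3 <- generate_fixture_registry(n_births = 4)
  expect_true(is.na(compute_hsr(fx3$registry)))
})

test_that("half-siblings ratio matches a brute-force pair enumeration", {
  brute_hsr <- function(reg) {
    tot <- 0; diff <- 0
    for (m in unique(reg$mother_id)) {
      f <- reg$bio_father_id[reg$mother_id == m]
      if (length(f) < 2) next
      for (i in seq_len(length(f) - 1)) for (j in seq(i + 1, length(f))) {
        tot <- tot + 1
        if (f[i] != f[j]) diff <- diff + 1
      }
    }
    if (tot == 0) NA_real_ else diff / tot
  }
  set.seed(21)
  for (rep in 1:5) {
    sib <- replicate(50, sample(LETTERS[1:4], sample(1:6, 1), replace = TRUE),
                     simplify = FALSE)
    fx <- generate_fixture_registry(sibships = sib)
    expect_equal(compute_hsr(fx$registry), brute_hsr(fx$registry))
  }
})

test_that("child-level half-sibling definition counts affected children", {
  # mother with fathers (A, A, B): all 3 children have a half-sibling
  fx <- generate_fixture_registry(sibships = list(c("A", "A", "B"),
                                                  c("C", "C")))
  # 3 of 5 children with a sibling have a half-sibling
  expect_equal(compute_hsr(fx$registry, method = "child"), 3 / 5)
})

test_that("appending a different-father child never lowers the ratio", {
  set.seed(22)
  for (rep in 1:20) {
    sib <- replicate(10, sample(c("A", "B"), sample(1:4, 1), replace = TRUE),
                     simplify = FALSE)
    before <- compute_hsr(generate_fixture_registry(sibships = sib)$registry)
    k <- sample(seq_along(sib), 1)
    sib[[k]] <- c(sib[[k]], "Z")           # new father joins sibship k
    after <- compute_hsr(generate_fixture_registry(sibships = sib)$registry)
    if (!is.na(before)) expect_gte(after, before)
  }
})

test_that("married-mothers scope excludes births outside wedlock", {
  fx <- generate_fixture_registry(sibships = list(c("A", "B")))
  reg <- fx$registry
  out <- reg[1, ]
  out$putative_father_id <- NA_integer_   # premarital birth, new father
  out$bio_father_id <- 99L
  out$child_id <- 3L
  reg2 <- rbind(reg, out)
  expect_equal(compute_hsr(reg2, scope = "married_mothers"), 1)
  expect_equal(compute_hsr(reg2, scope = "all_children"), 1)  # all pairs differ
  reg3 <- rbind(reg[c(1, 1), ], out)      # same-father pair + premarital child
  expect_equal(compute_hsr(reg3, scope = "married_mothers"), 0)
  expect_equal(compute_hsr(reg3, scope = "all_children"), 2 / 3)
})

test_that("extramarital partnership ratio counts window-overlapping episodes", {
  fx <- generate_fixture_registry(episodes = c(marital = 12, extramarital = 3))
  expect_equal(compute_epr(fx$plog, YEAR), 3 / 15)
  # no married woman in the window: undefined
  fx2 <- generate_fixture_registry(episodes = c(marital = 0))
  expect_true(is.na(compute_epr(fx2$plog, YEAR)))
  # premarital episodes of married women enter the denominator
  fx3 <- generate_fixture_registry(
    episodes = c(marital = 4, extramarital = 1, premarital = 1))
  expect_equal(compute_epr(fx3$plog, YEAR), 1 / 6)
})

test_that("episode-level ratio equals an independent full rescan on a run", {
  brute_epr <- function(plog, t) {
    n_den <- 0; n_num <- 0
    ov <- which(plog$start_day <= t &
                  (is.na(plog$end_day) | plog$end_day > t - YEAR))
    mar <- unique(plog$woman_id[intersect(ov, which(plog$class == "marital"))])
    for (i in ov) {
      if (plog$woman_id[i] %in% mar) {
        n_den <- n_den + 1
        if (plog$class[i] == "extramarital") n_num <- n_num + 1
      }
    }
    if (n_den == 0) NA_real_ else n_num / n_den
  }
  p <- scenario_params(initial_population = 200, horizon_years = 12,
                       burn_in_years = 0, extramarital_rate_mean = 0.3,
                       extramarital_rate_var = 0.1)
  sim <- run_simulation(p, seed = 30)
  for (t in c(2, 6, 11) * YEAR)
    expect_equal(compute_epr(sim$plog, t), brute_epr(sim$plog, t))
})

test_that("measures ignore registry row order and id relabeling", {
  fx <- generate_fixture_registry(n_births = 8, n_nonpaternity = 2,
                                  sibships = list(c("A", "A", "B")))
  reg <- fx$registry
  perm <- reg[sample(nrow(reg)), ]
  expect_equal(compute_npr(perm, YEAR), compute_npr(reg, YEAR))
  expect_equal(compute_hsr(perm), compute_hsr(reg))
  relab <- reg
  relab$mother_id <- reg$mother_id + 1000L
  relab$bio_father_id <- reg$bio_father_id * 7L
  relab$putative_father_id <- reg$putative_father_id * 7L
  expect_equal(compute_hsr(relab), compute_hsr(reg))
})

test_that("moving average smooths with truncated edges and NA exclusion", {
  expect_equal(moving_average(rep(0.4, 25), 10), rep(0.4, 25))
  x <- rep(c(0, 1), 10)
  sm <- moving_average(x, 10)
  expect_true(all(abs(sm[5:15] - 0.5) < 1e-12))
  # variance shrinks on white noise
  set.seed(31)
  z <- rnorm(200)
  expect_lt(var(moving_average(z, 10)), var(z))
  # window >= length: every value is the global mean
  expect_equal(moving_average(c(1, 2, 3), 10), rep(2, 3))
  # NA values are dropped from each window, not propagated
  expect_equal(moving_average(c(1, NA, 3), 3), c(1, 2, 3))
})
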