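#' Draw individual nonmarital partnering rates
#'
#' Individual heterogeneity in premarital/extramarital partnership
#' formation is modelled with a Gamma distribution parameterised by its
#' mean and variance (shape = mean^2/var, scale = var/mean), the standard
#' nonnegative choice that degenerates to a point mass as the variance
#' goes to 0.
#'
#' @param n Number of draws.
#' @param mean,variance Moments of the rate distribution (per year).
#' @return Numeric vector of `n` nonnegative per-year rates; all equal to
#'   `mean` when `variance == 0` (and identically 0 when `mean == 0`).
#' @export
draw_rate <- function(n, mean, variance) {
  if (!is.numeric(mean) || mean < 0 || !is.numeric(variance) || variance < 0)
    stop("mean and variance must be nonnegative", call. = FALSE)
  if (mean == 0 || variance == 0) return(rep(mean, n))
  stats::rgamma(n, shape = mean^2 / variance, scale = variance / mean)
}

#' Age-specific prevalence of current marriage under the two-state model
#'
#' In a population where eligible (age > `min_age`) unmarried women marry
#' at hazard `alpha` and marriages dissolve at hazard `mu`, the
#' probability of being currently married at age `a` is
#' `alpha/(alpha+mu) * (1 - exp(-(alpha+mu) * (a - min_age)))` for
#' `a > min_age` and 0 otherwise (mortality-free closed form).
#'
#' @param alpha Marriage formation hazard (per year).
#' @param mu Marital dissolution hazard (per year).
#' @param age Numeric vector of ages (years).
#' @param min_age Age at which women become eligible to marry.
#' @return Vector of currently-married probabilities.
#' @export
married_prevalence <- function(alpha, mu, age, min_age = 15) {
  a <- pmax(age - min_age, 0)
  if (alpha + mu == 0) return(rep(0, length(age)))
  alpha / (alpha + mu) * (1 - exp(-(alpha + mu) * a))
}

#' Calibrate the marriage rate to an age-specific marriage prevalence curve
#'
#' Finds the marriage formation hazard `alpha` minimising the squared
#' error between an observed table of currently-married prevalence by age
#' and the closed-form two-state prediction of [married_prevalence()],
#' given the marital dissolution hazard.  This is the calibration route
#' used for the default scenario's 0.12/year against DHS marriage
#' prevalence; it is deterministic.  If the target carries information
#' only about the asymptote (all ages effectively at the plateau), the
#' smallest `alpha` matching the plateau is returned.
#'
#' @param target Data frame with columns `age` and `prevalence` in \[0, 1\].
#' @param mu_marital Marital dissolution hazard (per year).
#' @param min_age Eligibility age.
#' @return The fitted `alpha` (per-year hazard).
#' @export
fit_marriage_rate <- function(target, mu_marital, min_age = 15) {
  if (!is.data.frame(target) || nrow(target) == 0 ||
      !all(c("age", "prevalence") %in% names(target)))
    stop("target must be a nonempty data frame with columns 'age' and 'prevalence'",
         call. = FALSE)
  if (any(target$prevalence < 0 | target$prevalence > 1))
    stop("prevalence values must lie in [0, 1]", call. = FALSE)
  if (all(target$prevalence == 0)) return(0)
  sse <- function(alpha) {
    pred <- married_prevalence(alpha, mu_marital, target$age, min_age)
    sum((pred - target$prevalence)^2)
  }
  fit <- stats::optimize(sse, interval = c(0, 20), tol = 1e-10)
  fit$minimum
}
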