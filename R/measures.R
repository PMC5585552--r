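# One simulation "year" in days; all *_day columns are in days from t = 0.
DAYS_PER_YEAR <- 365.25

#' Nonpaternity ratio NPR(t)
#'
#' Fraction of children born over the 12 months ending at `t` that are
#' nonpaternity events, i.e. children conceived through extramarital sex
#' by a married woman (biological father different from the mother's
#' husband at conception).
#'
#' @param registry Birth registry data frame with at least columns
#'   `birth_day` and `nonpaternity` (logical or 0/1); as produced by
#'   [run_simulation()] or read from CSV.
#' @param t Census time in days from the start of the simulation.
#' @return The ratio in \[0, 1\], or `NA_real_` when no births occurred in
#'   the window (an undefined ratio is never reported as 0).
#' @export
compute_npr <- function(registry, t) {
  sel <- registry$birth_day > t - DAYS_PER_YEAR & registry$birth_day <= t
  n <- sum(sel)
  if (n == 0L) return(NA_real_)
  sum(registry$nonpaternity[sel]) / n
}

#' Age-specific nonpaternity ratio NPR_x(t)
#'
#' Among individuals aged `[x, x+1)` years and alive at time `t`, the
#' fraction that are nonpaternity events.  In the absence of mortality
#' this back-projects the nonpaternity ratio `x` years before `t`:
#' NPR_x(t) = NPR(t - x).
#'
#' Survival is taken from a `death_day` column when present (alive at `t`
#' means `death_day` is `NA` or `> t`), otherwise from a logical `alive`
#' column interpreted as the status at `t`.
#'
#' @inheritParams compute_npr
#' @param x Integer age band (years).
#' @return Ratio or `NA_real_` when nobody of that age band is alive at `t`.
#' @export
compute_npr_x <- function(registry, t, x) {
  alive <- registry_alive_at(registry, t)
  age <- (t - registry$birth_day) / DAYS_PER_YEAR
  sel <- alive & age >= x & age < x + 1
  n <- sum(sel)
  if (n == 0L) return(NA_real_)
  sum(registry$nonpaternity[sel]) / n
}

registry_alive_at <- function(registry, t) {
  if (!is.null(registry$death_day))
    (is.na(registry$death_day) | registry$death_day > t) & registry$birth_day <= t
  else if (!is.null(registry$alive))
    as.logical(registry$alive) & registry$birth_day <= t
  else
    stop("registry needs a 'death_day' or 'alive' column for NPR_x", call. = FALSE)
}

#' Full NPR_x age profile at a census time
#'
#' @inheritParams compute_npr_x
#' @param ages Integer age bands to evaluate (default 0-50).
#' @return Named numeric vector `NPR_x(t)` for each `x` in `ages`.
#' @export
compute_npr_profile <- function(registry, t, ages = 0:50) {
  alive <- registry_alive_at(registry, t)
  age <- (t - registry$birth_day) / DAYS_PER_YEAR
  band <- floor(age)
  sel <- alive & band >= min(ages) & band <= max(ages)
  idx <- band[sel] - min(ages) + 1L
  nb <- length(ages)
  den <- tabulate(idx, nbins = nb)
  num <- tabulate(idx[as.logical(registry$nonpaternity[sel])], nbins = nb)
  out <- ifelse(den > 0, num / den, NA_real_)
  names(out) <- ages
  out
}

#' Extramarital partnership ratio EPR(t)
#'
#' Among women married at any point during the 12 months ending at `t`,
#' the number of extramarital partnership episodes overlapping that
#' window divided by all their partnership episodes (marital and
#' nonmarital) overlapping it.  An ongoing marriage counts as one episode
#' per window.
#'
#' @param plog Partnership log data frame with columns `woman_id`,
#'   `class` (`"marital"`, `"premarital"`, `"extramarital"`), `start_day`
#'   and `end_day` (`NA` while the episode is open).
#' @param t Census time in days.
#' @return Ratio or `NA_real_` when no such woman has any episode in the
#'   window.
#' @export
compute_epr <- function(plog, t) {
  w0 <- t - DAYS_PER_YEAR
  ov <- plog$start_day <= t & (is.na(plog$end_day) | plog$end_day > w0)
  married_women <- unique(plog$woman_id[ov & plog$class == "marital"])
  sel <- ov & plog$woman_id %in% married_women
  den <- sum(sel)
  if (den == 0L) return(NA_real_)
  sum(plog$class[sel] == "extramarital") / den
}

#' Half-siblings ratio HSR(t)
#'
#' Over children born by time `t` and (by default) alive at `t` — the
#' sibships one could actually genotype in a cross-sectional family
#' study, mirroring the alive-at-census conditioning of
#' [compute_npr_x()]; set `survivors_only = FALSE` to include dead
#' children.  Considering sibships of the same mother: with the default `"pair"` definition, the
#' fraction of unordered same-mother child pairs whose two children have
#' different biological fathers.  With the `"child"` definition, the
#' fraction of children having at least one maternal half-sibling among
#' children having at least one maternal sibling.
#'
#' With the default scope `"married_mothers"`, sibships comprise the
#' children born in wedlock (those with a putative father), so the ratio
#' captures the two father-mixing routes open to married women —
#' extramarital fathering and remarriage — which is what makes it a
#' proxy of extramarital sex.  `scope = "all_children"` includes births
#' to unmarried mothers as well, which adds premarital fathering and
#' makes the measure track premarital rather than extramarital
#' partnering; it is kept as an option for sensitivity analyses.
#'
#' @param registry Birth registry with columns `mother_id`,
#'   `bio_father_id`, `birth_day` and (for the default scope)
#'   `putative_father_id`.
#' @param t Census time in days (default: include every birth).
#' @param method `"pair"` (default) or `"child"`.
#' @param scope `"married_mothers"` (default) or `"all_children"`.
#' @param survivors_only Restrict to children alive at `t` (default);
#'   requires a `death_day` or `alive` column.
#' @return Ratio or `NA_real_` when no mother has two or more children
#'   in scope.
#' @export
compute_hsr <- function(registry, t = Inf, method = c("pair", "child"),
                        scope = c("married_mothers", "all_children"),
                        survivors_only = TRUE) {
  method <- match.arg(method)
  scope <- match.arg(scope)
  sel <- if (survivors_only) registry_alive_at(registry, t)
         else registry$birth_day <= t
  if (scope == "married_mothers")
    sel <- sel & !is.na(registry$putative_father_id)
  m <- registry$mother_id[sel]
  f <- registry$bio_father_id[sel]
  if (length(m) == 0L) return(NA_real_)
  mi <- match(m, unique(m))
  key <- mi * (max(abs(f)) + 1) + f          # unique per (mother, father)
  pi <- match(key, unique(key))
  n_m <- tabulate(mi)
  n_mf <- tabulate(pi)
  if (method == "pair") {
    tot <- sum(choose(n_m, 2))
    if (tot == 0) return(NA_real_)
    same <- sum(choose(n_mf, 2))
    (tot - same) / tot
  } else {
    has_sib <- n_m[mi] >= 2L
    if (!any(has_sib)) return(NA_real_)
    has_half <- (n_m[mi] - n_mf[pi]) >= 1L
    sum(has_sib & has_half) / sum(has_sib)
  }
}

#' Centered moving average with truncated edges
#'
#' Running mean of a series over a centered window of `window` points
#' (for even windows, one more trailing than leading point).  `NA`s are
#' excluded from each window's mean; positions whose window holds no
#' defined value stay `NA`.  Windows are truncated at the series edges,
#' and a window at least as long as the series yields the global mean
#' everywhere.
#'
#' @param x Numeric series (annual grid in this package's use).
#' @param window Window length in points (>= 1).
#' @return Smoothed series of the same length.
#' @export
moving_average <- function(x, window = 10) {
  stopifnot(window >= 1)
  n <- length(x)
  if (n == 0L) return(x)
  lo <- floor((window - 1) / 2)
  hi <- floor(window / 2)
  ok <- !is.na(x)
  v <- ifelse(ok, x, 0)
  cs <- c(0, cumsum(v))
  ck <- c(0, cumsum(ok))
  i <- seq_len(n)
  a <- pmax(i - lo, 1L)
  b <- pmin(i + hi, n)
  s <- cs[b + 1L] - cs[a]
  k <- ck[b + 1L] - ck[a]
  ifelse(k > 0, s / k, NA_real_)
}
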