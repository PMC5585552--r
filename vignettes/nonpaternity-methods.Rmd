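---
title: "Nonpaternity and half-sibling ratios as biomarkers of extramarital sex: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nonpaternity and half-sibling ratios as biomarkers of extramarital sex: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Why this package exists

Self-reported sexual behaviour data suffer from social-desirability and
recall biases, which limits their value for understanding sexually
transmitted infection dynamics, especially where partnership concurrency
matters.  Two quantities observable from genetic family data have been
proposed as objective proxies of extramarital sex: the **nonpaternity
ratio** (children whose biological father differs from the mother's
husband) and the **half-siblings ratio** (same-mother children with
different biological fathers).  This package implements an
individual-based Monte Carlo model of partnering, conception and
demography in a female population — parameterised for a Sub-Saharan
African (Kenya DHS-derived) setting — together with the four measures and
the simulation experiments that assess whether these biomarkers reliably
track actual extramarital partnering, both contemporaneously and
decades back in time.

## The model

Women are the simulated units; male partners are identity tokens only
(a husband token persists for the marriage; every new nonmarital
partnership receives a fresh token, i.e. partners are not re-met).  Each
woman is born, ages, and dies at an age-specific hazard $d(a)$.  From age
15 she can:

* **marry** at hazard $\alpha$ (0.12/year by default, calibrated against
  age-specific currently-married prevalence via the closed form
  $p(a) = \frac{\alpha}{\alpha+\mu}\,(1-e^{-(\alpha+\mu)(a-15)})$,
  see `fit_marriage_rate()`); marriages dissolve at hazard
  $\mu_{marital}$ (mean duration 20 years); there is no female polygamy
  and remarriage uses the same $\alpha$;
* **form nonmarital partnerships** (mean duration 6 months) at an
  individual rate: $\lambda_{p,i}$ while unmarried (premarital),
  $\lambda_{e,i}$ while married (extramarital).  Individual rates are
  Gamma draws with configurable mean and variance — the standard
  nonnegative heterogeneity choice, degenerating to a point mass at
  variance 0 — multiplied by an optional age profile and a
  time modifier $h(t)$ used by the historical scenarios.

Per step (7 days by default) every event fires with probability
$1-e^{-\text{rate}\cdot\Delta t}$.  Coital acts are Poisson with
age-specific monthly frequency $c(a)$; a married woman with at least one
extramarital partner gives a fraction $\varphi_m$ (default 0.7) of acts
to her spouse and splits the rest uniformly among extramarital partners;
an unmarried woman splits acts uniformly among her premarital partners.
Each act conceives with probability $f(a)\,(1 - \text{Eff}\cdot C_v)$,
where $f(a)$ is the per-act fecundability, Eff = 0.90 the condom
efficacy against conception, and $C_v$ the partnership-class condom
coverage (0.23 unmarried, 0.019 marital, 0.074 extramarital).  At most
one conception per woman per step (first success in randomised partner
order); no conception during gestation, which is
$\max(1, \text{round}(N(267, 10^2)))$ days.  Births are dated at the
exact due day; sex is assigned 1:1 and girls enter the simulated
population at birth, making long scenario runs self-sustaining.  The
birth registry records, for every child, the mother, the biological
father (the conceiving partner), the putative father (the mother's
husband at conception, if any) and the nonpaternity flag.

Marriage closes a woman's open nonmarital partnerships, so a married
woman's active partners are exactly her extramarital ones; this makes
the zero-extramarital-rate limit exact (no nonpaternity events, EPR
identically 0) rather than approximate.

Marital status **at conception** governs the nonpaternity flag: the
defining extramarital act happens at conception, so a woman who marries
during gestation does not create a nonpaternity event.  Episode class in
the partnership log is frozen at formation; for act allocation and
condom coverage the woman's *current* status is used (an ongoing
partnership of a woman whose marriage ended behaves premaritally from
then on).

## The four measures

With a 12-month window ending at census time $t$:

* `compute_npr()` — NPR(t): nonpaternity births / all births in the
  window;
* `compute_npr_x()` — NPR$_x$(t): among individuals aged $[x, x+1)$ and
  alive at $t$, the nonpaternity fraction.  Without mortality this
  back-projects exactly: NPR$_x$(t) = NPR(t−x); with mortality it is
  unbiased because death is independent of paternity status by
  construction;
* `compute_epr()` — EPR(t): among women married at any point in the
  window, extramarital episodes overlapping the window / all their
  episodes overlapping it (an ongoing marriage counts as one episode);
* `compute_hsr()` — HSR(t): over sibships of children born by $t$ and
  alive at $t$, the fraction of unordered same-mother pairs with
  different biological fathers (a child-level variant is available via
  `method = "child"`).

Undefined ratios (empty denominators) are `NA`, never silently 0.

**HSR scope.**  By default sibships comprise children born in wedlock
(those with a putative father), so HSR captures the two father-mixing
routes open to married women: extramarital fathering and remarriage.
Including births to unmarried mothers (`scope = "all_children"`) makes
the measure track *premarital* partnering instead — in the rate-sweep
experiment its between-run correlation with EPR drops from about 0.93 to
about 0.2 while its correlation with the premarital rate rises to about
0.95 — which would defeat its purpose as an extramarital-sex biomarker.
The formula-level definition in the source material is ambiguous on this
point; the narrative (a measure of partnerships "among married women")
supports the in-wedlock scope, which is therefore the default and is
what the headline correlation uses.  By default HSR also conditions on
the children being alive at $t$, like NPR$_x$: these are the sibships a
cross-sectional genetic family study could actually observe.  Since
death is independent of paternity here, the restriction adds sampling
noise but no bias; `survivors_only = FALSE` computes the full-pedigree
version.

## Experiments

* `run_npr_epr_experiment()` / `run_hsr_epr_experiment()`: each of
  `n_sims` runs draws the premarital/extramarital rate means and
  variances uniformly from the cross-country Sub-Saharan ranges
  (means in [0,1] / [0,0.5], variances in [0,2] / [0,1]), with
  $\varphi_m = 0.7$; after a 50-year burn-in, annual censuses pair
  NPR(T) (or HSR(T)) with EPR(T−1) — the one-year shift accommodates
  the gestation lag.  Pairs are pooled across runs and census years and
  summarised by a Pearson correlation.
* `run_historical_experiment()`: nonmarital rates are modulated by a
  piecewise-linear $h(t)$.  The *steady decline* scenario falls linearly
  to 30% of peak over the 10 years after burn-in and plateaus (the
  shape of the reduction in sexual risk behaviour after the onset of the
  HIV epidemic); the *transient drop* falls to 30% over 5 years and
  recovers over 5 more.  The base (DHS-derived, self-reported) rates are
  anchored at the scenario *floor*, i.e. divided by 0.3 to give the peak
  (variances scaled by the square, preserving the coefficient of
  variation).  Censuses cover every post-burn-in year; at each census
  the full NPR$_x$ profile (x = 0…50) is paired with EPR(T−x−1), the
  extramarital partnering of each cohort's conception year.  Raw pooled
  correlations are reported alongside correlations of 10-year
  moving-average-smoothed series (EPR smoothed over time, each census's
  NPR$_x$ profile smoothed over age).
* `run_phi_sweep()`: $\varphi_m$ from 0.1 to 0.9 in steps of 0.1 at
  fixed self-reported rates; reports mean NPR with a 95% CI across runs
  per $\varphi_m$.  Mean nonpaternity falls monotonically in
  $\varphi_m$, which is what lets observed nonpaternity levels bound the
  plausible marital share of coital acts.

Correlation uncertainty uses Fisher's z transformation
(`fisher_ci()`).  Census-level pairs within one run are autocorrelated,
so the interval's effective sample size defaults to the number of
independent runs rather than the pooled pair count — with r = 0.79 and
n = 100 runs this gives (0.703, 0.854), and pooled-pair intervals would
be anticonservative; both modes are exposed in `correlate()`.

## Default parameters and stand-in schedules

All scalar defaults (marriage and dissolution rates, partnership
durations, rate means/variances, $\varphi_m$, condom coverage and
efficacy, gestation moments) are the DHS-derived scenario values and are
listed in `?default_params`.  The three age schedules — per-act
fecundability $f(a)$, coital frequency $c(a)$, mortality $d(a)$ — come
from sources that do not publish full tables, so the package ships
editable stand-in step functions chosen once for demographic realism in
the study setting: $f(a)$ peaks at 0.0048/act in the early twenties and
reaches 0 at 50 (an *effective* fecundability, deliberately low enough
to absorb unmodelled postpartum infecundability and non-condom
contraception); $c(a)$ declines from 8 to 3 acts/month between 20
and 50; $d(a)$ is an abridged life-table shape with elevated infant
mortality (7%/year in infancy).  Under the defaults a run delivers a
total fertility rate near 4.5, life expectancy in the high fifties and
slow population growth (~1.5%/year) — Kenya-like values.  Correlations,
not absolute levels, are the package's headline outputs, and they are
insensitive to moderate changes in these schedules; all three are
configuration fields.

The simulation step is 7 days: fine enough to resolve the 10-day
gestation SD and the per-act conception scale, coarse enough to keep
multi-century population runs fast.  Event probabilities are exact
exponential-hazard forms, so halving the step changes results only
through within-step tie-breaks.

## Numerical and engineering choices

* Two engines share one per-step specification: a readable pure-R
  reference (`step_demography()`, `step_partnerships()`,
  `attempt_conceptions()`, `deliver_births()`) used by the unit tests,
  and a compiled C++ engine used for experiment-scale runs.  The
  compiled engine collapses the act-allocation block to its exact
  Poisson-thinning marginal (conception probability
  $1-e^{-\mu s p}$ per partner); the test suite cross-checks the two
  engines statistically and checks the closed form against the explicit
  allocation.
* Each engine is bit-reproducible given a seed; the two engines consume
  random numbers in different orders and therefore agree statistically,
  not bitwise.
* Undefined measures propagate as `NA` and are dropped pair-wise in
  correlations; a run contributing no defined pairs is reported, not
  silently ignored.
* The moving average is centred with truncated edges and NA exclusion;
  a window at least as long as the series yields the global mean.
* Initial populations draw ages from the stationary age distribution of
  the mortality schedule and marital status from the closed-form
  two-state prevalence, so burn-in converges quickly; 50 years of
  burn-in are nevertheless discarded before any measurement.

## Problem sizes

The package's own test and reproduction scripts run the experiments at
desk scale — 30 runs of 2,000 women (30 post-burn-in measurement years
for the contemporaneous correlations; 120-year horizon for the
historical scenarios) — completing in minutes on one CPU.  The study
design they reproduce uses 100 runs of 20,000 women and 101- or
201-year horizons; both scales run through the identical code path and
differ only in configuration.  At desk scale the pooled correlations
carry wider Monte Carlo error, and sampling noise in the annual measures
attenuates raw (unsmoothed) correlations; the historical-scenario
comparisons therefore emphasise the qualitative orderings (smoothing
strengthens the back-cast correlation; sustained declines are easier to
read back than transient dips) alongside the numeric values.

A note on the raw steady-decline correlation specifically: with a
120-year horizon nearly every census's 51-year lookback spans the
h(t) transition, so the pooled raw correlation sits *above* the value
obtained on a 201-year record, where many lookbacks fall entirely in
flat eras and contribute noise-only pairs.  The smoothed correlations
are insensitive to this.

## Known limitations

* Fertility is condom-and-fecundability only: no hormonal
  contraception, abortion or breastfeeding amenorrhea (absorbed into
  the effective $f(a)$); these act nondifferentially with respect to
  extramarital sex here, which is exactly the condition under which the
  biomarkers remain valid.
* No male-side constraints (a male token never links two women), no
  polygyny, no migration, and no paternity-test error model.
* Twins are not modelled; one child per delivery.
* The nonmarital age multiplier defaults to 1 for all ages; survey-based
  age calibrations can be supplied as a table.
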