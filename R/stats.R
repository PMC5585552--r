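#' Pearson correlation coefficient with undefined-pair handling
#'
#' Product-moment correlation of `x` and `y` after dropping pairs where
#' either value is `NA`.  Returns `NA_real_` (an explicit
#' undefined-correlation signal, never silently 0) when fewer than 3
#' complete pairs remain or when either vector has zero variance.
#'
#' @param x,y Numeric vectors of equal length.
#' @return Correlation in \[-1, 1\] or `NA_real_`.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) return(NA_real_)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Fisher z confidence interval for a correlation coefficient
#'
#' Transforms `r` with `z = atanh(r)`, forms the normal-theory interval
#' `z +/- z_crit / sqrt(n - 3)`, and back-transforms with `tanh`.  At
#' `|r| = 1` the interval degenerates to `{r}`.
#'
#' @param r Correlation coefficient.
#' @param n Effective sample size (>= 4 for a proper interval).
#' @param level Two-sided confidence level.
#' @return Numeric vector `c(lo, hi)`.
#' @examples
#' fisher_ci(0.79, 100)  # c(0.703, 0.854) to 3 decimals
#' @export
fisher_ci <- function(r, n, level = 0.95) {
  stopifnot(abs(r) <= 1, level > 0, level < 1)
  if (abs(r) == 1) return(c(r, r))
  if (n < 4) stop("n must be at least 4 for a Fisher z interval", call. = FALSE)
  z <- atanh(r)
  hw <- stats::qnorm(1 - (1 - level) / 2) / sqrt(n - 3)
  tanh(c(z - hw, z + hw))
}

#' Pool lagged measure pairs across simulation runs
#'
#' Builds the pooled `(x(T - lag), y(T))` pairs used by the correlation
#' experiments: for every run and every census year `T` where both values
#' are defined, one pair is formed; undefined (`NA`) entries are dropped.
#' With `per_sim_mean = TRUE`, pairs are averaged within each run first,
#' giving one pair per simulation.
#'
#' @param series_list List of per-run annual series: each element a data
#'   frame with a `year` column and the named measure columns.
#' @param lag_years Nonnegative lag applied to the `x` measure.
#' @param x,y Names of the columns to pair (e.g. `"epr"`, `"npr"`).
#' @param per_sim_mean Average pairs within each run before pooling.
#' @return List with vectors `x`, `y` and the per-pair `sim` index.
#' @export
paired_lagged_series <- function(series_list, lag_years, x = "epr", y = "npr",
                                 per_sim_mean = FALSE) {
  stopifnot(lag_years >= 0)
  xs <- numeric(0); ys <- numeric(0); sims <- integer(0)
  for (i in seq_along(series_list)) {
    s <- series_list[[i]]
    j <- match(s$year - lag_years, s$year)
    xv <- s[[x]][j]
    yv <- s[[y]]
    ok <- !is.na(xv) & !is.na(yv)
    if (!any(ok)) next
    if (per_sim_mean) {
      xs <- c(xs, mean(xv[ok])); ys <- c(ys, mean(yv[ok])); sims <- c(sims, i)
    } else {
      xs <- c(xs, xv[ok]); ys <- c(ys, yv[ok]); sims <- c(sims, rep(i, sum(ok)))
    }
  }
  if (length(xs) == 0L)
    stop("no defined pairs at lag ", lag_years, call. = FALSE)
  list(x = xs, y = ys, sim = sims)
}

#' Correlation with Fisher z interval as a result object
#'
#' Computes the pooled Pearson correlation of `x` and `y` and a Fisher z
#' confidence interval.  Because census-level pairs within one simulation
#' run are autocorrelated, the interval's effective sample size defaults
#' to the number of independent simulation runs (`ci_n`), not the number
#' of pooled pairs; pass `ci_n = NULL` to use the pair count.
#'
#' @param x,y Numeric vectors (pooled pairs).
#' @param ci_n Effective sample size for the interval; `NULL` for the
#'   number of complete pairs.
#' @param level Confidence level.
#' @param label Optional descriptor of the pairing (measure names, lag).
#' @return An object of class `np_cor` with fields `r`, `n_pairs`,
#'   `n_eff`, `ci`, `level`, `label`.
#' @export
correlate <- function(x, y, ci_n = NULL, level = 0.95, label = "") {
  r <- pearson_r(x, y)
  n_pairs <- sum(!is.na(x) & !is.na(y))
  n_eff <- if (is.null(ci_n)) n_pairs else ci_n
  ci <- if (is.na(r) || n_eff < 4) c(NA_real_, NA_real_)
        else fisher_ci(r, n_eff, level)
  structure(list(r = r, n_pairs = n_pairs, n_eff = n_eff,
                 ci = ci, level = level, label = label),
            class = "np_cor")
}

#' @export
print.np_cor <- function(x, ...) {
  cat(sprintf("Pearson correlation%s\n",
              if (nzchar(x$label)) paste0(" [", x$label, "]") else ""))
  cat(sprintf("  r = %.3f (%d%% CI %.3f-%.3f; %d pairs, effective n = %d)\n",
              x$r, round(100 * x$level), x$ci[1], x$ci[2],
              x$n_pairs, as.integer(x$n_eff)))
  invisible(x)
}
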