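#' Build a birth registry and partnership log with exact known counts
#'
#' Constructs synthetic measure inputs whose NPR, HSR and EPR values have
#' closed-form expected values, for testing and for demonstrating the
#' standalone measure functions.  All births and episodes fall in the
#' 12-month window ending at `t`.
#'
#' @param n_births Number of single-child mothers to add, the first
#'   `n_nonpaternity` of them flagged as nonpaternity events.
#' @param n_nonpaternity Number of nonpaternity births among `n_births`.
#' @param sibships List of vectors of father labels, one vector per
#'   mother; e.g. `list(c("A", "A", "B"))` is one mother with three
#'   children by fathers A, A and B.  Father labels are arbitrary keys
#'   mapped to token ids; sibship births are not nonpaternity events.
#' @param episodes Named counts of partnership episodes, e.g.
#'   `c(marital = 12, extramarital = 3, premarital = 0)`.  Extramarital
#'   and premarital episodes are attached to the married women (premarital
#'   episodes start before the marriage, consistent with class-at-start).
#' @param t Window end time in days (default one year).
#' @return List with elements `registry` and `plog`, column-compatible
#'   with [compute_npr()], [compute_npr_x()], [compute_hsr()] and
#'   [compute_epr()].
#' @export
generate_fixture_registry <- function(n_births = 0, n_nonpaternity = 0,
                                      sibships = list(), episodes = NULL,
                                      t = DAYS_PER_YEAR) {
  if (n_nonpaternity > n_births)
    stop("n_nonpaternity cannot exceed n_births", call. = FALSE)
  mother <- integer(0); bio <- integer(0); put <- integer(0)
  nonpat <- logical(0)
  next_mother <- 1L
  next_male <- MALE_TOKEN_BASE
  if (n_births > 0) {
    for (i in seq_len(n_births)) {
      hus <- next_male; next_male <- next_male + 1L
      np <- i <= n_nonpaternity
      father <- if (np) { next_male <- next_male + 1L; next_male - 1L } else hus
      mother <- c(mother, next_mother); next_mother <- next_mother + 1L
      bio <- c(bio, father); put <- c(put, hus); nonpat <- c(nonpat, np)
    }
  }
  for (s in sibships) {
    labs <- as.character(s)
    ids <- next_male + match(labs, unique(labs)) - 1L
    next_male <- next_male + length(unique(labs))
    k <- length(labs)
    mother <- c(mother, rep(next_mother, k)); next_mother <- next_mother + 1L
    bio <- c(bio, ids); put <- c(put, ids)       # own-father births
    nonpat <- c(nonpat, rep(FALSE, k))
  }
  n <- length(mother)
  birth_day <- if (n) t - stats::runif(n, 0, DAYS_PER_YEAR - 1) else numeric(0)
  registry <- data.frame(
    child_id = seq_len(n), mother_id = mother, bio_father_id = bio,
    putative_father_id = put, birth_day = birth_day,
    gestation_days = rep(267, n), nonpaternity = nonpat,
    sex = rep("F", n), death_day = rep(NA_real_, n),
    woman_idx = rep(NA_integer_, n))

  plog <- data.frame(woman_id = integer(0), partner_id = integer(0),
                     class = character(0), start_day = numeric(0),
                     end_day = numeric(0))
  if (!is.null(episodes)) {
    epi <- c(marital = 0, premarital = 0, extramarital = 0)
    bad <- setdiff(names(episodes), names(epi))
    if (length(bad))
      stop("unknown episode class(es): ", paste(bad, collapse = ", "),
           call. = FALSE)
    epi[names(episodes)] <- episodes
    n_mar <- epi[["marital"]]
    if (n_mar == 0 && (epi[["extramarital"]] > 0 || epi[["premarital"]] > 0))
      stop("extramarital/premarital episodes need married women in the window",
           call. = FALSE)
    add <- function(w, cls, start) {
      data.frame(woman_id = w, partner_id = next_male + seq_along(w),
                 class = cls, start_day = start,
                 end_day = rep(NA_real_, length(w)))
    }
    rows <- list()
    if (n_mar > 0)
      rows <- c(rows, list(add(seq_len(n_mar), "marital", t - DAYS_PER_YEAR / 2)))
    next_male <- next_male + n_mar
    if (epi[["extramarital"]] > 0) {
      w <- rep_len(seq_len(n_mar), epi[["extramarital"]])
      rows <- c(rows, list(add(w, "extramarital", t - DAYS_PER_YEAR / 4)))
      next_male <- next_male + length(w)
    }
    if (epi[["premarital"]] > 0) {
      w <- rep_len(seq_len(n_mar), epi[["premarital"]])
      rows <- c(rows, list(add(w, "premarital", t - DAYS_PER_YEAR)))
      next_male <- next_male + length(w)
    }
    plog <- do.call(rbind, rows)
  }
  list(registry = registry, plog = plog)
}
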