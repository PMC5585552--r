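# Hand-built reference-engine states with known ages / marital status /
# individual rates, for unit tests of the per-step operations.
make_state <- function(ages, married = rep(FALSE, length(ages)),
                       lam_p = 0, lam_e = 0, t = 0) {
  n <- length(ages)
  base <- 10000000L
  husband <- ifelse(married, base + seq_len(n), NA_integer_)
  st <- list(
    t = t,
    women = list(
      birth_day = t - ages * 365.25,
      death_day = rep(NA_real_, n),
      married = married,
      husband = husband,
      mar_row = rep(NA_integer_, n),
      gestating = rep(FALSE, n),
      due = rep(NA_real_, n),
      gest_start = rep(NA_real_, n),
      gf = rep(NA_integer_, n),
      gf_husband = rep(NA_integer_, n),
      lam_p = rep(lam_p, length.out = n),
      lam_e = rep(lam_e, length.out = n),
      reg_row = rep(NA_integer_, n)
    ),
    registry = list(
      mother_id = integer(0), bio_father_id = integer(0),
      putative_father_id = integer(0), birth_day = numeric(0),
      gestation_days = numeric(0), nonpaternity = logical(0),
      sex = character(0), death_day = numeric(0), woman_idx = integer(0)
    ),
    plog = list(woman_id = integer(0), partner_id = integer(0),
                class = integer(0), start_day = numeric(0),
                end_day = numeric(0)),
    active = integer(0),
    next_male = base + n + 1L
  )
  if (any(married)) {
    w <- which(married)
    st$plog <- list(woman_id = w, partner_id = husband[w],
                    class = rep(1L, length(w)),
                    start_day = rep(t, length(w)),
                    end_day = rep(NA_real_, length(w)))
    st$women$mar_row[w] <- seq_along(w)
  }
  class(st) <- "np_state"
  st
}

# give a woman an open nonmarital partnership
add_partner <- function(st, w, class = if (st$women$married[w]) 3L else 2L) {
  pid <- st$next_male
  st$next_male <- st$next_male + 1L
  r <- length(st$plog$woman_id) + 1L
  st$plog$woman_id[r] <- w
  st$plog$partner_id[r] <- pid
  st$plog$class[r] <- class
  st$plog$start_day[r] <- st$t
  st$plog$end_day[r] <- NA_real_
  st$active <- c(st$active, r)
  st
}

flat_table <- function(value, age = 0) data.frame(age = age, value = value)
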