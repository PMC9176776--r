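# Descriptive nuptiality surfaces: age at first marriage over time and
# cohort marriage outcomes (the cure-fraction check).

#' Mean age at first marriage by marriage year
#'
#' Pools colony-born first marriages with known ages over a forward rolling
#' window of calendar years (default 3, so the first window of a 1680-1750
#' span is 1680-82) and reports the mean age at first marriage for the
#' requested sex, plus the mean spousal age gap (groom minus bride) over
#' marriages where both birth dates are known.
#'
#' @param register a `register`.
#' @param sex `"M"` or `"F"`.
#' @param window_years window width in years; 1 gives plain annual means.
#' @return `data.table(year, n, mean_age, n_gap, mean_gap)`; `year` labels
#'   the first year of the window.  Windows without marriages carry `NA`.
#' @export
marriage_age_series <- function(register, sex = c("F", "M"), window_years = 3L) {
  sex <- match.arg(sex)
  stopifnot(window_years >= 1L)
  ind <- register$individuals
  fm <- .first_marriage(register)
  ev <- merge(fm[any_undated == FALSE],
              ind[immigrant == FALSE & !is.na(birth_date),
                  .(ind_id, sex, birth_date)], by = "ind_id")
  ev <- ev[!is.na(marriage_date)]
  ev[, `:=`(year = year_of(marriage_date),
            age = age_years(marriage_date, birth_date))]

  # spousal age gap per marriage act (both births known)
  m <- register$acts[kind == "marriage" & !is.na(date) &
                       !is.na(ind_id1) & !is.na(ind_id2)]
  sx <- setNames(ind$sex, ind$ind_id)
  bd <- setNames(as.numeric(ind$birth_date), ind$ind_id)
  gaps <- m[, {
    groom <- fifelse(sx[ind_id1] == "M", ind_id1, ind_id2)
    bride <- fifelse(sx[ind_id1] == "M", ind_id2, ind_id1)
    .(year = year_of(date),
      gap = (bd[bride] - bd[groom]) / DAYS_PER_YEAR)
  }]
  gaps <- gaps[!is.na(gap)]

  sex_arg <- sex
  evs <- ev[ev[["sex"]] == sex_arg]
  years <- seq(min(evs$year), max(evs$year))
  years <- years[years + window_years - 1L <= max(years)]
  rbindlist(lapply(years, function(y) {
    win <- evs[year >= y & year <= y + window_years - 1L]
    gw <- gaps[year >= y & year <= y + window_years - 1L]
    data.table(year = y, n = nrow(win),
               mean_age = if (nrow(win)) mean(win$age) else NA_real_,
               n_gap = nrow(gw),
               mean_gap = if (nrow(gw)) mean(gw$gap) else NA_real_)
  }))
}

#' Cohort marriage-outcome table
#'
#' Classifies colony-born individuals by birth decade and sex into: married
#' before 45; married at or after 45; survived to 45 never married; died
#' unmarried before 45; married at unknown age.  The share surviving to 45
#' never married is the empirical cure fraction; if it is small and
#' trendless, standard Cox models (which assume the event would eventually
#' occur absent censoring) are appropriate.  Individuals with neither a
#' marriage nor a known death date cannot be classified and are counted in
#' a separate `n_unresolved` diagnostics column rather than forced into a
#' category.
#'
#' @param register a `register`.
#' @return `data.table` with one row per (birth decade, sex): percentage
#'   shares of the five outcome categories (summing to 100 within
#'   rounding), the classified count `n`, and `n_unresolved`.
#' @export
cohort_outcome_table <- function(register) {
  ind <- register$individuals
  fm <- .first_marriage(register)
  d <- merge(ind[immigrant == FALSE & !is.na(birth_date),
                 .(ind_id, sex, birth_date, death_date)],
             fm, by = "ind_id", all.x = TRUE)
  d[, ever_married := !is.na(any_undated)]
  d[, age45 := birth_date + floor(45 * DAYS_PER_YEAR)]
  d[, outcome := NA_character_]
  d[ever_married & any_undated == FALSE & marriage_date < age45,
    outcome := "married_before_45"]
  d[ever_married & any_undated == FALSE & marriage_date >= age45,
    outcome := "married_over_45"]
  d[ever_married & any_undated == TRUE, outcome := "married_unknown_age"]
  d[!ever_married & !is.na(death_date) & death_date >= age45,
    outcome := "died_unmarried_over_45"]
  d[!ever_married & !is.na(death_date) & death_date < age45,
    outcome := "died_unmarried_before_45"]
  d[, decade := decade_of(birth_date)]

  cats <- c("married_before_45", "married_over_45", "died_unmarried_over_45",
            "died_unmarried_before_45", "married_unknown_age")
  out <- d[, {
    known <- outcome[!is.na(outcome)]
    n <- length(known)
    shares <- if (n > 0) 100 * as.numeric(table(factor(known, levels = cats))) / n
              else rep(NA_real_, length(cats))
    c(setNames(as.list(shares), cats),
      list(n = n, n_unresolved = sum(is.na(outcome))))
  }, by = .(decade, sex)]
  setorder(out, sex, decade)
  out[]
}
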