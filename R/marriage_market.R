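# Marriage-market pools and operational sex ratios.
#
# The operational sex ratio is the share of men (percent male) in the
# unmarried -- including widowed -- population aged [14, 50) present at the
# annual June-15 reference date, at colonial, regional, or parish scope.  The
# percentage-share form avoids the asymmetry of proper ratios.  An
# all-population variant (married individuals included) is provided for
# comparison.

#' Neighbor set for the regional sex ratio
#'
#' The regional marriage market of a parish is the focal parish plus its five
#' closest parishes by planar Euclidean distance, extended by any further
#' parish at most 0.5 km farther away than the fifth closest.  Only parishes
#' already founded by the evaluation year are candidates, since parishes
#' appear over time.
#'
#' @param focal focal `parish_id`.
#' @param parishes the `parishes` table of a register (or a register).
#' @param year optional evaluation year; if given, candidate parishes must be
#'   founded on or before June 15 of that year.
#' @return list of class `neighbor_set` with `focal`, `members` (focal
#'   first, then neighbors by increasing distance), `distances_km`
#'   (aligned with `members`, 0 for the focal), and `small` (TRUE when fewer
#'   than five other parishes existed).
#' @export
neighbor_set <- function(focal, parishes, year = NULL) {
  if (inherits(parishes, "register")) parishes <- parishes$parishes
  parishes <- as.data.table(parishes)[in_colony == TRUE]
  if (!focal %in% parishes$parish_id) {
    stop("unknown focal parish: ", focal, call. = FALSE)
  }
  if (!is.null(year)) {
    ref <- june15(year)
    parishes <- parishes[is.na(founded) | founded <= ref]
    if (!focal %in% parishes$parish_id) {
      stop("focal parish ", focal, " not founded by ", year, call. = FALSE)
    }
  }
  f <- parishes[parish_id == focal]
  if (is.na(f$x_km) || is.na(f$y_km)) {
    stop("focal parish ", focal, " has no coordinates", call. = FALSE)
  }
  others <- parishes[parish_id != focal & !is.na(x_km) & !is.na(y_km)]
  d <- sqrt((others$x_km - f$x_km)^2 + (others$y_km - f$y_km)^2)
  ord <- order(d, others$parish_id)
  others <- others[ord]; d <- d[ord]
  small <- nrow(others) < 5L
  if (small) {
    keep <- seq_len(nrow(others))
  } else {
    d5 <- d[5L]
    keep <- which(d <= d5 + 0.5)
  }
  structure(list(
    focal = focal,
    members = c(focal, others$parish_id[keep]),
    distances_km = c(0, d[keep]),
    small = small
  ), class = "neighbor_set")
}

#' @export
print.neighbor_set <- function(x, ...) {
  cat("<neighbor_set> focal ", x$focal, ": ", length(x$members) - 1L,
      " neighbor(s)", if (x$small) " [fewer than 5 parishes available]",
      "\n", sep = "")
  invisible(x)
}

# marriage spells: one row per (individual, marriage), with the date the
# union ends by a spouse's death (NA = still intact / unknown)
.marriage_spells <- function(register) {
  m <- register$acts[kind == "marriage" & !is.na(date) &
                       !is.na(ind_id1) & !is.na(ind_id2)]
  if (!nrow(m)) {
    return(data.table(ind_id = character(), spouse_id = character(),
                      start = as.Date(character()), spouse_death = as.Date(character())))
  }
  sp <- rbind(m[, .(ind_id = ind_id1, spouse_id = ind_id2, start = date)],
              m[, .(ind_id = ind_id2, spouse_id = ind_id1, start = date)])
  dd <- register$individuals[, .(spouse_id = ind_id, spouse_death = death_date)]
  merge(sp, dd, by = "spouse_id")[, .(ind_id, spouse_id, start, spouse_death)]
}

# ids of individuals in an intact marriage at `ref`
.married_at <- function(spells, ref) {
  s <- spells[start <= ref]
  if (!nrow(s)) return(character())
  s <- s[order(ind_id, -as.numeric(start))][, .SD[1L], by = ind_id]
  s[is.na(spouse_death) | spouse_death > ref, ind_id]
}

#' Pool membership at annual reference dates
#'
#' Lists, for each requested year, the individuals present at the June-15
#' reference date with known birth date and age in [14, 50), together with
#' their residence parish and marital state.  This is the common substrate
#' for every sex-ratio computation.
#'
#' @param register a `register`.
#' @param years integer vector of calendar years.
#' @param residence residence intervals as returned by
#'   [residence_intervals()] (any source: a localization strategy or a
#'   simulation truth log).
#' @return `data.table(year, ind_id, sex, parish_id, unmarried)`.
#' @export
pool_members <- function(register, years, residence) {
  residence <- as.data.table(residence)
  ind <- register$individuals[, .(ind_id, sex, birth_date, death_date)]
  spells <- .marriage_spells(register)
  out <- vector("list", length(years))
  for (k in seq_along(years)) {
    ref <- june15(years[k])
    at <- residence[start <= ref & end > ref, .(ind_id, parish_id)]
    at <- merge(at, ind, by = "ind_id")
    at <- at[!is.na(birth_date)]
    at[, age := age_years(ref, birth_date)]
    at <- at[age >= 14 & age < 50]
    at <- at[is.na(death_date) | death_date > ref]
    married <- .married_at(spells, ref)
    out[[k]] <- at[, .(year = years[k], ind_id, sex, parish_id,
                       unmarried = !(ind_id %in% married))]
  }
  rbindlist(out)
}

.scope_members <- function(members, scope, parish, parishes, year = NULL) {
  switch(scope,
    colonial = members,
    parish = members[parish_id == parish],
    regional = {
      stopifnot(!is.null(parish))
      if (is.null(year)) {
        members[, .SD[parish_id %in% neighbor_set(parish, parishes, year = .BY$year)$members],
                by = year]
      } else {
        ns <- neighbor_set(parish, parishes, year = year)
        members[parish_id %in% ns$members]
      }
    },
    stop("unknown scope: ", scope, call. = FALSE)
  )
}

#' Eligible pool counts for one year
#'
#' Counts men and women present at the June-15 reference date of `year`,
#' aged [14, 50), at the requested geographic scope.  For
#' `pool = "unmarried"` only individuals not currently in an intact marriage
#' (never married or widowed) are counted.  Acts localized to
#' [UNKNOWN_LOCALITY] contribute to colonial scope only.
#'
#' @inheritParams pool_members
#' @param year single calendar year.
#' @param scope `"colonial"`, `"regional"`, or `"parish"`.
#' @param parish focal parish id (required for regional/parish scope).
#' @param strategy localization strategy used when `residence` is not
#'   supplied.
#' @param pool `"unmarried"` (the operational pool) or `"all"`.
#' @param residence optional precomputed residence intervals.
#' @return named numeric `c(n_men, n_women)`.
#' @export
eligible_pool <- function(register, year, scope = c("colonial", "regional", "parish"),
                          parish = NULL,
                          strategy = c("retrospective", "prospective"),
                          pool = c("unmarried", "all"), residence = NULL) {
  scope <- match.arg(scope); strategy <- match.arg(strategy)
  pool <- match.arg(pool)
  if (is.null(residence)) residence <- residence_intervals(register, strategy)
  .check_year_range(register, year, residence)
  members <- pool_members(register, year, residence)
  if (pool == "unmarried") members <- members[unmarried == TRUE]
  if (scope != "colonial") members <- members[parish_id != UNKNOWN_LOCALITY]
  members <- .scope_members(members, scope, parish, register$parishes, year = year)
  c(n_men = sum(members$sex == "M"), n_women = sum(members$sex == "F"))
}

.check_year_range <- function(register, years, residence = NULL) {
  if (!is.null(residence) && nrow(residence)) {
    lo <- year_of(min(residence$start)); hi <- year_of(max(residence$end))
  } else {
    cand <- c(register$acts$date, register$individuals$birth_date,
              register$individuals$death_date)
    cand <- cand[!is.na(cand)]
    lo <- year_of(min(cand)); hi <- year_of(max(cand)) + 1L
  }
  bad <- years[years < lo | years > hi]
  if (length(bad)) {
    stop("year(s) outside register horizon [", lo, ", ", hi, "]: ",
         paste(head(bad, 5), collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Annual sex-ratio series
#'
#' Percent-male series of the eligible pool over a span of years at one
#' geographic scope, localization strategy and pool definition.
#'
#' @inheritParams eligible_pool
#' @param years integer vector of calendar years.
#' @return `data.table(year, n_men, n_women, percent_male, defined)` of class
#'   `sr_series`; `percent_male` is `100 * n_men / (n_men + n_women)` and
#'   `NA` (with `defined = FALSE`) for years with an empty pool.
#' @export
sr_series <- function(register, years, scope = c("colonial", "regional", "parish"),
                      parish = NULL,
                      strategy = c("retrospective", "prospective"),
                      pool = c("unmarried", "all"), residence = NULL) {
  scope <- match.arg(scope); strategy <- match.arg(strategy)
  pool <- match.arg(pool)
  if (is.null(residence)) residence <- residence_intervals(register, strategy)
  .check_year_range(register, years, residence)
  members <- pool_members(register, years, residence)
  if (pool == "unmarried") members <- members[unmarried == TRUE]
  if (scope != "colonial") members <- members[parish_id != UNKNOWN_LOCALITY]
  out <- rbindlist(lapply(years, function(y) {
    m <- .scope_members(members[year == y], scope, parish,
                        register$parishes, year = y)
    data.table(year = y, n_men = sum(m$sex == "M"), n_women = sum(m$sex == "F"))
  }))
  out[, percent_male := fifelse(n_men + n_women > 0,
                                100 * n_men / (n_men + n_women), NA_real_)]
  out[, defined := n_men + n_women > 0]
  setattr(out, "scope", scope); setattr(out, "strategy", strategy)
  setattr(out, "pool", pool); setattr(out, "parish", parish)
  setattr(out, "class", c("sr_series", class(out)))
  out[]
}

# sibling pairs sharing a mother or a father
.sibling_pairs <- function(register) {
  kids <- register$individuals[, .(ind_id, mother_id, father_id)]
  pair_on <- function(col) {
    a <- kids[!is.na(get(col)), .(ind_id, parent = get(col))]
    merge(a, a[, .(sib_id = ind_id, parent)], by = "parent",
          allow.cartesian = TRUE)[ind_id != sib_id, .(ind_id, sib_id)]
  }
  unique(rbind(pair_on("mother_id"), pair_on("father_id")))
}

#' Individual-level sex ratio with opposite-sex-sibling exclusion
#'
#' The sex ratio an individual actually faces excludes their own living
#' opposite-sex full- and half-siblings (sharing mother or father) from the
#' opposite-sex count, since siblings are not eligible partners.  The focal
#' individual remains in their own-sex count.
#'
#' @inheritParams eligible_pool
#' @param ind_id focal individual (must be in the pool for that year/scope).
#' @return percent male (possibly `NA` when the opposite-sex pool is empty
#'   after exclusion).
#' @export
individual_sr <- function(register, ind_id, year,
                          scope = c("colonial", "regional", "parish"),
                          parish = NULL,
                          strategy = c("retrospective", "prospective"),
                          residence = NULL) {
  scope <- match.arg(scope); strategy <- match.arg(strategy)
  focal_id <- ind_id
  if (is.null(residence)) residence <- residence_intervals(register, strategy)
  members <- pool_members(register, year, residence)[unmarried == TRUE]
  if (scope != "colonial") members <- members[parish_id != UNKNOWN_LOCALITY]
  focal_row <- members[ind_id == focal_id]
  if (!nrow(focal_row)) {
    stop("individual ", ind_id, " is not in the unmarried pool in ", year,
         call. = FALSE)
  }
  if (scope != "colonial" && is.null(parish)) parish <- focal_row$parish_id
  m <- .scope_members(members, scope, parish, register$parishes, year = year)
  sibs <- .sibling_pairs(register)[ind_id == focal_id, sib_id]
  focal_sex <- focal_row$sex
  opp <- m[sex != focal_sex]
  n_opp <- nrow(opp) - sum(opp$ind_id %in% sibs)
  n_own <- nrow(m[sex == focal_sex])
  n_men <- if (focal_sex == "M") n_own else n_opp
  n_women <- if (focal_sex == "F") n_own else n_opp
  if (n_opp <= 0) return(NA_real_)
  100 * n_men / (n_men + n_women)
}

#' Categorize a sex ratio into the six analysis bins
#'
#' Percent-male values are binned into six contiguous half-open categories:
#' 1 = \[0, 45), 2 = \[45, 50), 3 = \[50, 55), 4 = \[55, 60), 5 = \[60, 65),
#' 6 = \[65, 100\].  Category 4 (55 to <60 percent male) is the reference
#' level in every model.
#'
#' @param percent numeric vector in \[0, 100\] (NA propagates).
#' @return integer vector in 1..6 with attribute `reference = 4L`.
#' @export
categorize_sr <- function(percent) {
  if (any(percent < 0 | percent > 100, na.rm = TRUE)) {
    stop("percent must lie in [0, 100]", call. = FALSE)
  }
  out <- findInterval(percent, c(0, 45, 50, 55, 60, 65))
  out <- as.integer(out)
  attr(out, "reference") <- 4L
  out
}

#' Bookkeeping of episodes unusable below colonial scope
#'
#' Person-year pool episodes whose residence is [UNKNOWN_LOCALITY] enter the
#' colonial pool but cannot be assigned to a parish, so parish and regional
#' sex ratios rest on slightly smaller samples.  This reports the loss.
#'
#' @inheritParams sr_series
#' @return list with `n_colonial`, `n_unlocatable`, `fraction`.
#' @export
exclusion_loss <- function(register, years,
                           strategy = c("retrospective", "prospective"),
                           residence = NULL) {
  strategy <- match.arg(strategy)
  if (is.null(residence)) residence <- residence_intervals(register, strategy)
  members <- pool_members(register, years, residence)[unmarried == TRUE]
  n <- nrow(members)
  nu <- sum(members$parish_id == UNKNOWN_LOCALITY)
  list(n_colonial = n, n_unlocatable = nu,
       fraction = if (n > 0) nu / n else NA_real_)
}
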