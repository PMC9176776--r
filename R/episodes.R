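# Counting-process episode construction.
#
# One row per person-interval from age 14 to first marriage, censored at age
# 50, death, or the analysis horizon.  Rows are split at every June 15 (so
# the annual sex-ratio covariate is row-constant), at decade boundaries (so
# the decade control is row-constant), and at residence changes (so parish
# strata and parish-scope sex ratios are row-constant).  Family covariates
# add splits at parental death dates.  Immigrants enter the sex-ratio pools
# but contribute no rows: the models are fitted on colony-born life courses.

.first_marriage <- function(register) {
  m <- register$acts[kind == "marriage"]
  long <- rbind(m[!is.na(ind_id1), .(ind_id = ind_id1, date)],
                m[!is.na(ind_id2), .(ind_id = ind_id2, date)])
  if (!nrow(long)) {
    return(data.table(ind_id = character(), marriage_date = as.Date(character()),
                      any_undated = logical()))
  }
  long[, .(marriage_date = if (all(is.na(date))) as.Date(NA) else
             min(date, na.rm = TRUE),
           any_undated = anyNA(date)), by = ind_id]
}

# 14th and 50th birthday as dates; ceiling/floor keep start_age >= 14 and
# stop_age < 50 despite integer-day dates
.t14 <- function(birth) birth + ceiling(14 * DAYS_PER_YEAR)
.t50 <- function(birth) birth + floor(50 * DAYS_PER_YEAR)

#' Build the counting-process episode table
#'
#' Constructs, for every colony-born individual with a known birth date (and
#' known first-marriage date if ever married), the risk window from the 14th
#' birthday to first marriage, censored at age 50, death, or the end of the
#' analysis horizon; splits it at June 15 of each year, at decade
#' boundaries, and at residence changes; and attaches the time-varying
#' sex-ratio category (reference = category 4), the decade of the row start,
#' and strata labels (mother, row parish, birthplace).
#'
#' The sex-ratio covariate of a row is the percent-male of the configured
#' pool at the most recent June-15 reference date, at the configured scope
#' (parish and regional scope use the row's residence parish), with the
#' individual's living opposite-sex siblings removed from the opposite-sex
#' count (`sibling_exclusion = TRUE`).
#'
#' @param register a `register`.
#' @param scope `"colonial"`, `"regional"`, or `"parish"`.
#' @param strategy localization strategy for residence and pools.
#' @param pool `"unmarried"` or `"all"` pool for the sex-ratio covariate.
#' @param horizon integer `c(first_year, last_year)` of the analysis window.
#' @param sibling_exclusion remove the focal individual's living
#'   opposite-sex siblings from the opposite-sex pool count.
#' @param residence optional precomputed [residence_intervals()] table.
#' @return `data.table` of class `episode_table`: `ind_id, sex, start_date,
#'   stop_date, start_age, stop_age, event, sr_pct, sr_category, decade,
#'   parish_id, birthplace_id, mother_id`.  `attr(, "exclusions")` reports
#'   per-reason exclusion counts.
#' @export
build_episodes <- function(register,
                           scope = c("colonial", "regional", "parish"),
                           strategy = c("retrospective", "prospective"),
                           pool = c("unmarried", "all"),
                           horizon = c(1680L, 1750L),
                           sibling_exclusion = TRUE,
                           residence = NULL) {
  scope <- match.arg(scope); strategy <- match.arg(strategy)
  pool <- match.arg(pool)
  h_start <- as.Date(sprintf("%d-01-01", horizon[1]))
  h_end <- as.Date(sprintf("%d-12-31", horizon[2]))
  if (is.null(residence)) residence <- residence_intervals(register, strategy)
  residence <- as.data.table(residence)

  ind <- register$individuals
  fm <- .first_marriage(register)
  excl <- c(immigrant = sum(ind$immigrant),
            unknown_birth = 0L, unknown_marriage_date = 0L,
            married_before_14 = 0L, outside_horizon = 0L)

  subj <- ind[immigrant == FALSE]
  excl["unknown_birth"] <- sum(is.na(subj$birth_date))
  subj <- subj[!is.na(birth_date)]
  subj <- merge(subj, fm, by = "ind_id", all.x = TRUE)
  bad_marr <- subj[any_undated %in% TRUE, ind_id]
  excl["unknown_marriage_date"] <- length(bad_marr)
  subj <- subj[!(ind_id %in% bad_marr)]

  subj[, start := pmax(.t14(birth_date), h_start)]
  subj[, stop := pmin(
    fifelse(is.na(marriage_date), as.Date("9999-01-01"), marriage_date),
    .t50(birth_date),
    fifelse(is.na(death_date), as.Date("9999-01-01"), death_date),
    h_end)]
  pre14 <- subj[!is.na(marriage_date) & marriage_date < .t14(birth_date)]
  if (nrow(pre14)) {
    warning(nrow(pre14), " individual(s) married before age 14 excluded")
    excl["married_before_14"] <- nrow(pre14)
    subj <- subj[!(ind_id %in% pre14$ind_id)]
  }
  n0 <- nrow(subj)
  subj <- subj[start < stop]
  excl["outside_horizon"] <- n0 - nrow(subj)
  if (!nrow(subj)) {
    stop("no individuals with a non-empty risk window", call. = FALSE)
  }
  subj[, event_date := fifelse(!is.na(marriage_date) & marriage_date == stop,
                               marriage_date, as.Date(NA))]

  W <- subj[, .(ind_id, sex, birth_date, mother_id, start, stop, event_date)]

  # cut points: June 15s, decade Jan 1s, residence-change dates
  W[, `:=`(y0 = year_of(start), y1 = year_of(stop))]
  j15 <- W[, .(date = june15(seq(y0, y1))), by = ind_id]
  dec <- W[, {
    ys <- seq(y0, y1); ys <- ys[ys %% 10L == 0L]
    .(date = as.Date(sprintf("%d-01-01", ys)))
  }, by = ind_id]
  rchg <- residence[ind_id %in% W$ind_id, .(ind_id, date = start)]
  cuts <- rbind(j15, dec, rchg)
  cuts <- merge(cuts, W[, .(ind_id, start, stop)], by = "ind_id",
                allow.cartesian = TRUE)
  cuts <- cuts[date > start & date < stop, .(ind_id, date)]
  pts <- rbind(cuts, W[, .(ind_id, date = start)], W[, .(ind_id, date = stop)])
  setorder(pts, ind_id, date)
  pts <- unique(pts)
  rows <- pts[, .(start_date = head(date, -1L), stop_date = date[-1L]),
              by = ind_id]

  rows <- merge(rows, W[, .(ind_id, sex, birth_date, mother_id, event_date)],
                by = "ind_id")
  rows[, start_age := age_years(start_date, birth_date)]
  rows[, stop_age := age_years(stop_date, birth_date)]
  rows[, event := !is.na(event_date) & stop_date == event_date]
  rows[, decade := decade_of(start_date)]
  rows[, ref_year := ref_year(start_date)]

  # residence parish at row start (rows are cut at residence changes)
  ra <- residence[, .(ind_id, date = start, res_parish = parish_id)]
  setkey(ra, ind_id, date)
  rows[, parish_id := ra[.(rows$ind_id, rows$start_date), on = .(ind_id, date),
                         roll = TRUE, x.res_parish]]
  rows[is.na(parish_id), parish_id := UNKNOWN_LOCALITY]

  # birthplace: parish of own baptism (earliest), else unknown
  bp <- register$acts[kind == "baptism" & !is.na(ind_id1) & !is.na(date)]
  bp <- bp[order(date), .SD[1L], by = .(ind_id = ind_id1)]
  rows <- merge(rows, bp[, .(ind_id, birthplace_id = parish_id)],
                by = "ind_id", all.x = TRUE)
  rows[is.na(birthplace_id), birthplace_id := UNKNOWN_LOCALITY]

  rows <- .attach_sr(rows, register, scope, pool, residence,
                     sibling_exclusion)

  setorder(rows, ind_id, start_date)
  out <- rows[, .(ind_id, sex, start_date, stop_date, start_age, stop_age,
                  event, sr_pct, sr_category, decade, parish_id,
                  birthplace_id, mother_id)]
  setattr(out, "exclusions", excl)
  setattr(out, "scope", scope); setattr(out, "strategy", strategy)
  setattr(out, "pool", pool); setattr(out, "horizon", horizon)
  setattr(out, "class", c("episode_table", class(out)))
  out[]
}

# attach sr_pct / sr_category to episode rows
.attach_sr <- function(rows, register, scope, pool, residence,
                       sibling_exclusion) {
  years <- sort(unique(rows$ref_year))
  members <- pool_members(register, years, residence)
  if (pool == "unmarried") members <- members[unmarried == TRUE]
  rows[, row_id := .I]

  # opposite-sex siblings of each subject present in the pool, by year
  if (sibling_exclusion) {
    sp <- .sibling_pairs(register)
    sp <- sp[ind_id %in% unique(rows$ind_id)]
    sexes <- register$individuals[, .(sib_id = ind_id, sib_sex = sex)]
    sibpool <- merge(sp, members[, .(year, sib_id = ind_id, sib_parish = parish_id)],
                     by = "sib_id", allow.cartesian = TRUE)
    sibpool <- merge(sibpool, sexes, by = "sib_id")
  } else {
    sibpool <- data.table(ind_id = character(), sib_id = character(),
                          year = integer(), sib_parish = character(),
                          sib_sex = character())
  }

  if (scope == "colonial") {
    cnt <- members[, .(m = sum(sex == "M"), w = sum(sex == "F")), by = year]
    rows <- merge(rows, cnt, by.x = "ref_year", by.y = "year", all.x = TRUE)
    adj <- sibpool[, .(ind_id, year, sib_sex)]
  } else {
    members_p <- members[parish_id != UNKNOWN_LOCALITY]
    cntp <- members_p[, .(m = sum(sex == "M"), w = sum(sex == "F")),
                      by = .(year, parish_id)]
    if (scope == "parish") {
      rows <- merge(rows, cntp, by.x = c("ref_year", "parish_id"),
                    by.y = c("year", "parish_id"), all.x = TRUE)
      adj <- sibpool[, .(ind_id, year, sib_sex, unit = sib_parish)]
    } else {
      # regional: per (year, focal parish) neighbor aggregation
      combos <- unique(rows[parish_id != UNKNOWN_LOCALITY,
                            .(ref_year, parish_id)])
      N <- rbindlist(lapply(seq_len(nrow(combos)), function(k) {
        y <- combos$ref_year[k]; f <- combos$parish_id[k]
        ns <- tryCatch(neighbor_set(f, register$parishes, year = y),
                       error = function(e) NULL)
        if (is.null(ns)) return(NULL)
        data.table(year = y, focal = f, member = ns$members)
      }))
      if (is.null(N) || !nrow(N)) {
        N <- data.table(year = integer(), focal = character(),
                        member = character())
      }
      cntr <- merge(N, cntp, by.x = c("year", "member"),
                    by.y = c("year", "parish_id"))[
                      , .(m = sum(m), w = sum(w)), by = .(year, focal)]
      rows <- merge(rows, cntr, by.x = c("ref_year", "parish_id"),
                    by.y = c("year", "focal"), all.x = TRUE)
      adj <- merge(sibpool, N, by.x = c("year", "sib_parish"),
                   by.y = c("year", "member"),
                   allow.cartesian = TRUE)[, .(ind_id, year, sib_sex,
                                               unit = focal)]
    }
  }

  if (nrow(sibpool)) {
    if (scope == "colonial") {
      nadj <- adj[, .(n_ms = sum(sib_sex == "M"), n_fs = sum(sib_sex == "F")),
                  by = .(ind_id, year)]
      rows <- merge(rows, nadj, by.x = c("ind_id", "ref_year"),
                    by.y = c("ind_id", "year"), all.x = TRUE)
    } else {
      nadj <- adj[, .(n_ms = sum(sib_sex == "M"), n_fs = sum(sib_sex == "F")),
                  by = .(ind_id, year, unit)]
      rows <- merge(rows, nadj,
                    by.x = c("ind_id", "ref_year", "parish_id"),
                    by.y = c("ind_id", "year", "unit"), all.x = TRUE)
    }
  } else {
    rows[, `:=`(n_ms = 0L, n_fs = 0L)]
  }
  rows[is.na(n_ms), n_ms := 0L]; rows[is.na(n_fs), n_fs := 0L]
  rows[is.na(m), m := 0L]; rows[is.na(w), w := 0L]

  # focal remains in the own-sex count; opposite-sex siblings removed
  rows[, `:=`(m_adj = as.numeric(m), w_adj = as.numeric(w))]
  rows[sex == "F", m_adj := pmax(m - n_ms, 0)]
  rows[sex == "M", w_adj := pmax(w - n_fs, 0)]
  rows[, sr_pct := fifelse(m_adj + w_adj > 0,
                           100 * m_adj / (m_adj + w_adj), NA_real_)]
  if (scope != "colonial") {
    rows[parish_id == UNKNOWN_LOCALITY, sr_pct := NA_real_]
  }
  rows[, sr_category := {
    out <- rep(NA_integer_, .N)
    ok <- !is.na(sr_pct)
    out[ok] <- categorize_sr(sr_pct[ok])
    out
  }]
  rows[, c("m", "w", "n_ms", "n_fs", "m_adj", "w_adj", "row_id") := NULL]
  rows
}

#' Attach family covariates to an episode table
#'
#' Adds the family-structure controls: birth order (rank among the mother's
#' live-born children), number of siblings (sharing mother or father),
#' numbers of brothers and sisters alive at the individual's exact 14th
#' birthday, and time-varying maternal/paternal-loss flags.  Rows are
#' additionally split at a parent's death date so the loss flags are
#' row-constant.
#'
#' @param episodes an `episode_table` from [build_episodes()].
#' @param register the `register` the table was built from.
#' @return the episode table with columns `birth_order, n_siblings,
#'   n_brothers_alive_14, n_sisters_alive_14, mother_dead, father_dead`
#'   appended.
#' @export
attach_family_covariates <- function(episodes, register) {
  ep <- as.data.table(episodes)
  attrs <- attributes(episodes)
  ind <- register$individuals

  fam <- ind[ind_id %in% unique(ep$ind_id),
             .(ind_id, birth_date, mother_id, father_id)]
  pdeath <- ind[, .(parent_id = ind_id, parent_death = death_date)]
  fam <- merge(fam, pdeath[, .(mother_id = parent_id, mother_death = parent_death)],
               by = "mother_id", all.x = TRUE)
  fam <- merge(fam, pdeath[, .(father_id = parent_id, father_death = parent_death)],
               by = "father_id", all.x = TRUE)

  # split rows at parental deaths inside a row
  for (col in c("mother_death", "father_death")) {
    ep <- merge(ep, fam[, c("ind_id", col), with = FALSE], by = "ind_id")
    d <- ep[[col]]
    inside <- !is.na(d) & d > ep$start_date & d < ep$stop_date
    if (any(inside)) {
      left <- ep[inside]; right <- ep[inside]
      left[, stop_date := get(col)]
      left[, event := FALSE]
      right[, start_date := get(col)]
      ep <- rbind(ep[!inside], left, right)
    }
    ep[, (col) := NULL]
  }
  bd <- ind[, .(ind_id, birth_date)]
  ep <- merge(ep, bd, by = "ind_id")
  ep[, start_age := age_years(start_date, birth_date)]
  ep[, stop_age := age_years(stop_date, birth_date)]
  ep[, birth_date := NULL]

  # birth order among mother's live-born children
  kids <- ind[!is.na(mother_id), .(ind_id, mother_id, birth_date)]
  setorder(kids, mother_id, birth_date, ind_id)
  kids[, birth_order := seq_len(.N), by = mother_id]

  # siblings sharing either parent, with life dates
  sp <- .sibling_pairs(register)
  sp <- sp[ind_id %in% unique(ep$ind_id)]
  sibinfo <- merge(sp, ind[, .(sib_id = ind_id, sib_sex = sex,
                               sib_birth = birth_date, sib_death = death_date)],
                   by = "sib_id")
  focal14 <- fam[, .(ind_id, t14 = .t14(birth_date))]
  sibinfo <- merge(sibinfo, focal14, by = "ind_id")
  sibcnt <- sibinfo[, .(
    n_siblings = .N,
    n_brothers_alive_14 = sum(sib_sex == "M" & !is.na(sib_birth) &
                                sib_birth <= t14 &
                                (is.na(sib_death) | sib_death > t14)),
    n_sisters_alive_14 = sum(sib_sex == "F" & !is.na(sib_birth) &
                               sib_birth <= t14 &
                               (is.na(sib_death) | sib_death > t14))
  ), by = ind_id]

  ep <- merge(ep, kids[, .(ind_id, birth_order)], by = "ind_id", all.x = TRUE)
  ep <- merge(ep, sibcnt, by = "ind_id", all.x = TRUE)
  for (col in c("n_siblings", "n_brothers_alive_14", "n_sisters_alive_14")) {
    ep[is.na(get(col)), (col) := 0L]
  }
  # only children with a known mother get birth_order 1 even if unlisted
  ep[is.na(birth_order) & ind_id %in% fam[!is.na(mother_id), ind_id],
     birth_order := 1L]

  ep <- merge(ep, fam[, .(ind_id, mother_death, father_death)],
              by = "ind_id", all.x = TRUE)
  ep[, mother_dead := !is.na(mother_death) & mother_death <= start_date]
  ep[, father_dead := !is.na(father_death) & father_death <= start_date]
  ep[, c("mother_death", "father_death") := NULL]

  setorder(ep, ind_id, start_date)
  for (a in c("exclusions", "scope", "strategy", "pool", "horizon")) {
    setattr(ep, a, attrs[[a]])
  }
  setattr(ep, "class", unique(c("episode_table", class(ep))))
  ep[]
}
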