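# Demographic microsimulation of a settler colony register.
#
# The generator emulates the statistical structure the analysis assumes: a
# heavily male-skewed immigration stream followed by a sponsored female
# immigration pulse and a halt of immigration, after which a semi-closed
# population grows by natural fertility under pre-transition mortality.
# Events run on a yearly step aligned to the June-15 reference date: pools
# are evaluated at June 15, and the events of the following twelve months
# are dated uniformly inside the step, so episode splitting at June 15 is
# exercised nontrivially.  A truth log (exact residence history, exact pool
# counts, the generative sex-ratio effect) accompanies every emitted
# register so downstream stages can be tested against ground truth.

.age_band_lookup <- function(bands, ages) {
  # bands: data.frame(age_from, rate); constant within band
  idx <- findInterval(ages, bands$age_from)
  idx[idx < 1L] <- 1L
  bands$rate[idx]
}

.default_marriage_baseline <- function() {
  list(
    F = data.frame(age_from = c(14, 16, 20, 25, 30, 40),
                   rate = c(0.05, 0.20, 0.25, 0.18, 0.10, 0.04)),
    M = data.frame(age_from = c(14, 18, 22, 26, 31, 40),
                   rate = c(0.005, 0.08, 0.20, 0.22, 0.12, 0.05))
  )
}

.default_mortality <- function() {
  data.frame(age_from = c(0, 1, 5, 14, 40, 60, 75),
             rate = c(0.20, 0.05, 0.012, 0.012, 0.025, 0.06, 0.15))
}

#' Simulation parameters
#'
#' Builds and validates the parameter set for [simulate_colony()].  The
#' `"colony"` preset encodes the study conditions the package is built
#' around, at desk scale: an all-but-male immigration stream from the start
#' year, a sponsored female-immigration pulse (1663-1672), immigration
#' halting in the early 1670s, roughly ten births per married woman
#' surviving her fertile span, pre-transition mortality, sequential parish
#' founding, inter-parish moves, marriages sometimes recorded in the bride's
#' parish, a share of acts with unknown locality, and immigrants carrying a
#' dated out-of-colony act with some probability.  The `"demo"` preset is a
#' smaller, shorter variant for quick runs and tests.
#'
#' @param preset `"colony"` or `"demo"`.
#' @param ... overrides for any field of the returned list (see Details).
#' @details Fields: `start_year`, `end_year`; `male_imm`, `female_imm`
#'   (`list(years, per_year)`); `female_pulse` (`list(start, end, total)`);
#'   `arrival_age_m`, `arrival_age_f` (uniform age ranges at arrival);
#'   `marriage_baseline` (per-sex age-band annual hazards); `beta_sr`
#'   (named `c(F=, M=)` log-hazard effect per 10 points of percent-male
#'   above 50 on the colonial unmarried pool); `p_birth` (annual birth
#'   probability for eligible married women), `birth_spacing` (minimum
#'   years between births), `fert_age` (fertile age range); `mortality`
#'   (age-band annual death probabilities); `n_parishes`,
#'   `parish_extent_km`; `move_prob`; `p_bride_parish` (probability a
#'   marriage act is recorded in the bride's parish); `miss_locality`
#'   (fraction of acts with unknown locality); `p_french_act` (probability
#'   an immigrant carries a dated out-of-colony baptism).
#' @return list of class `sim_params`.
#' @export
sim_params <- function(preset = c("colony", "demo"), ...) {
  preset <- match.arg(preset)
  p <- list(
    start_year = 1650L, end_year = 1750L,
    male_imm = list(years = 1650:1672, per_year = 10L),
    female_imm = list(years = 1650:1662, per_year = 2L),
    female_pulse = list(start = 1663L, end = 1672L, total = 100L),
    arrival_age_m = c(18, 35), arrival_age_f = c(16, 30),
    marriage_baseline = .default_marriage_baseline(),
    beta_sr = c(F = 0.15, M = 0),
    p_birth = 0.35, birth_spacing = 2L, fert_age = c(15, 45),
    mortality = .default_mortality(),
    n_parishes = 12L, parish_extent_km = c(100, 20),
    move_prob = 0.02, p_bride_parish = 0.6,
    miss_locality = 0.05, p_french_act = 0.7
  )
  if (preset == "demo") {
    p$end_year <- 1720L
    p$male_imm <- list(years = 1650:1670, per_year = 8L)
    p$female_pulse <- list(start = 1663L, end = 1672L, total = 60L)
    p$n_parishes <- 8L
  }
  over <- list(...)
  unknown <- setdiff(names(over), names(p))
  if (length(unknown)) stop("unknown sim_params field(s): ",
                            paste(unknown, collapse = ", "), call. = FALSE)
  p[names(over)] <- over
  .validate_sim_params(p)
  structure(p, class = "sim_params")
}

.validate_sim_params <- function(p) {
  stopifnot(p$start_year < p$end_year, p$n_parishes >= 2L)
  probs <- c(p$p_birth, p$move_prob, p$p_bride_parish, p$miss_locality,
             p$p_french_act, p$mortality$rate)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0,1]",
                                       call. = FALSE)
  if (any(p$marriage_baseline$F$rate < 0) || any(p$marriage_baseline$M$rate < 0)) {
    stop("marriage hazards must be non-negative", call. = FALSE)
  }
  invisible(TRUE)
}

.immigration_schedule <- function(p) {
  yrs <- p$start_year:p$end_year
  n_m <- integer(length(yrs)); n_f <- integer(length(yrs))
  n_m[yrs %in% p$male_imm$years] <- p$male_imm$per_year
  n_f[yrs %in% p$female_imm$years] <- p$female_imm$per_year
  pulse_yrs <- p$female_pulse$start:p$female_pulse$end
  if (p$female_pulse$total > 0 && length(pulse_yrs)) {
    base <- p$female_pulse$total %/% length(pulse_yrs)
    extra <- p$female_pulse$total %% length(pulse_yrs)
    add <- rep(base, length(pulse_yrs))
    if (extra > 0) add[seq_len(extra)] <- add[seq_len(extra)] + 1L
    m <- match(pulse_yrs, yrs)
    ok <- !is.na(m)
    n_f[m[ok]] <- n_f[m[ok]] + add[ok]
  }
  data.table(year = yrs, n_men = n_m, n_women = n_f)
}

# draw a permutation of a vector (length-1 safe)
.shuffle <- function(x) x[sample.int(length(x))]

#' Simulate a colony register with known ground truth
#'
#' Runs the yearly-step microsimulation described in [sim_params()] and
#' emits a fully linked register plus a truth log.  Within a step: (1)
#' immigrants arrive and are placed in a founded parish; (2) pools are
#' evaluated at June 15 and recorded in the truth log; (3) unmarried
#' individuals aged \[14, 50) marry with hazard
#' `baseline(age, sex) * exp(beta_sr * (percent_male - 50) / 10)` and are
#' matched to a random eligible opposite-sex non-sibling partner; (4)
#' eligible married women give birth; (5) deaths are drawn from the
#' mortality schedule (widowed survivors return to the unmarried pool); (6)
#' individuals and families move between parishes.  Every event emits an
#' act dated uniformly within the step; a fraction of acts lose their
#' locality.  The same seed always yields an identical register.
#'
#' @param params a [sim_params()] object.
#' @param seed integer seed; all randomness flows from it.
#' @return list of class `colony_sim` with elements `register` (a
#'   `register`), and `truth`: `residence` (exact residence intervals in the
#'   format of [residence_intervals()]), `pools` (exact per-year, per-parish
#'   pool counts by sex, unmarried and total), `colonial` (per-year colonial
#'   unmarried counts and percent male), and `beta_sr`.
#' @export
simulate_colony <- function(params = sim_params(), seed = 1L) {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(as.integer(seed))

  yrs <- p$start_year:p$end_year
  sched <- .immigration_schedule(p)

  # parishes: two founded at start, the rest spread over the first 70 years
  npar <- p$n_parishes
  founded_years <- c(rep(p$start_year, min(2L, npar)),
                     sort(sample(p$start_year:(min(p$start_year + 70L, p$end_year)),
                                 max(0L, npar - 2L), replace = TRUE)))
  parish_ids <- sprintf("P%02d", seq_len(npar))
  parishes <- data.table(
    parish_id = parish_ids, name = paste0("Parish ", parish_ids),
    founded = as.Date(sprintf("%d-01-01", founded_years)), founded_prec = "day",
    x_km = round(runif(npar, 0, p$parish_extent_km[1]), 2),
    y_km = round(runif(npar, 0, p$parish_extent_km[2]), 2),
    in_colony = TRUE
  )

  # growable person state (parallel vectors, indexed by integer id)
  P <- new.env(parent = emptyenv())
  P$sex <- character(); P$birth <- as.Date(character())
  P$death <- as.Date(character()); P$mother <- integer(); P$father <- integer()
  P$immigrant <- logical(); P$parish <- character()
  P$married <- logical(); P$spouse <- integer()
  P$last_birth_year <- integer(); P$event_year <- integer()
  P$n_marr <- integer()
  add_persons <- function(sex, birth, mother = NA_integer_, father = NA_integer_,
                          immigrant = FALSE, parish) {
    n <- length(sex)
    ids <- length(P$sex) + seq_len(n)
    P$sex <- c(P$sex, sex); P$birth <- c(P$birth, birth)
    P$death <- c(P$death, as.Date(rep(NA, n)))
    P$mother <- c(P$mother, rep_len(mother, n))
    P$father <- c(P$father, rep_len(father, n))
    P$immigrant <- c(P$immigrant, rep_len(immigrant, n))
    P$parish <- c(P$parish, parish)
    P$married <- c(P$married, rep(FALSE, n))
    P$spouse <- c(P$spouse, rep(NA_integer_, n))
    P$last_birth_year <- c(P$last_birth_year, rep(NA_integer_, n))
    P$event_year <- c(P$event_year, rep(NA_integer_, n))
    P$n_marr <- c(P$n_marr, rep(0L, n))
    ids
  }

  acts <- list()
  add_acts <- function(kind, date, parish, id1, id2 = NA_integer_,
                       rank = NA_integer_) {
    acts[[length(acts) + 1L]] <<- data.table(
      kind = kind, date = date, parish = parish,
      id1 = id1, id2 = rep_len(id2, length(id1)),
      rank = rep_len(rank, length(id1)))
  }
  drop_locality <- function(parish) {
    miss <- runif(length(parish)) < p$miss_locality
    parish[miss] <- UNKNOWN_LOCALITY
    parish
  }

  res_log <- list()
  log_res <- function(ids, dates, parish) {
    res_log[[length(res_log) + 1L]] <<- data.table(
      id = ids, date = rep_len(dates, length(ids)),
      parish = rep_len(parish, length(ids)))
  }

  pools <- list(); colonial <- list()
  horizon_end <- as.Date(sprintf("%d-12-31", p$end_year))

  for (t in yrs) {
    ref <- june15(t)
    founded_now <- parishes[founded <= ref, parish_id]
    row <- sched[year == t]

    # 1. immigration -------------------------------------------------------
    for (s in c("M", "F")) {
      n_new <- if (s == "M") row$n_men else row$n_women
      if (n_new > 0) {
        rng <- if (s == "M") p$arrival_age_m else p$arrival_age_f
        age_new <- runif(n_new, rng[1], rng[2])
        birth <- ref - round(age_new * DAYS_PER_YEAR)
        par <- founded_now[sample.int(length(founded_now), n_new, replace = TRUE)]
        ids <- add_persons(rep(s, n_new), birth, immigrant = TRUE, parish = par)
        log_res(ids, ref, par)
        has_fr <- which(runif(n_new) < p$p_french_act)
        if (length(has_fr)) {
          add_acts("baptism", birth[has_fr], "FRANCE", ids[has_fr])
        }
      }
    }

    alive <- is.na(P$death)
    if (!any(alive)) {
      future <- sched[year > t, sum(n_men + n_women)]
      if (future == 0) stop("population extinct before horizon end (year ", t,
                            ")", call. = FALSE)
      next
    }

    # 2. pools at the reference date --------------------------------------
    age <- age_years(ref, P$birth)
    in_range <- alive & age >= 14 & age < 50
    elig <- in_range & !P$married
    idx_all <- which(in_range); idx_elig <- which(elig)
    pools[[length(pools) + 1L]] <- data.table(
      year = t,
      parish_id = P$parish[idx_all],
      sex = P$sex[idx_all],
      unmarried = !P$married[idx_all]
    )
    n_m <- sum(P$sex[idx_elig] == "M"); n_w <- sum(P$sex[idx_elig] == "F")
    pm <- if (n_m + n_w > 0) 100 * n_m / (n_m + n_w) else NA_real_
    colonial[[length(colonial) + 1L]] <- data.table(
      year = t, n_men = n_m, n_women = n_w, percent_male = pm)

    # 3. marriages ---------------------------------------------------------
    if (length(idx_elig) && !is.na(pm)) {
      bl <- p$marriage_baseline
      haz <- numeric(length(idx_elig))
      for (s in c("M", "F")) {
        pick <- P$sex[idx_elig] == s
        haz[pick] <- .age_band_lookup(bl[[s]], age[idx_elig][pick]) *
          exp(p$beta_sr[[s]] * (pm - 50) / 10)
      }
      marry <- runif(length(idx_elig)) < (1 - exp(-haz))
      men <- idx_elig[marry & P$sex[idx_elig] == "M"]
      wom <- idx_elig[marry & P$sex[idx_elig] == "F"]
      n_pairs <- min(length(men), length(wom))
      if (n_pairs > 0) {
        men <- .shuffle(men)[seq_len(n_pairs)]
        wom <- .shuffle(wom)[seq_len(n_pairs)]
        sib <- (!is.na(P$mother[men]) & !is.na(P$mother[wom]) &
                  P$mother[men] == P$mother[wom]) |
               (!is.na(P$father[men]) & !is.na(P$father[wom]) &
                  P$father[men] == P$father[wom])
        men <- men[!sib]; wom <- wom[!sib]
        if (length(men)) {
          dates <- ref + sample.int(350L, length(men), replace = TRUE)
          bride_par <- P$parish[wom]; groom_par <- P$parish[men]
          ranks <- P$n_marr[men] + 1L
          P$married[c(men, wom)] <- TRUE
          P$spouse[men] <- wom; P$spouse[wom] <- men
          P$n_marr[c(men, wom)] <- P$n_marr[c(men, wom)] + 1L
          P$event_year[c(men, wom)] <- t
          act_par <- fifelse(runif(length(men)) < p$p_bride_parish,
                             bride_par, groom_par)
          add_acts("marriage", dates, drop_locality(act_par), men, wom, ranks)
          moved <- which(bride_par != groom_par)
          if (length(moved)) {
            P$parish[wom[moved]] <- groom_par[moved]
            log_res(wom[moved], dates[moved], groom_par[moved])
          }
        }
      }
    }

    # 4. births ------------------------------------------------------------
    n_before <- length(alive)
    mothers <- which(alive & P$married[seq_len(n_before)] & P$sex[seq_len(n_before)] == "F" &
                       age >= p$fert_age[1] & age < p$fert_age[2] &
                       (is.na(P$event_year[seq_len(n_before)]) |
                          P$event_year[seq_len(n_before)] != t) &
                       (is.na(P$last_birth_year[seq_len(n_before)]) |
                          t - P$last_birth_year[seq_len(n_before)] >= p$birth_spacing))
    if (length(mothers)) {
      gives <- mothers[runif(length(mothers)) < p$p_birth]
      if (length(gives)) {
        bdates <- ref + sample.int(350L, length(gives), replace = TRUE)
        csex <- sample(c("M", "F"), length(gives), replace = TRUE)
        mo_par <- P$parish[gives]
        ids <- add_persons(csex, bdates, mother = gives,
                           father = P$spouse[gives], immigrant = FALSE,
                           parish = mo_par)
        log_res(ids, bdates, mo_par)
        add_acts("baptism", bdates, drop_locality(mo_par), ids)
        P$last_birth_year[gives] <- t
        P$event_year[gives] <- t
        P$event_year[ids] <- t  # newborns not exposed this step
      }
    }

    # 5. deaths ------------------------------------------------------------
    alive <- is.na(P$death)
    exposed <- which(alive & (is.na(P$event_year) | P$event_year != t))
    if (length(exposed)) {
      q <- .age_band_lookup(p$mortality, age_years(ref, P$birth[exposed]))
      dies <- exposed[runif(length(exposed)) < q]
      if (length(dies)) {
        ddates <- ref + sample.int(350L, length(dies), replace = TRUE)
        P$death[dies] <- ddates
        add_acts("burial", ddates, drop_locality(P$parish[dies]), dies)
        sp <- P$spouse[dies]
        was_married <- P$married[dies]
        P$married[dies] <- FALSE; P$spouse[dies] <- NA_integer_
        widowed <- sp[!is.na(sp) & was_married]
        if (length(widowed)) {
          P$married[widowed] <- FALSE; P$spouse[widowed] <- NA_integer_
        }
      }
    }

    # 6. moves --------------------------------------------------------------
    if (p$move_prob > 0 && length(founded_now) > 1L) {
      alive <- is.na(P$death)
      age_now <- age_years(ref, P$birth)
      heads <- which(alive & (is.na(P$event_year) | P$event_year != t) &
                       age_now >= 14 & (P$sex == "M" | !P$married))
      movers <- heads[runif(length(heads)) < p$move_prob]
      if (length(movers)) {
        mdates <- ref + sample.int(350L, length(movers), replace = TRUE)
        for (j in seq_along(movers)) {
          i <- movers[j]
          cand <- setdiff(founded_now, P$parish[i])
          dest <- if (length(cand) == 1L) cand else cand[sample.int(length(cand), 1L)]
          group <- i
          if (P$married[i] && !is.na(P$spouse[i])) group <- c(group, P$spouse[i])
          kids <- which(alive & !P$married &
                          (is.na(P$event_year) | P$event_year != t) &
                          ((!is.na(P$mother) & P$mother %in% group) |
                             (!is.na(P$father) & P$father %in% group)) &
                          P$parish == P$parish[i] & age_now < 14)
          group <- unique(c(group, kids))
          P$parish[group] <- dest
          log_res(group, mdates[j], dest)
        }
      }
    }
  }

  # assemble register ------------------------------------------------------
  n <- length(P$sex)
  id_of <- function(k) ifelse(is.na(k), NA_character_, sprintf("I%05d", k))
  individuals <- data.table(
    ind_id = id_of(seq_len(n)), sex = P$sex,
    birth_date = P$birth, birth_prec = "day",
    death_date = P$death,
    death_prec = ifelse(is.na(P$death), "unknown", "day"),
    mother_id = id_of(P$mother), father_id = id_of(P$father),
    immigrant = P$immigrant
  )
  if (length(acts)) {
    raw <- rbindlist(acts)
    acts_dt <- data.table(
      act_id = sprintf("A%06d", seq_len(nrow(raw))),
      kind = raw$kind, date = raw$date, date_prec = "day",
      parish_id = raw$parish,
      ind_id1 = id_of(raw$id1), ind_id2 = id_of(raw$id2),
      marriage_rank = raw$rank
    )
  } else {
    acts_dt <- data.table(act_id = character(), kind = character(),
                          date = as.Date(character()), date_prec = character(),
                          parish_id = character(), ind_id1 = character(),
                          ind_id2 = character(), marriage_rank = integer())
  }
  all_parishes <- rbind(parishes, data.table(
    parish_id = "FRANCE", name = "France (out of colony)",
    founded = as.Date("1000-01-01"), founded_prec = "day",
    x_km = NA_real_, y_km = NA_real_, in_colony = FALSE))
  reg <- new_register(all_parishes, individuals, acts_dt,
                      source = paste0("simulate_colony:seed=", seed))

  # truth residence intervals ----------------------------------------------
  res <- rbindlist(res_log)
  setorder(res, id, date)
  res[, end := shift(date, -1L), by = id]
  exit <- fifelse(is.na(P$death), horizon_end, P$death)
  res[is.na(end), end := exit[id]]
  res <- res[date < end]
  truth_res <- res[, .(ind_id = id_of(id), parish_id = parish,
                       start = date, end)]
  truth_res[, strategy := "truth"]

  truth_pools <- rbindlist(pools)[, .(
    n_unmarried_men = sum(sex == "M" & unmarried),
    n_unmarried_women = sum(sex == "F" & unmarried),
    n_all_men = sum(sex == "M"), n_all_women = sum(sex == "F")
  ), by = .(year, parish_id)]
  setorder(truth_pools, year, parish_id)

  structure(list(
    register = reg,
    truth = list(residence = truth_res, pools = truth_pools,
                 colonial = rbindlist(colonial), beta_sr = p$beta_sr),
    params = p, seed = as.integer(seed)
  ), class = "colony_sim")
}

#' @export
print.colony_sim <- function(x, ...) {
  cat("<colony_sim> seed ", x$seed, ": ", sep = "")
  print(x$register)
  invisible(x)
}

#' Single-covariate cohort generator for estimator validation
#'
#' Simulates first-marriage waiting times for a cohort of women entering the
#' risk window at age 14 under a constant baseline hazard and a fixed binary
#' high/low sex-ratio covariate with a known hazard ratio, censored at age
#' 50.  This harness has an analytically known truth and is used to check
#' parameter recovery and confidence-interval coverage of the Cox fitting
#' machinery.
#'
#' @param n cohort size.
#' @param hr true hazard ratio of the `sr_high = 1` group.
#' @param baseline annual baseline marriage hazard.
#' @param seed integer seed.
#' @return `data.table(ind_id, sex, start_age, stop_age, event, sr_high)`,
#'   one counting-process row per woman.
#' @export
simulate_binary_sr_cohort <- function(n, hr = 1.5, baseline = 0.08, seed = 1L) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(as.integer(seed))
  x <- rbinom(n, 1L, 0.5)
  tt <- rexp(n, rate = baseline * hr^x)
  cens <- 36  # age 50 - age 14
  event <- tt <= cens
  data.table(
    ind_id = sprintf("S%05d", seq_len(n)), sex = "F",
    start_age = 14, stop_age = 14 + pmin(tt, cens),
    event = event, sr_high = x
  )
}

#' Null-effect cohort generator for calibration checks
#'
#' Like [simulate_binary_sr_cohort()] but with a six-level categorical
#' sex-ratio covariate drawn independently of the (constant) hazard, so
#' every level's true hazard ratio is 1.  Used to verify that the fitting
#' machinery's type-I error rate is nominal.
#'
#' @param n cohort size.
#' @param baseline annual baseline marriage hazard.
#' @param seed integer seed.
#' @return `data.table(ind_id, sex, start_age, stop_age, event,
#'   sr_category)`.
#' @export
simulate_null_cohort <- function(n, baseline = 0.08, seed = 1L) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(as.integer(seed))
  cat6 <- sample(1:6, n, replace = TRUE)
  tt <- rexp(n, rate = baseline)
  cens <- 36
  data.table(
    ind_id = sprintf("S%05d", seq_len(n)), sex = "F",
    start_age = 14, stop_age = 14 + pmin(tt, cens),
    event = tt <= cens, sr_category = cat6
  )
}
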