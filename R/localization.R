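# Residence localization: where (and from when) each individual is present.
#
# Parish registers only pin an individual to a place at the dates of their
# acts; the years in between are ambiguous.  Two bracketing strategies are
# implemented:
#   retrospective - stay in the earlier-known parish until a later act (own
#     marriage, or a younger sibling's baptism while the focal is under 14)
#     places the individual elsewhere: the latest plausible arrival.
#   prospective   - a differing subsequent record ends the prior residence
#     immediately after the earlier act: the earliest plausible arrival.
# For immigrants the same logic bounds colony entry: retrospective entry is
# the first in-colony act, prospective entry the day after the last
# out-of-colony act.

.act_kind_prio <- c(baptism = 1L, marriage = 2L, burial = 3L)

# default end of observation when an individual's death is unknown
register_horizon_end <- function(register) {
  cand <- c(register$acts$date, register$individuals$death_date)
  cand <- cand[!is.na(cand)]
  if (!length(cand)) stop("register has no dated records", call. = FALSE)
  max(cand) + 1L
}

# long table of (ind_id, act) pairs with parish colony status attached
.acts_long <- function(register) {
  a <- register$acts
  long <- rbind(
    a[!is.na(ind_id1), .(ind_id = ind_id1, act_id, kind, date, parish_id)],
    a[!is.na(ind_id2), .(ind_id = ind_id2, act_id, kind, date, parish_id)]
  )
  long[is.na(parish_id), parish_id := UNKNOWN_LOCALITY]
  pc <- register$parishes[, .(parish_id, in_colony)]
  long <- merge(long, pc, by = "parish_id", all.x = TRUE)
  # unknown locality is treated as in-colony-with-unknown-parish
  long[parish_id == UNKNOWN_LOCALITY, in_colony := TRUE]
  long[]
}

#' Presence windows in the colony
#'
#' Computes, per individual, the date interval during which the individual is
#' considered present in the colony under a localization strategy.
#' Colony-born individuals enter at birth; immigrants enter at the first
#' in-colony act (retrospective) or the day after their last out-of-colony
#' act (prospective; if they carry none, the first in-colony act minus
#' `lead_days`).  Exit is death, or `horizon_end` when the death date is
#' unknown.
#'
#' @param register a `register`.
#' @param strategy `"retrospective"` or `"prospective"`.
#' @param horizon_end censoring date for individuals without a known death;
#'   default: day after the register's last dated record.
#' @param lead_days fallback lead (days) before the first in-colony act used
#'   as prospective entry for immigrants without out-of-colony acts.
#' @return `data.table` with columns `ind_id, entry, exit`.  Individuals that
#'   cannot be placed (no dated act; immigrants with no in-colony act) are
#'   omitted and listed in `attr(, "excluded")`.
#' @export
presence_intervals <- function(register, strategy = c("retrospective", "prospective"),
                               horizon_end = NULL, lead_days = 0) {
  strategy <- match.arg(strategy)
  if (is.null(horizon_end)) horizon_end <- register_horizon_end(register)
  horizon_end <- as.Date(horizon_end)
  long <- .acts_long(register)[!is.na(date)]
  ind <- register$individuals

  per <- long[, .(
    first_in = suppressWarnings(min(date[in_colony %in% TRUE])),
    last_out = suppressWarnings(max(date[in_colony %in% FALSE])),
    n_in = sum(in_colony %in% TRUE)
  ), by = ind_id]
  tab <- merge(ind[, .(ind_id, birth_date, death_date, immigrant)], per,
               by = "ind_id", all.x = TRUE)
  tab[is.na(n_in), n_in := 0L]

  excluded <- data.table(ind_id = character(), reason = character())
  no_act <- tab[!(ind_id %in% per$ind_id), ind_id]
  if (length(no_act)) {
    excluded <- rbind(excluded, data.table(ind_id = no_act, reason = "no dated act"))
  }
  no_col <- tab[immigrant & n_in == 0L & ind_id %in% per$ind_id, ind_id]
  if (length(no_col)) {
    excluded <- rbind(excluded,
                      data.table(ind_id = no_col, reason = "immigrant without in-colony act"))
  }
  tab <- tab[ind_id %in% per$ind_id & !(ind_id %in% no_col)]

  tab[, entry := as.Date(NA)]
  tab[immigrant == FALSE, entry := fifelse(is.na(birth_date), first_in, birth_date)]
  if (strategy == "retrospective") {
    tab[immigrant == TRUE, entry := first_in]
  } else {
    tab[immigrant == TRUE,
        entry := fifelse(is.finite(last_out), last_out + 1L, first_in - lead_days)]
  }
  tab[, exit := fifelse(is.na(death_date), horizon_end, death_date)]
  out <- tab[entry < exit, .(ind_id, entry, exit)]
  setkey(out, ind_id)
  setattr(out, "excluded", excluded)
  out[]
}

#' Residence intervals under a localization strategy
#'
#' Attributes a parish to each individual over their full presence window.
#' Location anchors are the individual's own dated in-colony acts with a
#' known parish plus, while the individual is strictly under 14, the baptism
#' parishes of younger siblings (children stay with their parents until 14).
#' Between two anchors in different parishes, the retrospective strategy
#' extends the earlier parish up to the later act's date; the prospective
#' strategy switches to the later parish the day after the earlier act.
#' Acts with unknown locality are not anchors and never break a residence
#' spell.  Individuals with no known-parish anchor get a single
#' [UNKNOWN_LOCALITY] interval covering their presence window.
#'
#' @inheritParams presence_intervals
#' @param ind_ids optional subset of individuals.
#' @return `data.table(ind_id, parish_id, start, end, strategy)` with
#'   half-open `[start, end)` intervals that tile each presence window.
#'   `attr(, "excluded")` carries unplaceable individuals,
#'   `attr(, "conflicts")` same-day anchors in different parishes (resolved
#'   by act-kind priority baptism > marriage > burial, then act id).
#' @export
residence_intervals <- function(register, strategy = c("retrospective", "prospective"),
                                ind_ids = NULL, horizon_end = NULL, lead_days = 0) {
  strategy <- match.arg(strategy)
  pres <- presence_intervals(register, strategy, horizon_end, lead_days)
  if (!is.null(ind_ids)) pres <- pres[ind_id %in% ind_ids]
  long <- .acts_long(register)[!is.na(date)]
  ind <- register$individuals

  own <- long[in_colony %in% TRUE & parish_id != UNKNOWN_LOCALITY,
              .(ind_id, date, parish_id, kind, act_id, own = 0L)]

  # sibling anchors: younger siblings' baptisms while the focal is under 14
  kids <- ind[, .(ind_id, mother_id, father_id, birth_date)]
  pair_on <- function(col) {
    a <- kids[!is.na(get(col)), .(ind_id, parent = get(col), birth_date)]
    merge(a, a[, .(sib_id = ind_id, parent)], by = "parent",
          allow.cartesian = TRUE)[ind_id != sib_id,
                                  .(ind_id, sib_id, birth_date)]
  }
  sib_pairs <- unique(rbind(pair_on("mother_id"), pair_on("father_id")))
  sib_bapt <- long[kind == "baptism" & in_colony %in% TRUE &
                     parish_id != UNKNOWN_LOCALITY,
                   .(sib_id = ind_id, date, parish_id, act_id)]
  sib <- merge(sib_pairs, sib_bapt, by = "sib_id", allow.cartesian = TRUE)
  sib <- sib[!is.na(birth_date) & date > birth_date &
               age_years(date, birth_date) < 14,
             .(ind_id, date, parish_id, kind = "baptism", act_id, own = 1L)]

  anchors <- rbind(own, sib)
  anchors <- anchors[ind_id %in% pres$ind_id]
  anchors[, prio := .act_kind_prio[kind]]
  setorder(anchors, ind_id, date, own, prio, act_id)

  # same-day conflicting anchors: keep the highest-priority one, log the rest
  anchors[, n_parish := uniqueN(parish_id), by = .(ind_id, date)]
  conflicts <- unique(anchors[n_parish > 1L, .(ind_id, date)])
  anchors <- anchors[, .SD[1L], by = .(ind_id, date)]

  # drop anchors that repeat the current parish
  anchors[, keep := parish_id != shift(parish_id, fill = ""), by = ind_id]
  anchors <- anchors[keep == TRUE]

  tab <- merge(anchors[, .(ind_id, date, parish_id)], pres, by = "ind_id")
  tab <- tab[date < exit]  # anchors at/after exit carry no residence time
  tab[, seq := seq_len(.N), by = ind_id]
  tab[, n := .N, by = ind_id]
  if (strategy == "retrospective") {
    tab[, start := fifelse(seq == 1L, entry, date)]
    tab[, end := shift(date, -1L), by = ind_id]
    tab[seq == n, end := exit]
  } else {
    tab[, start := {
      s <- shift(date) + 1L
      fifelse(seq == 1L, entry, s)
    }, by = ind_id]
    tab[, end := shift(start, -1L), by = ind_id]
    tab[seq == n, end := exit]
  }
  # first anchor's parish extends back to entry under both strategies; clip
  tab[start < entry, start := entry]
  out <- tab[start < end, .(ind_id, parish_id, start, end)]

  # individuals present but with no usable anchor: unknown locality throughout
  unloc <- pres[!(ind_id %in% out$ind_id)]
  if (nrow(unloc)) {
    out <- rbind(out, unloc[, .(ind_id, parish_id = UNKNOWN_LOCALITY,
                                start = entry, end = exit)])
  }
  out[, strategy := strategy]
  setorder(out, ind_id, start)
  setattr(out, "excluded", attr(pres, "excluded"))
  setattr(out, "conflicts", conflicts)
  out[]
}
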