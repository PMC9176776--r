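# Independent brute-force oracles, written directly from the definitions and
# kept free of the package's interval/pool machinery.  They are deliberately
# slow (per-individual loops) and only used on small inputs.

# location anchors of one individual: own dated in-colony acts with known
# parish, plus siblings' baptisms while the focal is strictly under 14,
# restricted to dates before the focal's exit
oracle_anchors <- function(reg, id, exit) {
  ind <- reg$individuals[reg$individuals$ind_id == id, ]
  acts <- as.data.frame(reg$acts)
  in_col <- stats::setNames(reg$parishes$in_colony, reg$parishes$parish_id)
  own <- acts[(acts$ind_id1 %in% id |
                 (!is.na(acts$ind_id2) & acts$ind_id2 %in% id)) &
                !is.na(acts$date), ]
  own <- own[!is.na(own$parish_id) & own$parish_id != UNKNOWN_LOCALITY &
               in_col[own$parish_id], ]
  anc <- data.frame(date = own$date, parish = own$parish_id,
                    prio = match(own$kind, c("baptism", "marriage", "burial")),
                    own = rep(0L, nrow(own)), act = own$act_id,
                    stringsAsFactors = FALSE)
  if (!is.na(ind$birth_date)) {
    sibs <- reg$individuals[
      ((!is.na(reg$individuals$mother_id) & !is.na(ind$mother_id) &
          reg$individuals$mother_id == ind$mother_id) |
         (!is.na(reg$individuals$father_id) & !is.na(ind$father_id) &
            reg$individuals$father_id == ind$father_id)) &
        reg$individuals$ind_id != id, ]
    sb <- acts[acts$kind == "baptism" & acts$ind_id1 %in% sibs$ind_id &
                 !is.na(acts$date), ]
    sb <- sb[!is.na(sb$parish_id) & sb$parish_id != UNKNOWN_LOCALITY &
               in_col[sb$parish_id], ]
    sb <- sb[sb$date > ind$birth_date &
               as.numeric(sb$date - ind$birth_date) / 365.25 < 14, ]
    if (nrow(sb)) {
      anc <- rbind(anc, data.frame(date = sb$date, parish = sb$parish_id,
                                   prio = rep(1L, nrow(sb)),
                                   own = rep(1L, nrow(sb)), act = sb$act_id,
                                   stringsAsFactors = FALSE))
    }
  }
  anc <- anc[anc$date < exit, , drop = FALSE]
  anc <- anc[order(anc$date, anc$own, anc$prio, anc$act), , drop = FALSE]
  anc <- anc[!duplicated(anc$date), , drop = FALSE]
  # collapse runs of the same parish
  if (nrow(anc) > 1) {
    keep <- c(TRUE, anc$parish[-1] != anc$parish[-nrow(anc)])
    anc <- anc[keep, , drop = FALSE]
  }
  anc
}

# presence window (entry, exit) of one individual, or NULL if unplaceable
oracle_presence <- function(reg, id, strategy, horizon_end) {
  ind <- reg$individuals[reg$individuals$ind_id == id, ]
  acts <- as.data.frame(reg$acts)
  in_col <- stats::setNames(reg$parishes$in_colony, reg$parishes$parish_id)
  own <- acts[(acts$ind_id1 %in% id |
                 (!is.na(acts$ind_id2) & acts$ind_id2 %in% id)) &
                !is.na(acts$date), ]
  if (!nrow(own)) return(NULL)
  colside <- is.na(own$parish_id) | own$parish_id == UNKNOWN_LOCALITY |
    in_col[own$parish_id]
  in_dates <- own$date[colside]; out_dates <- own$date[!colside]
  if (ind$immigrant) {
    if (!length(in_dates)) return(NULL)
    entry <- if (strategy == "retrospective") min(in_dates) else
      if (length(out_dates)) max(out_dates) + 1 else min(in_dates)
  } else {
    entry <- if (!is.na(ind$birth_date)) ind$birth_date else min(in_dates)
  }
  exit <- if (!is.na(ind$death_date)) ind$death_date else horizon_end
  if (entry >= exit) return(NULL)
  list(entry = entry, exit = exit)
}

# parish of one individual at a reference date (NA when absent)
oracle_parish_at <- function(reg, id, ref, strategy, horizon_end) {
  pres <- oracle_presence(reg, id, strategy, horizon_end)
  if (is.null(pres) || ref < pres$entry || ref >= pres$exit) return(NA_character_)
  anc <- oracle_anchors(reg, id, pres$exit)
  if (!nrow(anc)) return(UNKNOWN_LOCALITY)
  if (strategy == "retrospective") {
    k <- which(anc$date <= ref)
    if (!length(k)) return(anc$parish[1])
    anc$parish[max(k)]
  } else {
    k <- which(anc$date >= ref)
    if (!length(k)) return(anc$parish[nrow(anc)])
    anc$parish[min(k)]
  }
}

# is the individual in an intact marriage at ref?
oracle_married_at <- function(reg, id, ref) {
  acts <- as.data.frame(reg$acts)
  m <- acts[acts$kind == "marriage" & !is.na(acts$date) & acts$date <= ref &
              (acts$ind_id1 %in% id |
                 (!is.na(acts$ind_id2) & acts$ind_id2 %in% id)), ]
  if (!nrow(m)) return(FALSE)
  m <- m[which.max(as.numeric(m$date)), ]
  spouse <- if (m$ind_id1 == id) m$ind_id2 else m$ind_id1
  sd <- reg$individuals$death_date[reg$individuals$ind_id == spouse]
  is.na(sd) || sd > ref
}

# neighbor members by direct application of the 5-closest + 500 m rule
oracle_neighbors <- function(reg, focal, ref) {
  p <- as.data.frame(reg$parishes)
  p <- p[p$in_colony & (is.na(p$founded) | p$founded <= ref), ]
  f <- p[p$parish_id == focal, ]
  o <- p[p$parish_id != focal & !is.na(p$x_km), ]
  d <- sqrt((o$x_km - f$x_km)^2 + (o$y_km - f$y_km)^2)
  o <- o[order(d, o$parish_id), ]; d <- sort(d)
  if (nrow(o) < 5) return(c(focal, o$parish_id))
  c(focal, o$parish_id[d <= d[5] + 0.5])
}

# full pool recount from the definitions
oracle_pool <- function(reg, year, scope = "colonial", parish = NULL,
                        strategy = "retrospective", pool = "unmarried",
                        horizon_end) {
  ref <- as.Date(sprintf("%04d-06-15", year))
  n_men <- 0L; n_women <- 0L
  for (i in seq_len(nrow(reg$individuals))) {
    ind <- reg$individuals[i, ]
    if (is.na(ind$birth_date)) next
    age <- as.numeric(ref - ind$birth_date) / 365.25
    if (age < 14 || age >= 50) next
    if (!is.na(ind$death_date) && ind$death_date <= ref) next
    par <- oracle_parish_at(reg, ind$ind_id, ref, strategy, horizon_end)
    if (is.na(par)) next
    if (scope == "parish" && par != parish) next
    if (scope == "regional" &&
        !(par %in% oracle_neighbors(reg, parish, ref))) next
    if (scope != "colonial" && par == UNKNOWN_LOCALITY) next
    if (pool == "unmarried" && oracle_married_at(reg, ind$ind_id, ref)) next
    if (ind$sex == "M") n_men <- n_men + 1L else n_women <- n_women + 1L
  }
  c(n_men = n_men, n_women = n_women)
}

# ---- Cox partial likelihood by exhaustive risk-set enumeration -------------

oracle_coxpl <- function(beta, start, stop, event, X, ties = "efron") {
  X <- as.matrix(X)
  eta <- drop(X %*% beta)
  ll <- 0
  for (t in sort(unique(stop[event]))) {
    at_risk <- which(start < t & stop >= t)
    D <- which(event & stop == t)
    d <- length(D)
    Sr <- sum(exp(eta[at_risk])); Sd <- sum(exp(eta[D]))
    ll <- ll + sum(eta[D])
    if (ties == "breslow") {
      ll <- ll - d * log(Sr)
    } else {
      for (l in seq_len(d) - 1) ll <- ll - log(Sr - (l / d) * Sd)
    }
  }
  ll
}

oracle_cox_score <- function(beta, start, stop, event, X, ties = "efron",
                             h = 1e-6) {
  vapply(seq_along(beta), function(j) {
    e <- replace(rep(0, length(beta)), j, h)
    (oracle_coxpl(beta + e, start, stop, event, X, ties) -
       oracle_coxpl(beta - e, start, stop, event, X, ties)) / (2 * h)
  }, numeric(1))
}

oracle_cox_mle <- function(start, stop, event, X, ties = "efron") {
  X <- as.matrix(X)
  fit <- stats::optim(rep(0, ncol(X)),
                      function(b) -oracle_coxpl(b, start, stop, event, X, ties),
                      method = "BFGS", control = list(reltol = 1e-14))
  fit$par
}

# shift every date in a register by a fixed number of days
shift_register <- function(reg, days) {
  p <- data.table::copy(reg$parishes); i <- data.table::copy(reg$individuals)
  a <- data.table::copy(reg$acts)
  p$founded <- p$founded + days
  i$birth_date <- i$birth_date + days; i$death_date <- i$death_date + days
  a$date <- a$date + days
  new_register(p, i, a, source = paste0(reg$source, "+", days, "d"))
}
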