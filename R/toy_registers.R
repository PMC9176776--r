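# Hand-built miniature registers with hand-countable expected outputs.
# These are the package's documentation fixtures: small enough that every
# localization interval and pool count can be derived on paper, so they anchor
# the oracle tests for the localization and marriage_market modules.

.toy_parishes <- function(df) {
  data.table(
    parish_id = df$parish_id, name = df$name,
    founded = as.Date(df$founded), founded_prec = "day",
    x_km = df$x_km, y_km = df$y_km, in_colony = df$in_colony
  )
}

.toy_inds <- function(...) {
  rows <- list(...)
  rbindlist(lapply(rows, function(r) {
    data.table(
      ind_id = r[[1]], sex = r[[2]],
      birth_date = if (is.na(r[[3]])) as.Date(NA) else as.Date(r[[3]]),
      birth_prec = if (is.na(r[[3]])) "unknown" else "day",
      death_date = if (is.na(r[[4]])) as.Date(NA) else as.Date(r[[4]]),
      death_prec = if (is.na(r[[4]])) "unknown" else "day",
      mother_id = r[[5]], father_id = r[[6]],
      immigrant = r[[7]]
    )
  }))
}

.toy_acts <- function(...) {
  rows <- list(...)
  rbindlist(lapply(seq_along(rows), function(k) {
    r <- rows[[k]]
    data.table(
      act_id = sprintf("A%03d", k), kind = r[[1]],
      date = as.Date(r[[2]]), date_prec = "day",
      parish_id = r[[3]], ind_id1 = r[[4]],
      ind_id2 = if (length(r) >= 5) r[[5]] else NA_character_,
      marriage_rank = if (length(r) >= 6) as.integer(r[[6]]) else NA_integer_
    )
  }))
}

#' Hand-built fixture registers
#'
#' Returns one of a set of small, documented registers whose expected
#' localization intervals and sex-ratio pools are derivable by hand.
#'
#' Available fixtures:
#' \describe{
#'   \item{`fig1_migrant`}{One migrant life course: baptism in parish A
#'     (1700-03-10), a younger sibling baptized in parish B (1709-05-20, focal
#'     aged 9), marriage in parish C (1725-08-01).  The retrospective and
#'     prospective strategies attribute the ambiguous gaps differently:
#'     retrospective keeps A until the sibling's baptism, B until the
#'     marriage; prospective switches to B the day after the own baptism and
#'     to C the day after the sibling's baptism.}
#'   \item{`twenty_person`}{20 colony-born individuals in parishes P and Q.
#'     At the 1700-06-15 reference date the unmarried 14-50 pool is 4 men /
#'     5 women colonially, 3 men / 1 woman in P (percent-male 75.0), and
#'     1 man / 3 women in Q; one woman's baptism has unknown locality so she
#'     counts only at colonial scope.  M01 and W01 are full siblings.}
#'   \item{`immigrant_bounds`}{One immigrant with a French baptism
#'     (1640-04-02) and a colonial marriage (1665-06-01): retrospective entry
#'     is the marriage date (latest plausible arrival), prospective entry is
#'     the day after the French baptism (earliest plausible arrival).}
#' }
#'
#' @param name fixture key.
#' @return A `register`.
#' @export
make_toy_register <- function(name) {
  fixtures <- c("fig1_migrant", "twenty_person", "immigrant_bounds")
  if (!is.character(name) || length(name) != 1 || !(name %in% fixtures)) {
    stop("unknown fixture '", name, "'; available: ",
         paste(fixtures, collapse = ", "), call. = FALSE)
  }
  switch(name,
    fig1_migrant = .toy_fig1_migrant(),
    twenty_person = .toy_twenty_person(),
    immigrant_bounds = .toy_immigrant_bounds()
  )
}

.toy_fig1_migrant <- function() {
  parishes <- .toy_parishes(data.frame(
    parish_id = c("A", "B", "C"), name = c("Alpha", "Beta", "Gamma"),
    founded = "1650-01-01", x_km = c(0, 10, 20), y_km = 0, in_colony = TRUE
  ))
  inds <- .toy_inds(
    list("F1", "M", "1675-01-01", NA, NA, NA, FALSE),
    list("M1", "F", "1678-01-01", NA, NA, NA, FALSE),
    list("X1", "M", "1700-03-10", "1760-01-01", "M1", "F1", FALSE),
    list("Y1", "M", "1709-05-20", NA, "M1", "F1", FALSE),
    list("W1", "F", "1702-01-01", NA, NA, NA, FALSE)
  )
  acts <- .toy_acts(
    list("baptism", "1700-03-10", "A", "X1"),
    list("baptism", "1709-05-20", "B", "Y1"),
    list("baptism", "1702-01-01", "C", "W1"),
    list("marriage", "1725-08-01", "C", "X1", "W1", 1L)
  )
  new_register(parishes, inds, acts, source = "toy:fig1_migrant")
}

.toy_twenty_person <- function() {
  parishes <- .toy_parishes(data.frame(
    parish_id = c("P", "Q"), name = c("StP", "StQ"),
    founded = "1650-01-01", x_km = c(0, 5), y_km = 0, in_colony = TRUE
  ))
  inds <- .toy_inds(
    list("FF1", "M", "1650-01-01", NA, NA, NA, FALSE),
    list("MM1", "F", "1655-01-01", NA, NA, NA, FALSE),
    list("M01", "M", "1680-01-01", NA, "MM1", "FF1", FALSE),
    list("W01", "F", "1682-01-01", NA, "MM1", "FF1", FALSE),
    list("M02", "M", "1675-01-01", NA, NA, NA, FALSE),
    list("M03", "M", "1684-01-01", NA, NA, NA, FALSE),
    list("M04", "M", "1670-01-01", NA, NA, NA, FALSE),
    list("W02", "F", "1670-06-01", NA, NA, NA, FALSE),
    list("M05", "M", "1665-01-01", "1699-05-01", NA, NA, FALSE),
    list("W03", "F", "1660-01-01", NA, NA, NA, FALSE),
    list("M06", "M", "1685-01-01", NA, NA, NA, FALSE),
    list("W04", "F", "1686-01-01", NA, NA, NA, FALSE),
    list("W05", "F", "1686-06-01", NA, NA, NA, FALSE),
    list("M07", "M", "1650-02-01", NA, NA, NA, FALSE),
    list("M08", "M", "1688-01-01", NA, NA, NA, FALSE),
    list("M09", "M", "1672-01-01", NA, NA, NA, FALSE),
    list("W07", "F", "1674-01-01", NA, NA, NA, FALSE),
    list("W06", "F", "1650-01-01", "1698-01-01", NA, NA, FALSE),
    list("W08", "F", "1684-01-01", NA, NA, NA, FALSE),
    list("C01", "F", "1695-12-01", NA, "W07", "M09", FALSE)
  )
  acts <- .toy_acts(
    list("baptism", "1650-01-01", "P", "FF1"),
    list("baptism", "1655-01-01", "P", "MM1"),
    list("baptism", "1680-01-01", "P", "M01"),
    list("baptism", "1682-01-01", "P", "W01"),
    list("baptism", "1675-01-01", "P", "M02"),
    list("baptism", "1684-01-01", "P", "M03"),
    list("baptism", "1670-01-01", "P", "M04"),
    list("baptism", "1670-06-01", "P", "W02"),
    list("baptism", "1665-01-01", "P", "M05"),
    list("baptism", "1660-01-01", "Q", "W03"),
    list("baptism", "1685-01-01", "Q", "M06"),
    list("baptism", "1686-01-01", "Q", "W04"),
    list("baptism", "1686-06-01", "Q", "W05"),
    list("baptism", "1650-02-01", "P", "M07"),
    list("baptism", "1688-01-01", "Q", "M08"),
    list("baptism", "1672-01-01", "Q", "M09"),
    list("baptism", "1674-01-01", "Q", "W07"),
    list("baptism", "1650-01-01", "P", "W06"),
    list("baptism", "1684-01-01", UNKNOWN_LOCALITY, "W08"),
    list("baptism", "1695-12-01", "Q", "C01"),
    list("marriage", "1679-01-01", "P", "FF1", "MM1", 1L),
    list("marriage", "1698-02-01", "P", "M04", "W02", 1L),
    list("marriage", "1690-01-01", "Q", "M05", "W03", 1L),
    list("marriage", "1695-02-01", "Q", "M09", "W07", 1L),
    list("burial", "1699-05-01", "P", "M05"),
    list("burial", "1698-01-01", "P", "W06")
  )
  new_register(parishes, inds, acts, source = "toy:twenty_person")
}

.toy_immigrant_bounds <- function() {
  parishes <- .toy_parishes(data.frame(
    parish_id = c("FR1", "A"), name = c("FranceOrigin", "Alpha"),
    founded = c("1600-01-01", "1650-01-01"),
    x_km = c(NA, 0), y_km = c(NA, 0), in_colony = c(FALSE, TRUE)
  ))
  inds <- .toy_inds(
    list("IM1", "M", "1640-04-02", "1700-01-01", NA, NA, TRUE),
    list("WA1", "F", "1645-01-01", NA, NA, NA, FALSE)
  )
  acts <- .toy_acts(
    list("baptism", "1640-04-02", "FR1", "IM1"),
    list("baptism", "1645-01-01", "A", "WA1"),
    list("marriage", "1665-06-01", "A", "IM1", "WA1", 1L)
  )
  new_register(parishes, inds, acts, source = "toy:immigrant_bounds")
}
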