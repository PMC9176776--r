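#' @import data.table
#' @importFrom stats setNames optim runif rbinom rexp complete.cases cor.test
#'   pchisq qnorm
#' @importFrom utils head
NULL

#' Sentinel for acts whose locality is unknown
#'
#' Registers record some acts "somewhere in the colony" with no parish.  Such
#' acts contribute to colonial-scope pools but are excluded from parish and
#' regional sex ratios.  The sentinel is a first-class parish id so downstream
#' code never silently drops these records.
#' @export
UNKNOWN_LOCALITY <- "UNKNOWN_LOCALITY"

.parish_cols <- c("parish_id", "name", "founded", "x_km", "y_km", "in_colony")
.ind_cols    <- c("ind_id", "sex", "birth_date", "death_date",
                  "mother_id", "father_id", "immigrant")
.act_cols    <- c("act_id", "kind", "date", "parish_id",
                  "ind_id1", "ind_id2", "marriage_rank")

#' Construct a register from its three component tables
#'
#' A register is the package's central container: a list of three
#' `data.table`s (`parishes`, `individuals`, `acts`) carrying a
#' family-reconstitution register of linked vital acts, plus provenance
#' metadata.  Most users will obtain one from [load_register()] or
#' [simulate_colony()] rather than calling this directly.
#'
#' @param parishes,individuals,acts data.frames with the documented columns
#'   (see [load_register()] for the file schema).  Date columns must already
#'   be `Date` with matching `*_prec` precision columns ("day", "year",
#'   "unknown"); unknown ids are `NA`.
#' @param source character provenance tag (file path or generator seed).
#' @return An object of class `register`.
#' @export
new_register <- function(parishes, individuals, acts, source = "constructed") {
  parishes <- as.data.table(parishes)
  individuals <- as.data.table(individuals)
  acts <- as.data.table(acts)
  for (nm in c("founded")) {
    if (!paste0(nm, "_prec") %in% names(parishes)) {
      parishes[, paste0(nm, "_prec") := ifelse(is.na(get(nm)), "unknown", "day")]
    }
  }
  for (nm in c("birth_date", "death_date")) {
    pc <- sub("_date$", "_prec", nm)
    if (!pc %in% names(individuals)) {
      individuals[, (pc) := ifelse(is.na(get(nm)), "unknown", "day")]
    }
  }
  if (!"date_prec" %in% names(acts)) {
    acts[, date_prec := ifelse(is.na(date), "unknown", "day")]
  }
  miss <- setdiff(.parish_cols, names(parishes))
  if (length(miss)) stop("parishes table missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  miss <- setdiff(.ind_cols, names(individuals))
  if (length(miss)) stop("individuals table missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  miss <- setdiff(.act_cols, names(acts))
  if (length(miss)) stop("acts table missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  structure(
    list(parishes = parishes, individuals = individuals, acts = acts,
         source = source),
    class = "register"
  )
}

#' @export
print.register <- function(x, ...) {
  cat("<register> ", nrow(x$individuals), " individuals, ",
      nrow(x$acts), " acts, ", nrow(x$parishes), " parishes",
      "  [", x$source, "]\n", sep = "")
  invisible(x)
}

.read_table <- function(path, required, label) {
  dt <- data.table::fread(path, colClasses = "character", na.strings = NULL,
                          encoding = "UTF-8")
  miss <- setdiff(required, names(dt))
  if (length(miss)) {
    stop("schema error in ", label, " (", path, "): missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  dt
}

.blank_to_na <- function(x) {
  x <- trimws(as.character(x))
  x[x == ""] <- NA_character_
  x
}

#' Load a register from delimiter-separated tables
#'
#' Reads the three register tables (UTF-8, header row, comma- or
#' tab-separated) and links them into a [new_register()] object.
#'
#' File schema (unknown values are empty fields; dates are ISO-8601 or a bare
#' year, the latter completed internally to July 1):
#' \describe{
#'   \item{parishes}{`parish_id, name, founded, x_km, y_km, in_colony`.
#'     Coordinates are planar kilometres; `in_colony` is TRUE/FALSE (FALSE for
#'     out-of-colony places such as origin parishes in France).}
#'   \item{individuals}{`ind_id, sex (M/F), birth_date, death_date, mother_id,
#'     father_id, immigrant`.}
#'   \item{acts}{`act_id, kind (baptism/marriage/burial), date, parish_id,
#'     ind_id1, ind_id2, marriage_rank`.  `ind_id2` only for marriage acts;
#'     `parish_id` may be the [UNKNOWN_LOCALITY] sentinel.}
#' }
#'
#' @param parish_path,individual_path,act_path file paths.
#' @return A `register`.  Unknown dates and localities are preserved as
#'   sentinels, never dropped.
#' @seealso [write_register()], [validate_register()]
#' @export
load_register <- function(parish_path, individual_path, act_path) {
  p <- .read_table(parish_path, .parish_cols, "parishes")
  i <- .read_table(individual_path, .ind_cols, "individuals")
  a <- .read_table(act_path, .act_cols, "acts")

  fd <- parse_flex_date(p$founded)
  parishes <- data.table(
    parish_id = .blank_to_na(p$parish_id), name = as.character(p$name),
    founded = fd$date, founded_prec = fd$prec,
    x_km = suppressWarnings(as.numeric(p$x_km)),
    y_km = suppressWarnings(as.numeric(p$y_km)),
    in_colony = toupper(trimws(p$in_colony)) %in% c("TRUE", "T", "1")
  )
  bd <- parse_flex_date(i$birth_date); dd <- parse_flex_date(i$death_date)
  individuals <- data.table(
    ind_id = .blank_to_na(i$ind_id), sex = toupper(trimws(i$sex)),
    birth_date = bd$date, birth_prec = bd$prec,
    death_date = dd$date, death_prec = dd$prec,
    mother_id = .blank_to_na(i$mother_id), father_id = .blank_to_na(i$father_id),
    immigrant = toupper(trimws(i$immigrant)) %in% c("TRUE", "T", "1")
  )
  ad <- parse_flex_date(a$date)
  acts <- data.table(
    act_id = .blank_to_na(a$act_id), kind = tolower(trimws(a$kind)),
    date = ad$date, date_prec = ad$prec,
    parish_id = .blank_to_na(a$parish_id),
    ind_id1 = .blank_to_na(a$ind_id1), ind_id2 = .blank_to_na(a$ind_id2),
    marriage_rank = suppressWarnings(as.integer(a$marriage_rank))
  )

  # hard linkage errors: dangling ids make the register unusable
  known_ind <- individuals$ind_id
  dangle <- acts[!is.na(ind_id1) & !(ind_id1 %in% known_ind) |
                   (!is.na(ind_id2) & !(ind_id2 %in% known_ind))]
  if (nrow(dangle)) {
    bad <- unique(c(dangle$ind_id1[!dangle$ind_id1 %in% known_ind],
                    dangle$ind_id2[!is.na(dangle$ind_id2) &
                                     !dangle$ind_id2 %in% known_ind]))
    stop("linkage error: acts reference unknown individual id(s): ",
         paste(head(bad, 10), collapse = ", "),
         " (rows ", paste(head(dangle$act_id, 10), collapse = ", "), ")",
         call. = FALSE)
  }
  known_par <- c(parishes$parish_id, UNKNOWN_LOCALITY)
  dangle <- acts[!is.na(parish_id) & !(parish_id %in% known_par)]
  if (nrow(dangle)) {
    stop("linkage error: acts reference unknown parish id(s): ",
         paste(head(unique(dangle$parish_id), 10), collapse = ", "),
         " (rows ", paste(head(dangle$act_id, 10), collapse = ", "), ")",
         call. = FALSE)
  }
  new_register(parishes, individuals, acts,
               source = paste0("files:", act_path))
}

#' Write a register to delimiter-separated tables
#'
#' Inverse of [load_register()]: emits `parishes.csv`, `individuals.csv`,
#' `acts.csv` under `dir`.  Year-only and unknown dates are re-emitted in
#' their original form, so a load/write round trip is lossless.
#'
#' @param register a `register`.
#' @param dir output directory (created if absent).
#' @return Invisibly, the three file paths.
#' @export
write_register <- function(register, dir) {
  stopifnot(inherits(register, "register"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  na_blank <- function(x) ifelse(is.na(x), "", as.character(x))
  p <- register$parishes
  pout <- data.table(
    parish_id = na_blank(p$parish_id), name = na_blank(p$name),
    founded = format_flex_date(p$founded, p$founded_prec),
    x_km = na_blank(p$x_km), y_km = na_blank(p$y_km),
    in_colony = ifelse(p$in_colony, "TRUE", "FALSE")
  )
  i <- register$individuals
  iout <- data.table(
    ind_id = na_blank(i$ind_id), sex = na_blank(i$sex),
    birth_date = format_flex_date(i$birth_date, i$birth_prec),
    death_date = format_flex_date(i$death_date, i$death_prec),
    mother_id = na_blank(i$mother_id), father_id = na_blank(i$father_id),
    immigrant = ifelse(i$immigrant, "TRUE", "FALSE")
  )
  a <- register$acts
  aout <- data.table(
    act_id = na_blank(a$act_id), kind = na_blank(a$kind),
    date = format_flex_date(a$date, a$date_prec),
    parish_id = na_blank(a$parish_id),
    ind_id1 = na_blank(a$ind_id1), ind_id2 = na_blank(a$ind_id2),
    marriage_rank = na_blank(a$marriage_rank)
  )
  paths <- file.path(dir, c("parishes.csv", "individuals.csv", "acts.csv"))
  data.table::fwrite(pout, paths[1], quote = FALSE)
  data.table::fwrite(iout, paths[2], quote = FALSE)
  data.table::fwrite(aout, paths[3], quote = FALSE)
  invisible(paths)
}

.violation <- function(rule, id, detail) {
  data.table(rule = rule, id = as.character(id), detail = detail)
}

#' Validate register invariants
#'
#' Checks every structural invariant of the data model and returns a report
#' of violations; it never throws.  Checked rules: unique ids; referential
#' integrity of parent and parish links; in-colony parishes carry
#' coordinates; acts postdate their parish's founding; marriage acts have
#' exactly two principals of opposite sex; per-individual temporal
#' consistency (baptism <= other acts <= burial; birth <= death); mothers are
#' female and alive nine months before each birth.
#'
#' @param register a `register`.
#' @return A `data.table` of class `validation_report` with columns
#'   `rule`, `id`, `detail`; zero rows iff all invariants hold.
#' @export
validate_register <- function(register) {
  p <- register$parishes; ind <- register$individuals; a <- register$acts
  v <- list()

  dup <- function(x) unique(x[duplicated(x)])
  for (d in dup(p$parish_id)) v[[length(v) + 1]] <-
    .violation("unique_parish_id", d, "duplicated parish_id")
  for (d in dup(ind$ind_id)) v[[length(v) + 1]] <-
    .violation("unique_ind_id", d, "duplicated ind_id")
  for (d in dup(a$act_id)) v[[length(v) + 1]] <-
    .violation("unique_act_id", d, "duplicated act_id")

  bad <- p[in_colony & (is.na(x_km) | is.na(y_km))]
  for (k in bad$parish_id) v[[length(v) + 1]] <-
    .violation("parish_coordinates", k, "in-colony parish without coordinates")

  bad <- ind[!is.na(sex) & !sex %in% c("M", "F")]
  for (k in bad$ind_id) v[[length(v) + 1]] <-
    .violation("sex_code", k, "sex not in {M, F}")

  bad <- ind[!is.na(mother_id) & !mother_id %in% ind$ind_id]
  for (k in bad$ind_id) v[[length(v) + 1]] <-
    .violation("mother_link", k, "mother_id not in register")
  bad <- ind[!is.na(father_id) & !father_id %in% ind$ind_id]
  for (k in bad$ind_id) v[[length(v) + 1]] <-
    .violation("father_link", k, "father_id not in register")

  bad <- a[!is.na(parish_id) & parish_id != UNKNOWN_LOCALITY &
             !parish_id %in% p$parish_id]
  for (k in bad$act_id) v[[length(v) + 1]] <-
    .violation("act_parish_link", k, "parish_id not in register")
  bad <- a[!(ind_id1 %in% ind$ind_id) |
             (!is.na(ind_id2) & !(ind_id2 %in% ind$ind_id))]
  for (k in bad$act_id) v[[length(v) + 1]] <-
    .violation("act_principal_link", k, "principal not in register")

  # acts before parish founding
  aa <- merge(a[!is.na(parish_id) & parish_id != UNKNOWN_LOCALITY & !is.na(date)],
              p[, .(parish_id, founded)], by = "parish_id")
  bad <- aa[!is.na(founded) & date < founded]
  for (k in bad$act_id) v[[length(v) + 1]] <-
    .violation("act_before_founding", k, "act predates parish founding")

  # marriages: two principals, opposite sex, positive rank
  m <- a[kind == "marriage"]
  bad <- m[is.na(ind_id1) | is.na(ind_id2) | ind_id1 == ind_id2]
  for (k in bad$act_id) v[[length(v) + 1]] <-
    .violation("marriage_principals", k, "marriage lacks two distinct principals")
  sex_of <- setNames(ind$sex, ind$ind_id)
  ok <- m[!is.na(ind_id1) & !is.na(ind_id2) & ind_id1 != ind_id2 &
            ind_id1 %in% ind$ind_id & ind_id2 %in% ind$ind_id]
  bad <- ok[sex_of[ind_id1] == sex_of[ind_id2]]
  for (k in bad$act_id) v[[length(v) + 1]] <-
    .violation("marriage_opposite_sex", k, "marriage principals share sex")
  bad <- m[!is.na(marriage_rank) & marriage_rank < 1L]
  for (k in bad$act_id) v[[length(v) + 1]] <-
    .violation("marriage_rank", k, "marriage_rank < 1")

  # individual temporal consistency
  bad <- ind[!is.na(birth_date) & !is.na(death_date) & death_date < birth_date]
  for (k in bad$ind_id) v[[length(v) + 1]] <-
    .violation("birth_before_death", k, "death precedes birth")

  long <- rbind(
    a[!is.na(ind_id1), .(ind_id = ind_id1, kind, date, act_id)],
    a[!is.na(ind_id2), .(ind_id = ind_id2, kind, date, act_id)]
  )[!is.na(date)]
  per <- long[, {
    bapt <- date[kind == "baptism"]
    bur <- date[kind == "burial"]
    .(bad_order = (length(bapt) > 0 && any(date < max(bapt))) ||
        (length(bur) > 0 && any(date > min(bur))))
  }, by = ind_id]
  for (k in per[bad_order == TRUE, ind_id]) v[[length(v) + 1]] <-
    .violation("act_order", k, "acts violate baptism <= other <= burial")

  # mother female and alive 9 months before birth
  mm <- merge(ind[!is.na(mother_id), .(ind_id, birth_date, mother_id)],
              ind[, .(mother_id = ind_id, m_sex = sex, m_death = death_date)],
              by = "mother_id")
  bad <- mm[!is.na(m_sex) & m_sex != "F"]
  for (k in bad$ind_id) v[[length(v) + 1]] <-
    .violation("mother_female", k, "mother is not female")
  bad <- mm[!is.na(birth_date) & !is.na(m_death) & m_death < birth_date - 270]
  for (k in bad$ind_id) v[[length(v) + 1]] <-
    .violation("mother_alive", k, "mother dead more than 9 months before birth")

  rep <- if (length(v)) rbindlist(v) else
    data.table(rule = character(), id = character(), detail = character())
  setattr(rep, "class", c("validation_report", class(rep)))
  rep[]
}

#' @export
print.validation_report <- function(x, ...) {
  if (nrow(x) == 0) {
    cat("<validation_report> clean: all register invariants hold\n")
  } else {
    cat("<validation_report>", nrow(x), "violation(s):\n")
    print(as.data.table(unclass(x)))
  }
  invisible(x)
}
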