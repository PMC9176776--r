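# Shared fixtures.  Simulated registers are cached per test run; each cache
# key pins its own seed so tests stay independent of execution order.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, make) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- make()
  .fixture_cache[[key]]
}

demo_sim <- function() {
  cached("demo", function() simulate_colony(sim_params("demo"), seed = 101))
}

colony_sim_fx <- function() {
  cached("colony", function() simulate_colony(sim_params("colony"), seed = 202))
}

# male-only immigration stream, running immigration to the end of the
# horizon so the population cannot go extinct
male_only_sim <- function() {
  cached("male_only", function() {
    simulate_colony(
      sim_params("demo", end_year = 1685L,
                 male_imm = list(years = 1650:1685, per_year = 8L),
                 female_imm = list(years = integer(), per_year = 0L),
                 female_pulse = list(start = 1663L, end = 1663L, total = 0L)),
      seed = 303)
  })
}

# a ~2,000-person register for the episode-conservation checks
large_sim <- function() {
  cached("large", function() {
    simulate_colony(
      sim_params("colony",
                 female_pulse = list(start = 1663L, end = 1672L, total = 130L)),
      seed = 404)
  })
}

# write a small well-formed register as CSV files; returns the three paths
write_family_csvs <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(c(
    "parish_id,name,founded,x_km,y_km,in_colony",
    "P,SaintP,1650-01-01,0,0,TRUE",
    "Q,SaintQ,1652-01-01,4,1,TRUE"
  ), file.path(dir, "parishes.csv"))
  writeLines(c(
    "ind_id,sex,birth_date,death_date,mother_id,father_id,immigrant",
    "F1,M,1670-02-01,1730-01-01,,,FALSE",
    "M1,F,1672,,,,FALSE",            # year-only birth date
    "K1,M,1695-03-01,,M1,F1,FALSE",
    "K2,F,1697-08-01,1699-01-05,M1,F1,FALSE",
    "S1,F,1694-01-01,,,,FALSE"
  ), file.path(dir, "individuals.csv"))
  writeLines(c(
    "act_id,kind,date,parish_id,ind_id1,ind_id2,marriage_rank",
    "A1,marriage,1694-02-10,P,F1,M1,1",
    "A2,baptism,1695-03-01,P,K1,,",
    "A3,baptism,1697-08-01,P,K2,,",
    "A4,burial,1699-01-05,P,K2,,",
    "A5,baptism,1694-01-01,Q,S1,,",
    paste0("A6,marriage,1716-05-20,", UNKNOWN_LOCALITY, ",K1,S1,1"),
    "A7,burial,1730-01-01,P,F1,,"
  ), file.path(dir, "acts.csv"))
  file.path(dir, c("parishes.csv", "individuals.csv", "acts.csv"))
}

# hand-built family register for episode covariate checks: firstborn of
# five, parents' deaths inside/outside risk windows
family_register <- function() {
  parishes <- data.frame(
    parish_id = "P", name = "SaintP", founded = as.Date("1650-01-01"),
    founded_prec = "day", x_km = 0, y_km = 0, in_colony = TRUE)
  mk_ind <- function(id, sex, b, d = NA, mo = NA, fa = NA) {
    data.frame(ind_id = id, sex = sex,
               birth_date = as.Date(b), birth_prec = "day",
               death_date = if (is.na(d)) as.Date(NA) else as.Date(d),
               death_prec = if (is.na(d)) "unknown" else "day",
               mother_id = mo, father_id = fa, immigrant = FALSE)
  }
  inds <- rbind(
    mk_ind("FA", "M", "1655-01-01", "1712-03-01"),
    mk_ind("MO", "F", "1660-01-01", "1740-01-01"),
    mk_ind("C1", "M", "1686-03-01", NA, "MO", "FA"),
    mk_ind("C2", "F", "1688-01-01", NA, "MO", "FA"),
    mk_ind("C3", "M", "1690-01-01", "1695-01-01", "MO", "FA"),
    mk_ind("C4", "F", "1692-01-01", NA, "MO", "FA"),
    mk_ind("C5", "M", "1694-01-01", NA, "MO", "FA"),
    mk_ind("SP", "F", "1685-01-01", NA),
    mk_ind("ON", "F", "1687-06-01", "1750-01-01")  # only child, never marries
  )
  mk_act <- function(id, kind, date, par, i1, i2 = NA, rank = NA) {
    data.frame(act_id = id, kind = kind, date = as.Date(date),
               date_prec = "day", parish_id = par, ind_id1 = i1, ind_id2 = i2,
               marriage_rank = rank)
  }
  acts <- rbind(
    mk_act("B1", "baptism", "1686-03-01", "P", "C1"),
    mk_act("B2", "baptism", "1688-01-01", "P", "C2"),
    mk_act("B3", "baptism", "1690-01-01", "P", "C3"),
    mk_act("B4", "baptism", "1692-01-01", "P", "C4"),
    mk_act("B5", "baptism", "1694-01-01", "P", "C5"),
    mk_act("B6", "baptism", "1685-01-01", "P", "SP"),
    mk_act("B7", "baptism", "1687-06-01", "P", "ON"),
    mk_act("D3", "burial", "1695-01-01", "P", "C3"),
    mk_act("DF", "burial", "1712-03-01", "P", "FA"),
    mk_act("M1", "marriage", "1701-09-01", "P", "C1", "SP", 1)
  )
  new_register(parishes, inds, acts, source = "test:family")
}
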