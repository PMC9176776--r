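test_that("the migrant fixture yields the hand-derived interval tables", {
  reg <- make_toy_register("fig1_migrant")
  r <- residence_intervals(reg, "retrospective", ind_ids = "X1")
  expect_equal(r$parish_id, c("A", "B", "C"))
  expect_equal(r$start, as.Date(c("1700-03-10", "1709-05-20", "1725-08-01")))
  expect_equal(r$end, as.Date(c("1709-05-20", "1725-08-01", "1760-01-01")))
  p <- residence_intervals(reg, "prospective", ind_ids = "X1")
  expect_equal(p$parish_id, c("A", "B", "C"))
  expect_equal(p$start, as.Date(c("1700-03-10", "1700-03-11", "1709-05-21")))
  expect_equal(p$end, as.Date(c("1700-03-11", "1709-05-21", "1760-01-01")))
})

test_that("single-parish lives are identical under both strategies", {
  reg <- make_toy_register("twenty_person")
  r <- residence_intervals(reg, "retrospective", ind_ids = "M02")
  p <- residence_intervals(reg, "prospective", ind_ids = "M02")
  expect_equal(nrow(r), 1)
  expect_equal(r$parish_id, "P")
  expect_equal(r[, .(ind_id, parish_id, start, end)],
               p[, .(ind_id, parish_id, start, end)])
})

test_that("unknown-locality acts never break a residence spell", {
  parishes <- data.frame(parish_id = "A", name = "A",
                         founded = as.Date("1650-01-01"), founded_prec = "day",
                         x_km = 0, y_km = 0, in_colony = TRUE)
  inds <- data.frame(
    ind_id = c("X", "Y"), sex = c("M", "F"),
    birth_date = as.Date(c("1700-01-01", "1702-01-01")), birth_prec = "day",
    death_date = as.Date(c("1770-01-01", NA)),
    death_prec = c("day", "unknown"),
    mother_id = NA_character_, father_id = NA_character_, immigrant = FALSE)
  acts <- data.frame(
    act_id = c("a1", "a2", "a3", "a4"),
    kind = c("baptism", "baptism", "marriage", "burial"),
    date = as.Date(c("1700-01-01", "1702-01-01", "1725-01-01", "1770-01-01")),
    date_prec = "day",
    parish_id = c("A", "A", UNKNOWN_LOCALITY, "A"),
    ind_id1 = c("X", "Y", "X", "X"), ind_id2 = c(NA, NA, "Y", NA),
    marriage_rank = c(NA, NA, 1L, NA))
  reg <- new_register(parishes, inds, acts)
  for (s in c("retrospective", "prospective")) {
    r <- residence_intervals(reg, s, ind_ids = "X")
    expect_equal(nrow(r), 1, label = s)
    expect_equal(r$parish_id, "A")
    expect_equal(r$start, as.Date("1700-01-01"))
    expect_equal(r$end, as.Date("1770-01-01"))
  }
})

test_that("immigrant entry dates bracket the plausible arrival window", {
  reg <- make_toy_register("immigrant_bounds")
  pr <- presence_intervals(reg, "retrospective")
  expect_equal(pr[ind_id == "IM1", entry], as.Date("1665-06-01"))
  pp <- presence_intervals(reg, "prospective")
  expect_equal(pp[ind_id == "IM1", entry], as.Date("1640-04-03"))
  # colony-born: entry equals birth under both strategies
  expect_equal(pr[ind_id == "WA1", entry], as.Date("1645-01-01"))
  expect_equal(pp[ind_id == "WA1", entry], as.Date("1645-01-01"))
})

test_that("immigrants with no in-colony act are excluded and logged", {
  reg <- make_toy_register("immigrant_bounds")
  reg$individuals <- rbind(reg$individuals, data.table::data.table(
    ind_id = "IM2", sex = "M", birth_date = as.Date("1630-01-01"),
    birth_prec = "day", death_date = as.Date(NA), death_prec = "unknown",
    mother_id = NA_character_, father_id = NA_character_, immigrant = TRUE))
  reg$acts <- rbind(reg$acts, data.table::data.table(
    act_id = "A099", kind = "baptism", date = as.Date("1630-01-01"),
    date_prec = "day", parish_id = "FR1", ind_id1 = "IM2",
    ind_id2 = NA_character_, marriage_rank = NA_integer_))
  pres <- presence_intervals(reg, "retrospective")
  expect_false("IM2" %in% pres$ind_id)
  excl <- attr(pres, "excluded")
  expect_true("IM2" %in% excl$ind_id)
})

test_that("intervals tile each presence window with no gaps or overlaps", {
  reg <- demo_sim()$register
  for (s in c("retrospective", "prospective")) {
    res <- residence_intervals(reg, s)
    pres <- presence_intervals(reg, s)
    expect_true(all(res$start < res$end))
    chk <- res[, .(first = min(start), last = max(end),
                   contiguous = all(start[-1] == end[-.N])),
               by = ind_id]
    chk <- merge(chk, pres, by = "ind_id")
    expect_true(all(chk$contiguous), label = s)
    expect_equal(chk$first, chk$entry)
    expect_equal(chk$last, chk$exit)
  }
})

test_that("prospective male counts dominate retrospective under male-only immigration", {
  sim <- male_only_sim()
  reg <- sim$register
  yrs <- 1655:1685
  sr_r <- sr_series(reg, yrs, "colonial", strategy = "retrospective")
  sr_p <- sr_series(reg, yrs, "colonial", strategy = "prospective")
  expect_true(all(sr_p$n_men >= sr_r$n_men))
  expect_true(any(sr_p$n_men > sr_r$n_men))
  expect_true(all(sr_p$n_women == 0))
  # an all-male register reads 100 percent male every defined year
  expect_true(all(sr_p[defined == TRUE, percent_male] == 100))
})

test_that("residence localization agrees with the direct-rule oracle", {
  reg <- demo_sim()$register
  he <- max(c(reg$acts$date, reg$individuals$death_date), na.rm = TRUE) + 1
  set.seed(5)
  ids <- sample(reg$individuals$ind_id, 40)
  refs <- as.Date(sprintf("%d-06-15", sample(1660:1715, 6)))
  for (s in c("retrospective", "prospective")) {
    res <- residence_intervals(reg, s)
    for (id in ids) {
      for (ref in refs) {
        ref <- as.Date(ref, origin = "1970-01-01")
        got <- res[ind_id == id & start <= ref & end > ref, parish_id]
        want <- oracle_parish_at(reg, id, ref, s, he)
        if (is.na(want)) {
          expect_length(got, 0)
        } else {
          expect_equal(got, want,
                       label = sprintf("%s %s @%s", s, id, format(ref)))
        }
      }
    }
  }
})
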