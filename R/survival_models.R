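# Cox proportional-hazards fitting on counting-process episodes.
#
# The model battery crosses sexes, localization strategies, sex-ratio
# scopes, four control-variable variants and four fixed-effects versions.
# "Fixed effects" are fitted as stratified baseline hazards (the standard
# Cox analogue, appropriate for many small strata such as mothers); dummy
# coding is available for small label sets.  Partial-likelihood
# maximisation itself is delegated to survival::coxph (Efron ties by
# default); an independent brute-force likelihood oracle cross-checks it in
# the test suite.

.variant_controls <- function(variant) {
  fam <- c("birth_order", "n_siblings", "n_brothers_alive_14",
           "n_sisters_alive_14", "mother_dead", "father_dead")
  switch(as.character(variant),
    "1" = character(),
    "2" = "factor(decade)",
    "3" = fam,
    "4" = c("factor(decade)", fam),
    stop("variant must be 1, 2, 3, or 4", call. = FALSE))
}

.fe_column <- c(none = NA_character_, mother = "mother_id",
                parish = "parish_id", birthplace = "birthplace_id")

#' Fit one Cox model on an episode table
#'
#' Fits a Cox proportional-hazards model for the transition into first
#' marriage on counting-process rows `(start_age, stop_age, event)`.  The
#' sex-ratio category enters as a categorical covariate with category 4
#' (55 to <60 percent male) as reference; the variant selects the control
#' set (1: none; 2: decade; 3: family covariates; 4: both); fixed effects
#' are stratified baseline hazards by the chosen label (or dummy
#' covariates).
#'
#' @param episodes an `episode_table` (with family covariates attached for
#'   variants 3 and 4), or any data.frame with `start_age, stop_age, event`
#'   and the covariate columns used.
#' @param sex optional `"M"`/`"F"` filter.
#' @param variant control-variable variant, 1-4.
#' @param fe `"none"`, `"mother"`, `"parish"`, or `"birthplace"`.
#' @param sr_term name of the sex-ratio covariate column; the default
#'   six-level category is treated as a factor with reference level 4, any
#'   other column is entered as supplied.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param fe_as `"strata"` (default) or `"dummy"`.
#' @param robust cluster-robust standard errors by individual.
#' @return list of class `cox_result`: `fit` (the `coxph` object), `tidy`
#'   (`data.table` of term, level, hr, se, lo95, hi95, p), `n_events`,
#'   `exposure` (person-years), `n_rows`, `dropped` (rows removed for
#'   missing covariates/labels or inestimable levels), `converged`,
#'   `reference` (named reference levels).
#' @export
cox_fit <- function(episodes, sex = NULL, variant = 1L,
                    fe = c("none", "mother", "parish", "birthplace"),
                    sr_term = "sr_category",
                    ties = c("efron", "breslow"),
                    fe_as = c("strata", "dummy"), robust = FALSE) {
  fe <- match.arg(fe); ties <- match.arg(ties); fe_as <- match.arg(fe_as)
  d <- as.data.table(episodes)
  if (!is.null(sex)) d <- d[d[["sex"]] == sex]
  dropped <- c(missing_sr = 0L, missing_fe = 0L, inestimable_level = 0L)

  n0 <- nrow(d)
  d <- d[!is.na(d[[sr_term]])]
  dropped["missing_sr"] <- n0 - nrow(d)

  terms <- character()
  if (identical(sr_term, "sr_category")) {
    d[, sr_cat := factor(get(sr_term), levels = as.character(1:6))]
    d[, sr_cat := droplevels(sr_cat)]
    if ("4" %in% levels(d$sr_cat)) d[, sr_cat := stats::relevel(sr_cat, "4")]
    # levels without events are not identifiable: drop their rows
    ev_by <- d[, .(ev = sum(event)), by = sr_cat]
    bad <- as.character(ev_by[ev == 0, sr_cat])
    if (length(bad)) {
      warning("sex-ratio category level(s) without events dropped: ",
              paste(bad, collapse = ", "))
      nb <- nrow(d)
      d <- d[!(as.character(sr_cat) %in% bad)]
      d[, sr_cat := droplevels(sr_cat)]
      dropped["inestimable_level"] <- nb - nrow(d)
    }
    terms <- c(terms, "sr_cat")
  } else {
    terms <- c(terms, sr_term)
  }
  terms <- c(terms, .variant_controls(variant))

  fe_col <- .fe_column[[fe]]
  if (!is.na(fe_col)) {
    nb <- nrow(d)
    d <- d[!is.na(d[[fe_col]]) & d[[fe_col]] != UNKNOWN_LOCALITY]
    dropped["missing_fe"] <- nb - nrow(d)
    terms <- c(terms,
               if (fe_as == "strata") sprintf("strata(%s)", fe_col)
               else sprintf("factor(%s)", fe_col))
  }
  if (robust) terms <- c(terms, "cluster(ind_id)")
  if (!nrow(d) || sum(d$event) == 0) {
    stop("no events left to fit on", call. = FALSE)
  }

  fml <- stats::as.formula(paste(
    "survival::Surv(start_age, stop_age, event) ~",
    paste(terms, collapse = " + ")))
  fit <- survival::coxph(fml, data = d, ties = ties)

  sm <- summary(fit)
  co <- sm$coefficients
  if (is.null(co) || nrow(co) == 0) {
    tidy <- data.table(term = character(), level = character(),
                       hr = numeric(), se = numeric(), lo95 = numeric(),
                       hi95 = numeric(), p = numeric())
  } else {
    beta <- co[, "coef"]
    se <- co[, if (robust) "robust se" else "se(coef)"]
    z <- beta / se
    tidy <- data.table(
      term = rownames(co),
      level = ifelse(grepl("^sr_cat", rownames(co)),
                     sub("^sr_cat", "", rownames(co)), NA_character_),
      hr = exp(beta), se = se,
      lo95 = exp(beta - qnorm(0.975) * se),
      hi95 = exp(beta + qnorm(0.975) * se),
      p = 2 * stats::pnorm(-abs(z))
    )
  }
  structure(list(
    fit = fit, tidy = tidy,
    n_events = sum(d$event),
    exposure = sum(d$stop_age - d$start_age),
    n_rows = nrow(d), dropped = dropped,
    converged = !any(is.na(stats::coef(fit))),
    reference = c(sr_category = "4",
                  decade = if (variant %in% c(2L, 4L))
                    as.character(min(d$decade)) else NA_character_)
  ), class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat("<cox_result> ", x$n_events, " events over ",
      round(x$exposure, 1), " person-years (", x$n_rows, " rows)\n", sep = "")
  print(x$tidy, digits = 3)
  invisible(x)
}

#' Run the full Cox model battery
#'
#' Crosses 2 sexes x 2 localization strategies x 3 sex-ratio scopes x 4
#' control variants x 4 fixed-effects versions (192 fits by default) on
#' episodes built from one register, collecting hazard ratios in a long
#' results table.  Individual fit failures are recorded and the battery
#' continues.
#'
#' @param register a `register`.
#' @param horizon analysis window passed to [build_episodes()].
#' @param sexes,strategies,scopes,variants,fes subsets of the full grid.
#' @param pool pool definition for the sex-ratio covariate.
#' @param ties,fe_as passed to [cox_fit()].
#' @return list of class `battery_result`: `results` (long `data.table`
#'   keyed by sex, strategy, scope, variant, fe with one row per
#'   coefficient), `failures` (specs that errored, with messages), and
#'   `n_fits`.
#' @export
model_battery <- function(register, horizon = c(1680L, 1750L),
                          sexes = c("F", "M"),
                          strategies = c("retrospective", "prospective"),
                          scopes = c("colonial", "regional", "parish"),
                          variants = 1:4,
                          fes = c("none", "mother", "parish", "birthplace"),
                          pool = "unmarried",
                          ties = "efron", fe_as = "strata") {
  results <- list(); failures <- list(); n_fits <- 0L
  for (strat in strategies) {
    residence <- residence_intervals(register, strat)
    for (sc in scopes) {
      ep <- tryCatch({
        e <- build_episodes(register, scope = sc, strategy = strat,
                            pool = pool, horizon = horizon,
                            residence = residence)
        attach_family_covariates(e, register)
      }, error = function(e) e)
      if (inherits(ep, "error")) {
        failures[[length(failures) + 1L]] <- data.table(
          sex = NA_character_, strategy = strat, scope = sc,
          variant = NA_integer_, fe = NA_character_,
          message = conditionMessage(ep))
        next
      }
      for (sx in sexes) for (v in variants) for (fe in fes) {
        n_fits <- n_fits + 1L
        res <- tryCatch(
          suppressWarnings(cox_fit(ep, sex = sx, variant = v, fe = fe,
                                   ties = ties, fe_as = fe_as)),
          error = function(e) e)
        if (inherits(res, "error")) {
          failures[[length(failures) + 1L]] <- data.table(
            sex = sx, strategy = strat, scope = sc, variant = v, fe = fe,
            message = conditionMessage(res))
        } else {
          td <- copy(res$tidy)
          td[, `:=`(sex = sx, strategy = strat, scope = sc,
                    variant = v, fe = fe, n_events = res$n_events,
                    converged = res$converged)]
          results[[length(results) + 1L]] <- td
        }
      }
    }
  }
  structure(list(
    results = if (length(results)) rbindlist(results) else data.table(),
    failures = if (length(failures)) rbindlist(failures) else data.table(),
    n_fits = n_fits
  ), class = "battery_result")
}

#' @export
print.battery_result <- function(x, ...) {
  cat("<battery_result> ", x$n_fits, " fits attempted, ",
      nrow(x$failures), " failure(s)\n", sep = "")
  invisible(x)
}

#' Sex-ratio hazard ratios in forest-plot layout
#'
#' Extracts the sex-ratio-category coefficients from a battery result in a
#' layout suitable for a forest plot (one panel per strategy x scope, rows
#' by category and model variant).  If ggplot2 is installed a plot can be
#' drawn with `plot = TRUE`.
#'
#' @param battery a `battery_result`.
#' @param plot draw a ggplot2 forest plot (requires ggplot2).
#' @return `data.table` of the sex-ratio coefficients (invisibly returns the
#'   plot object instead when `plot = TRUE`).
#' @export
forest_data <- function(battery, plot = FALSE) {
  stopifnot(inherits(battery, "battery_result"))
  d <- battery$results[!is.na(level)]
  if (!plot) return(d[])
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plot = TRUE", call. = FALSE)
  }
  g <- ggplot2::ggplot(
    d, ggplot2::aes(x = hr, y = level,
                    color = factor(variant), shape = fe)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2) +
    ggplot2::geom_point(position = ggplot2::position_dodge(0.6)) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = lo95, xmax = hi95),
      position = ggplot2::position_dodge(0.6), height = 0.2) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_grid(strategy + sex ~ scope) +
    ggplot2::labs(x = "hazard ratio (log scale)", y = "sex-ratio category",
                  color = "variant", shape = "fixed effects")
  invisible(g)
}
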