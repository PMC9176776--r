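---
title: "Sex ratios and marriage timing in reconstituted parish registers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sex ratios and marriage timing in reconstituted parish registers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(marriagemarkets)
library(data.table)
```

## The problem

In a family-reconstitution register, each person exists only as a chain of
dated, parish-stamped vital acts: baptism, marriage(s), burial.  From such
chains this package reconstructs the *marriage market* an individual faced
— the operational sex ratio (OSR) of potential partners around them, year
by year — and asks how that market relates to the timing and the lifetime
likelihood of first marriage.  The motivating setting is a
seventeenth/eighteenth-century settler colony: a heavily male immigration
stream, a brief sponsored pulse of female immigrants, then a semi-closed
population growing by natural fertility, in which the share of men in the
unmarried population falls from extreme skew toward balance over several
decades.

The pipeline has five analysis stages plus a data generator, each usable on
its own:

1. **registers** — a validated data model for linked parishes /
   individuals / acts tables (`load_register()`, `validate_register()`).
2. **localization** — where was each individual, and from when
   (`residence_intervals()`, `presence_intervals()`).
3. **marriage_market** — eligible pools, percent-male series, the
   categorical covariate (`sr_series()`, `individual_sr()`,
   `categorize_sr()`, `neighbor_set()`).
4. **episodes** — counting-process rows from age 14 to first marriage
   (`build_episodes()`, `attach_family_covariates()`).
5. **survival** — the Cox proportional-hazards battery (`cox_fit()`,
   `model_battery()`), plus descriptive surfaces
   (`marriage_age_series()`, `cohort_outcome_table()`).

`simulate_colony()` generates registers with this statistical structure
*and a truth log*, so every stage can be checked against known ground
truth; `run_pipeline()` chains everything from one seeded config.

## The sex-ratio measure

The OSR is the share of men among the unmarried (never-married or widowed)
population aged [14, 50) present at the annual reference date, expressed as
percent male rather than a men:women ratio — percentages are symmetric
around 50 whereas proper ratios are not.  Three geographic scopes are
computed: the whole colony; the parish; and a regional market consisting of
the focal parish, its five closest parishes by planar Euclidean distance,
and any further parish at most 0.5 km farther than the fifth closest.
Neighbor sets are recomputed per year over parishes already founded,
because parishes appear over time and newly founded ones tend to be
male-skewed.  A comparison variant includes married individuals
(`pool = "all"`).

For the individual-level covariate, an individual's own living
opposite-sex siblings (sharing mother or father) are removed from the
opposite-sex count — siblings are not eligible partners; the focal person
stays in their own-sex count.  In the models the percent is categorized
into six contiguous half-open bins, [0,45), [45,50), [50,55), [55,60),
[60,65), [65,100], with [55,60) as reference.  (The bins are printed with
gaps in some descriptions — "45 <49", "50 <54" — but a contiguous
half-open reading with an inclusive top bin is the only partition
consistent with all the printed labels; the partition is verified by an
exhaustive 0.1-step sweep in the tests.)

## Localization: two bracketing strategies

Registers pin a person to a parish only at their acts.  Between two acts in
different parishes, residence is genuinely ambiguous — about a fifth of
historical grooms married in the bride's parish without moving there — so
the package computes both defensible attributions and treats them as
bounds:

* **retrospective** — stay in the earlier parish until a later record
  contradicts it: the *latest plausible* arrival at the later parish;
* **prospective** — a differing subsequent record ends the previous
  residence immediately after the earlier act: the *earliest plausible*
  arrival.

While an individual is strictly under 14 their younger siblings' baptism
parishes stand in for the parental residence (children are assumed to live
with their parents to 14); at or after 14 only own acts anchor.  Acts with
unknown locality are first-class (`UNKNOWN_LOCALITY`): they never break a
residence spell, and person-years localized only to "somewhere in the
colony" count in colonial pools but are excluded from parish and regional
ones (the exclusion is reported by `exclusion_loss()`).

The same logic bounds immigrant arrival: retrospective entry is the first
in-colony act, prospective entry the day after the last out-of-colony act
(with a configurable lead, default zero, when no such act exists).  For a
male-dominated immigration stream the prospective pool therefore dominates
the retrospective one every year — retrospective counts an unmarried
immigrant only once the register first sees him, which can be as late as
his burial, and is thus *severely* conservative in the early decades.  A
"semi-prospective" variant is mentioned in passing in the source
literature but never defined, so it is not implemented.

Numerical conventions: dates are calendar `Date`s; year-only inputs
complete to July 1; age is `(date - birth) / 365.25` years; same-day
conflicting acts are resolved by kind priority (baptism > marriage >
burial) then act id, deterministically and with a logged warning; marriage
acts anchor residence at the marriage parish from the marriage date onward
under both strategies, with the pre-marriage gap governed by the strategy.

## Episodes and the model battery

Colony-born individuals with known birth dates (and known first-marriage
dates, if ever married) contribute counting-process rows from their 14th
birthday to first marriage, censored at 50, death, or the end of the
analysis window.  Immigrants shape the pools but contribute no rows: their
records are too incomplete and too survivorship-selected for life-course
modelling.  Rows are split at June 15 of every year — the annual reference
date; splitting mid-year rather than at January 1 matches the annual
resolution at which individuals are localized — and additionally at decade
boundaries, at residence changes (so parish strata and parish-scope
covariates are row-constant, which makes parish fixed effects well defined
for movers), and at parental deaths (so the loss flags are row-constant).
A row carries the sex-ratio category of the most recent reference date at
the configured scope, using the row's residence parish.  Exposure is
conserved exactly: row spans sum to risk-window lengths to machine
precision, and scope choices change covariate values but never the risk
windows.

The analysis window defaults to 1680–1750 (the source gives both
"1680–1750" and "1670–1749" in different places; the window is a config
argument).

`model_battery()` crosses 2 sexes x 2 localization strategies x 3 scopes x
4 control variants (none; decade; family covariates — birth order, number
of siblings, brothers and sisters alive at 14, maternal/paternal loss;
both) x 4 fixed-effects versions (none / mother / parish / birthplace) =
192 fits.  Fixed effects are implemented as stratified baseline hazards —
the standard Cox analogue, which tolerates many small strata such as
mothers; dummy coding is available for small label sets
(`fe_as = "dummy"`).  Ties use the Efron approximation by default (annual
splitting produces many same-date transitions); Breslow is an option.  No
multiple-testing correction is applied across the battery, matching
per-model inference; treat the 192 fits as a sensitivity surface, not 192
independent discoveries.  Partial-likelihood maximisation is delegated to
`survival::coxph()`; the test suite cross-checks it coefficient-by-
coefficient against an exhaustive risk-set enumeration oracle on small
tables, and against generative truth (hazard-ratio recovery and confidence
interval coverage) on simulated cohorts.

A deliberately unresolved question in the literature is whether the
focal individual should be removed from their own-sex count in the
individual-level sex ratio; they are kept in (both choices are defensible;
keeping them makes the measure identical to the pool share for people
without siblings present).

## What the generator emulates — and what it does not

`simulate_colony()` runs a yearly-step microsimulation aligned to the
June-15 reference date: pools are evaluated at June 15 and recorded in the
truth log, and the following year's events are dated uniformly inside the
step, so the episode splitter is exercised by events on arbitrary dates.
Within a step: immigrants arrive per schedule; unmarried individuals aged
[14, 50) marry with hazard `baseline(age, sex) * exp(beta_sr * (pm - 50) /
10)` where `pm` is the colonial unmarried percent male; marrying men and
women are matched at random, excluding sibling pairs (matching is
colony-wide: with a dozen parishes and a colonial hazard covariate,
parish-resolved matching would add state without changing anything the
package measures); married women bear children under a minimum-spacing
model; deaths follow an age-band schedule; widowed survivors return to the
pool; individuals and families move between parishes; every event emits an
act, and a fraction of acts lose their locality.

The `"colony"` preset encodes the study conditions at desk scale
(~2,000 individuals over 1650–1750; all sizes were chosen as the package's
own working scale): male immigration 10/year 1650–1672, a female pulse of
100 in 1663–1672 atop a trickle of 2/year, uniform arrival ages (men
18–35, women 16–30), `beta_sr = 0.15` per 10 points of percent male for
women and 0 for men (the generative pattern under study: markets move
women's timing, not men's), annual birth probability 0.35 with 2-year
spacing over ages 15–45 (≈9–10 births per woman married through her
fertile span), and a generic pre-transition mortality schedule (infant
q ≈ 0.20, childhood 0.05 falling to ~0.012, rising again past 40) — no
mortality schedule is given in the source, so this is config-overridable.
Locality is dropped from 5% of acts; 70% of immigrants carry a dated
out-of-colony baptism.  These defaults reproduce the qualitative shape:
an early unmarried pool above 80–95% male, decline toward balance after
immigration stops, female age at first marriage rising as the ratio falls,
a male age near-flat, a shrinking husband-older age gap, and a small,
trendless never-married-by-45 share (the near-zero cure fraction that
licenses standard Cox models).

Known divergences from real register data, hence limits on what passing
tests show: linkage is perfect by construction (no record-linkage error);
birth dates are known for everyone including immigrants; there are no
censuses, contracts, or other side-sources, so a never-marrying immigrant
is invisible to retrospective localization until burial — more invisible
than in a rich historical database; fertility and mortality do not vary by
region or class; matching ignores assortment beyond the sibling exclusion;
and out-migration is absent (the semi-closed assumption is built in, not
tested).

One structural property surfaced by the truth log deserves note: the
all-population series is *not* always bounded below by 50 in years when
the unmarried share exceeds 50.  Because pools are age-restricted to
[14, 50) and husbands are systematically older than wives, married men age
out of the band years before their wives, leaving the in-band married
subset female-skewed; when the unmarried share is only mildly male, adding
married individuals can push the total below parity.  The moderating
direction — the all-population share always sits strictly below the
unmarried share, and strictly between 50 and it when the skew is strong —
is what the tests assert.

## Worked example

```{r example}
sim <- simulate_colony(sim_params("demo"), seed = 1)
sim$register
sr <- sr_series(sim$register, 1660:1715, scope = "colonial",
                strategy = "prospective")
sr[year %in% c(1660, 1680, 1700, 1715)]

ep <- build_episodes(sim$register, scope = "colonial",
                     strategy = "prospective", horizon = c(1680L, 1715L))
ep <- attach_family_covariates(ep, sim$register)
fit <- cox_fit(ep, sex = "F", variant = 2, fe = "none")
fit
```

The `sr_cat` rows are hazard ratios of first marriage for women relative
to the reference market (55 to <60% male); the decade terms absorb period
effects.  On a register this small individual categories are noisy — the
battery exists precisely to show which contrasts survive across
specifications.

## Reproducibility

`run_pipeline()` executes simulate → localize → sexratio → episodes → fit
→ describe from a single validated config and writes every table with a
manifest (seed, config, row counts, checksums); the same config and seed
reproduce every output byte-identically.  `scripts/acceptance.R` runs the
full pipeline on the `"colony"` preset plus the estimator-validation
harnesses and writes the headline quantities as JSON.  Test problem sizes
(a few hundred to ~2,000 simulated individuals, 100–200 replicate fits)
are the package's chosen working scale for routine verification.
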