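#' Start a birth-cohort ledger
#'
#' A cohort ledger tracks one birth cohort through five states: alive without
#' T1D, alive with diagnosed T1D (sub-indexed by age at diagnosis, so that
#' duration of disease can be read off later), dead at onset from
#' non-diagnosis, dead after diagnosis, and dead from background causes
#' without T1D. The five states always sum to the cohort size.
#'
#' @param birth_year calendar year of birth.
#' @param size cohort size in persons (>= 0).
#' @param a_max terminal age; age `a_max` is absorbing-to-death.
#' @return an object of class `cohort_ledger`.
#' @export
new_cohort_ledger <- function(birth_year, size, a_max = 99L) {
  if (size < 0) stop_validation("cohort size must be >= 0")
  structure(list(birth_year = as.integer(birth_year), size = as.numeric(size),
                 age = 0L, a_max = as.integer(a_max),
                 alive_no_t1d = as.numeric(size),
                 alive_dx = numeric(a_max + 1L),   # indexed by onset age + 1
                 dead_onset_nondx = 0, dead_after_dx = 0, dead_background = 0,
                 # flows recorded during the most recent step
                 last_new_dx = 0, last_onset_deaths = 0,
                 last_dx_deaths = 0, last_bg_deaths = 0),
            class = "cohort_ledger")
}

#' @export
print.cohort_ledger <- function(x, ...) {
  cat(sprintf(paste0("<cohort_ledger> born %d, size %g, age %d: ",
                     "no-T1D %.3f, diagnosed %.3f, dead (onset %.3f, dx %.3f, bg %.3f)\n"),
              x$birth_year, x$size, x$age, x$alive_no_t1d, sum(x$alive_dx),
              x$dead_onset_nondx, x$dead_after_dx, x$dead_background))
  invisible(x)
}

# conservation check, relative tolerance 1e-9
ledger_balance <- function(ledger) {
  tot <- ledger$alive_no_t1d + sum(ledger$alive_dx) + ledger$dead_onset_nondx +
    ledger$dead_after_dx + ledger$dead_background
  abs(tot - ledger$size) <= 1e-9 * max(1, ledger$size)
}

#' Advance a cohort ledger by one model year
#'
#' Within the year, events happen in a fixed order: (1) onset of symptomatic
#' T1D among the susceptible at `incidence / 100,000`; (2) a fraction
#' `nondx_rate(year, age)` of the new onsets dies immediately without ever
#' being diagnosed, the remainder joins the diagnosed; (3) background deaths
#' among the remaining susceptible at probability `q`; (4) deaths among all
#' diagnosed (including this year's onsets) at
#' `q_t1d = 1 - (1 - q)^SMR`, the SMR applied on the hazard scale so that the
#' probability never exceeds 1. At the terminal age `a_max` the year is
#' absorbing: `q` is forced to 1 and everyone still alive dies through the
#' ordinary channels.
#'
#' @param ledger a [new_cohort_ledger()].
#' @param inputs a [country_inputs()] bundle.
#' @param clamp passed to surface lookups; when `TRUE` ages/years beyond the
#'   data horizon reuse the nearest covered cell.
#' @return the advanced ledger (age incremented by one).
#' @export
step_cohort <- function(ledger, inputs, clamp = FALSE) {
  age <- ledger$age
  year <- ledger$birth_year + age
  if (age > ledger$a_max) stop_validation("cohort already past terminal age")
  ctx <- inputs$country_id

  p_onset <- min(1, ays_value(inputs$incidence, age, year, clamp, ctx) / 1e5)
  q <- ays_value(inputs$background_mortality, age, year, clamp, ctx)
  smr <- ays_value(inputs$smr, age, year, clamp, ctx)
  ndx <- get_nondx(inputs, year, age, clamp)
  if (age == ledger$a_max) q <- 1
  q_t1d <- min(1, 1 - (1 - q)^smr)

  onsets <- ledger$alive_no_t1d * p_onset
  onset_deaths <- onsets * ndx
  new_dx <- onsets - onset_deaths
  ledger$alive_no_t1d <- ledger$alive_no_t1d - onsets

  bg_deaths <- ledger$alive_no_t1d * q
  ledger$alive_no_t1d <- ledger$alive_no_t1d - bg_deaths

  ledger$alive_dx[age + 1L] <- ledger$alive_dx[age + 1L] + new_dx
  dx_deaths <- sum(ledger$alive_dx) * q_t1d
  ledger$alive_dx <- ledger$alive_dx * (1 - q_t1d)

  ledger$dead_onset_nondx <- ledger$dead_onset_nondx + onset_deaths
  ledger$dead_background <- ledger$dead_background + bg_deaths
  ledger$dead_after_dx <- ledger$dead_after_dx + dx_deaths
  ledger$last_new_dx <- new_dx
  ledger$last_onset_deaths <- onset_deaths
  ledger$last_dx_deaths <- dx_deaths
  ledger$last_bg_deaths <- bg_deaths
  ledger$age <- age + 1L

  if (!ledger_balance(ledger)) {
    stop_validation("cohort conservation violated for birth year %d at age %d",
                    ledger$birth_year, age)
  }
  ledger
}

#' Run the Markov engine for one country
#'
#' Follows one birth cohort per birth year from `first_year - a_max` through
#' `last_year`, so that every age up to `a_max` is represented in every
#' reported year, and aggregates the cohorts into a burden result: diagnosed
#' prevalence (end-of-year), incident diagnosed cases, and deaths decomposed
#' into the three channels (at onset from non-diagnosis, after diagnosis,
#' and background deaths among those without T1D). Deterministic: no
#' randomness anywhere.
#'
#' @param inputs a [country_inputs()] bundle. Its surfaces must cover ages
#'   `0:a_max` and years `first_year - a_max` through `last_year`.
#' @param first_year,last_year reporting window (calendar years).
#' @param a_max terminal age (absorbing-to-death), default 99.
#' @return an object of class `burden_result`: a list of `prevalence`,
#'   `incident_diagnosed`, `deaths_onset_nondx`, `deaths_after_dx`,
#'   `deaths_background` (each an [age_year_surface()] over the reporting
#'   window) plus `totals`, a per-year data frame.
#' @export
run_country <- function(inputs, first_year, last_year, a_max = 99L) {
  first_year <- as.integer(first_year); last_year <- as.integer(last_year)
  yrs <- surface_years(inputs$population)
  need_from <- first_year - a_max
  if (min(yrs) > need_from) {
    stop_coverage(paste0("insufficient historical coverage for %s: ",
                         "population must reach back to birth year %d ",
                         "(earliest supplied: %d)"),
                  inputs$country_id, need_from, min(yrs))
  }
  report_years <- first_year:last_year
  nyr <- length(report_years); nag <- a_max + 1L
  acc <- function() matrix(0, nag, nyr, dimnames = list(age = 0:a_max,
                                                        year = report_years))
  prev <- acc(); inc <- acc(); d_ndx <- acc(); d_dx <- acc(); d_bg <- acc()

  for (b in need_from:last_year) {
    size <- ays_value(inputs$population, 0L, b, context = inputs$country_id)
    led <- new_cohort_ledger(b, size, a_max = a_max)
    top_age <- min(a_max, last_year - b)
    for (a in 0:top_age) {
      led <- step_cohort(led, inputs)
      y <- b + a
      j <- match(y, report_years)
      if (!is.na(j)) {
        prev[a + 1L, j] <- sum(led$alive_dx)
        inc[a + 1L, j] <- led$last_new_dx
        d_ndx[a + 1L, j] <- led$last_onset_deaths
        d_dx[a + 1L, j] <- led$last_dx_deaths
        d_bg[a + 1L, j] <- led$last_bg_deaths
      }
    }
  }
  mk <- function(m) age_year_surface(m, ages = 0:a_max, years = report_years,
                                     unit = "persons")
  totals <- data.frame(year = report_years,
                       prevalence = colSums(prev),
                       incident_diagnosed = colSums(inc),
                       deaths_onset_nondx = colSums(d_ndx),
                       deaths_after_dx = colSums(d_dx),
                       deaths_background = colSums(d_bg))
  structure(list(country_id = inputs$country_id,
                 prevalence = mk(prev), incident_diagnosed = mk(inc),
                 deaths_onset_nondx = mk(d_ndx), deaths_after_dx = mk(d_dx),
                 deaths_background = mk(d_bg),
                 totals = totals, a_max = a_max),
            class = "burden_result")
}

#' @export
print.burden_result <- function(x, ...) {
  last <- x$totals[nrow(x$totals), ]
  cat(sprintf(paste0("<burden_result> %s, years %d-%d\n",
                     "  %d: prevalence %.1f, incident %.1f, deaths ",
                     "(onset-nondx %.2f, after-dx %.2f, background %.1f)\n"),
              x$country_id, min(x$totals$year), max(x$totals$year),
              last$year, last$prevalence, last$incident_diagnosed,
              last$deaths_onset_nondx, last$deaths_after_dx,
              last$deaths_background))
  invisible(x)
}

#' Tidy export of a burden result
#'
#' @param x a `burden_result`.
#' @param ... unused.
#' @return data frame with columns `country_id, quantity, age, year, value`.
#' @export
as.data.frame.burden_result <- function(x, ...) {
  qty <- c("prevalence", "incident_diagnosed", "deaths_onset_nondx",
           "deaths_after_dx", "deaths_background")
  do.call(rbind, lapply(qty, function(q) {
    cbind(country_id = x$country_id, quantity = q,
          as.data.frame(x[[q]])[c("age", "year", "value")])
  }))
}

# Survival bookkeeping for one person diagnosed at (onset_age, onset_year):
# per model year, the probability of being alive at the start, the death
# probability within the year, and person-years credited (survivors a full
# year, deaths half a year). The non-diagnosis risk applies at onset only.
survival_trace <- function(inputs, onset_age, onset_year, a_max = 99L,
                           background_only = FALSE, smr_override = NULL) {
  if (onset_age > a_max) stop_validation("onset_age exceeds terminal age %d", a_max)
  ndx <- if (background_only) 0 else get_nondx(inputs, onset_year, onset_age, clamp = TRUE)
  ages <- onset_age:a_max
  n <- length(ages)
  S <- numeric(n); py <- numeric(n); qd <- numeric(n)
  s <- 1
  for (k in seq_len(n)) {
    a <- ages[k]; y <- onset_year + (k - 1L)
    q <- ays_value(inputs$background_mortality, min(a, max(surface_ages(inputs$background_mortality))),
                   y, clamp = TRUE, context = inputs$country_id)
    if (a == a_max) q <- 1
    if (background_only) {
      qy <- q
    } else {
      smr <- if (is.null(smr_override)) {
        ays_value(inputs$smr, min(a, max(surface_ages(inputs$smr))), y,
                  clamp = TRUE, context = inputs$country_id)
      } else smr_override
      qy <- min(1, 1 - (1 - q)^smr)
    }
    S[k] <- s
    qd[k] <- qy
    py[k] <- s * ((1 - qy) + 0.5 * qy)
    s <- s * (1 - qy)
  }
  list(onset_age = onset_age, onset_year = onset_year, ages = ages,
       duration = seq_len(n) - 1L, alive_at_start = S, death_prob = qd,
       person_years = py, nondx_at_onset = ndx)
}

#' Life expectancy at onset of symptomatic T1D
#'
#' Expected remaining years for a person developing symptomatic T1D at a
#' given age and year, including the risk of dying undiagnosed at onset.
#' Deaths are credited half a year in the year they occur (half-cycle
#' correction); surfaces are extended by last-value carry-forward beyond the
#' data horizon.
#'
#' @param inputs a [country_inputs()] bundle.
#' @param onset_age,onset_year age (completed years) and calendar year of
#'   onset.
#' @param a_max terminal age, absorbing-to-death. May exceed the surface age
#'   range, in which case the oldest covered age's rates are reused.
#' @return remaining life expectancy in years.
#' @export
life_expectancy_at_onset <- function(inputs, onset_age, onset_year,
                                     a_max = 99L) {
  tr <- survival_trace(inputs, onset_age, onset_year, a_max)
  le_dx <- sum(tr$person_years)
  tr$nondx_at_onset * 0.5 + (1 - tr$nondx_at_onset) * le_dx
}

#' @rdname life_expectancy_at_onset
#' @details `background_life_expectancy()` is the same computation with the
#'   background death probability alone (no SMR, no non-diagnosis risk); it is
#'   the reference against which the T1D effect is measured.
#' @export
background_life_expectancy <- function(inputs, onset_age, onset_year,
                                       a_max = 99L) {
  sum(survival_trace(inputs, onset_age, onset_year, a_max,
                     background_only = TRUE)$person_years)
}

#' Missing prevalence: the people who should be here
#'
#' The counterfactual number of additional people who would be alive with
#' diagnosed T1D in a given year had nobody died undiagnosed at onset and had
#' diagnosed people faced only background mortality (SMR = 1), all else
#' equal.
#'
#' @param inputs a [country_inputs()] bundle.
#' @param year reporting year.
#' @param a_max terminal age.
#' @return persons (never negative).
#' @export
missing_prevalence <- function(inputs, year, a_max = 99L) {
  fact <- run_country(inputs, year, year, a_max = a_max)
  cf <- run_country(counterfactual_inputs(inputs), year, year, a_max = a_max)
  max(0, cf$totals$prevalence[1] - fact$totals$prevalence[1])
}

#' Split T1D deaths into non-diagnosis and post-diagnosis shares
#'
#' Returns the two percentages of the total, rounded to the nearest integer;
#' if rounding makes them miss 100, the larger share absorbs the difference.
#'
#' @param deaths_onset deaths at onset from non-diagnosis (persons).
#' @param deaths_after_dx deaths among people living with diagnosed T1D.
#' @return named numeric vector `c(onset_nondx = , after_dx = )` in percent.
#' @examples
#' mortality_shares(35000, 140000)   # 20 / 80
#' @export
mortality_shares <- function(deaths_onset, deaths_after_dx) {
  if (deaths_onset < 0 || deaths_after_dx < 0)
    stop_validation("death counts must be >= 0")
  tot <- deaths_onset + deaths_after_dx
  if (tot == 0) stop_validation("undefined shares: both death counts are zero")
  sh <- round(c(onset_nondx = deaths_onset, after_dx = deaths_after_dx) / tot * 100)
  if (sum(sh) != 100) {
    i <- which.max(sh)
    sh[i] <- sh[i] + (100 - sum(sh))
  }
  sh
}
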