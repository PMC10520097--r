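#' Scenario specification for future projections
#'
#' Two scenarios are supported. Under the conservative scenario, incidence,
#' SMR, and non-diagnosis rates are held constant at their last data-year
#' values. Under the momentum scenario each of them keeps changing at its
#' average annual rate of change over the momentum window (default
#' 2012-2021), implemented as the per-age geometric mean of year-on-year
#' ratios so that the compounding is self-consistent.
#'
#' @param kind `"conservative"` or `"momentum"`.
#' @param horizon_year last projected year (after the last data year).
#' @param momentum_window two years, default `c(2012, 2021)`.
#' @return a `scenario_spec` list.
#' @export
scenario_spec <- function(kind = c("conservative", "momentum"),
                          horizon_year, momentum_window = c(2012L, 2021L)) {
  kind <- match.arg(kind)
  if (momentum_window[1] >= momentum_window[2])
    stop_validation("momentum window start must precede its end")
  structure(list(kind = kind, horizon_year = as.integer(horizon_year),
                 momentum_window = as.integer(momentum_window)),
            class = "scenario_spec")
}

# per-age geometric mean annual ratio of a surface over [w1, w2]
momentum_ratio <- function(s, w1, w2) {
  v1 <- vapply(surface_ages(s), function(a) ays_value(s, a, w1), numeric(1))
  v2 <- vapply(surface_ages(s), function(a) ays_value(s, a, w2), numeric(1))
  g <- rep(1, length(v1))
  ok <- v1 > 0 & v2 > 0
  g[ok] <- (v2[ok] / v1[ok])^(1 / (w2 - w1))
  g
}

# extend a surface to horizon with per-age multiplier g per year
compound_forward <- function(s, horizon, g, unit_cap = NULL) {
  last <- max(surface_years(s))
  if (horizon <= last) return(s)
  k <- seq_len(horizon - last)
  base <- vapply(surface_ages(s), function(a) ays_value(s, a, last), numeric(1))
  fut <- outer(seq_along(base), k, function(i, kk) base[i] * g[i]^kk)
  if (!is.null(unit_cap)) fut <- pmin(fut, unit_cap)
  vals <- cbind(unclass(s), fut)
  age_year_surface(vals, ages = surface_ages(s),
                   years = c(surface_years(s), last + k), unit = surface_unit(s))
}

#' Build projected inputs under a scenario
#'
#' Incidence, SMR, and (through the complement `1 - rate`, so values stay in
#' \[0, 1\] under compounding) the non-diagnosis rate are extended to the
#' horizon year. A schedule-form non-diagnosis input is materialised into a
#' surface over ages 0-24 before projecting. If the population surface does
#' not reach the horizon it is carried forward constant, with a warning.
#'
#' @param inputs a [country_inputs()] bundle.
#' @param scenario a [scenario_spec()].
#' @return a [country_inputs()] bundle covering years up to the horizon.
#' @export
project_inputs <- function(inputs, scenario) {
  last <- max(surface_years(inputs$incidence))
  hz <- scenario$horizon_year
  if (hz <= last)
    stop_validation("horizon_year must be after the last data year (%d)", last)
  w <- scenario$momentum_window
  momentum <- scenario$kind == "momentum"
  if (momentum &&
      (w[1] < min(surface_years(inputs$incidence)) || w[2] > last)) {
    stop_coverage("momentum window %d-%d not covered by the inputs", w[1], w[2])
  }
  ones <- function(s) rep(1, length(surface_ages(s)))
  g_inc <- if (momentum) momentum_ratio(inputs$incidence, w[1], w[2]) else ones(inputs$incidence)
  g_smr <- if (momentum) momentum_ratio(inputs$smr, w[1], w[2]) else ones(inputs$smr)
  out <- inputs
  out$incidence <- compound_forward(inputs$incidence, hz, g_inc)
  out$smr <- compound_forward(inputs$smr, hz, g_smr)

  # non-diagnosis: materialise, then compound the diagnosed complement
  nd <- inputs$nondx
  if (!is.null(nd)) {
    if (!inherits(nd, "age_year_surface")) {
      yrs <- surface_years(inputs$incidence)
      vals <- outer(0:24, yrs, Vectorize(function(a, y)
        nondx_rate(nd, inputs$region, inputs$income_group, y, a)))
      nd <- age_year_surface(vals, ages = 0:24, years = yrs, unit = "probability")
    }
    comp <- age_year_surface(1 - unclass(nd), ages = surface_ages(nd),
                             years = surface_years(nd), unit = "probability")
    g_c <- if (momentum) momentum_ratio(comp, w[1], w[2]) else ones(comp)
    comp <- compound_forward(comp, hz, g_c, unit_cap = 1)
    out$nondx <- age_year_surface(1 - unclass(comp), ages = surface_ages(comp),
                                  years = surface_years(comp),
                                  unit = "probability")
  }
  if (max(surface_years(inputs$population)) < hz) {
    warn_t1dsim("population carried forward constant to %d", hz,
                class = "t1dsim_population_carryforward")
    out$population <- ays_extend(inputs$population, hz)
  }
  if (max(surface_years(inputs$background_mortality)) < hz) {
    out$background_mortality <- ays_extend(inputs$background_mortality, hz)
  }
  out
}

#' Project burden forward and report prevalence growth
#'
#' Runs the Markov engine on [project_inputs()] output and reports total
#' diagnosed prevalence in the requested years together with the percentage
#' growth from the first to the last reported year.
#'
#' @param inputs a [country_inputs()] bundle.
#' @param scenario a [scenario_spec()].
#' @param report_years years to report (all <= horizon).
#' @param a_max terminal age.
#' @return list with `burden` (a `burden_result`), `totals` (data frame
#'   year/prevalence), and `growth_pct`.
#' @export
project_burden <- function(inputs, scenario, report_years, a_max = 99L) {
  proj <- project_inputs(inputs, scenario)
  b <- run_country(proj, min(report_years), max(report_years), a_max = a_max)
  tot <- b$totals[b$totals$year %in% report_years, c("year", "prevalence")]
  p0 <- tot$prevalence[which.min(tot$year)]
  p1 <- tot$prevalence[which.max(tot$year)]
  growth <- if (p0 > 0) (p1 / p0 - 1) * 100 else NA_real_
  list(burden = b, totals = tot, growth_pct = growth)
}
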