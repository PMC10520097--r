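#' World regions and income groups used throughout the model
#'
#' The seven-region set used for survey-based non-diagnosis rates and for
#' stratified incidence imputation, and the four World Bank style income
#' groups.
#'
#' @return character vector of labels.
#' @export
t1d_regions <- function() {
  c("East Asia and Pacific", "Europe and Central Asia",
    "Latin America and Caribbean", "Middle East and North Africa",
    "North America", "South Asia", "Sub-Saharan Africa")
}

#' @rdname t1d_regions
#' @export
t1d_income_groups <- function() c("LIC", "LMIC", "UMIC", "HIC")

#' Assemble the inputs the Markov engine needs for one country
#'
#' Bundles the four surfaces (population, background mortality, incidence,
#' SMR), the non-diagnosis schedule, and country covariates. Deaths from
#' non-diagnosis are structurally zero for ages 25 and over and for
#' high-income countries, whatever the supplied schedule says: those are
#' modelling assumptions, not data.
#'
#' The SMR may be given directly as a surface, or resolved from a care-level
#' mix: a data frame with columns `name`, `share`, `mean_hba1c`, whose shares
#' sum to 1. In that case the country's all-age SMR is the share-weighted
#' mean of [smr_from_hba1c()] over the mix, applied as a constant surface on
#' the incidence grid.
#'
#' @param country_id short identifier.
#' @param region one of [t1d_regions()].
#' @param income_group one of [t1d_income_groups()].
#' @param population [age_year_surface()] of persons.
#' @param background_mortality [age_year_surface()] of annual death
#'   probabilities.
#' @param incidence [age_year_surface()] of diagnosed-symptomatic onset rates
#'   per 100,000 person-years.
#' @param smr [age_year_surface()] (dimensionless) or `NULL` when `care_mix`
#'   is given. Values below 1 are permitted but flagged with a warning.
#' @param care_mix optional care-level mix (see Details).
#' @param hba1c_smr_knots knot table for [smr_from_hba1c()], used only to
#'   resolve `care_mix`.
#' @param nondx non-diagnosis death rates: either `NULL` (zero everywhere), a
#'   survey schedule data frame with columns `region`, `era`, `rate` (see
#'   [nondx_rate()]), or an [age_year_surface()] of proportions.
#' @param covariates optional [country_covariates()].
#' @return an object of class `country_inputs`.
#' @export
country_inputs <- function(country_id, region, income_group,
                           population, background_mortality, incidence,
                           smr = NULL, care_mix = NULL,
                           hba1c_smr_knots = default_hba1c_smr_knots(),
                           nondx = NULL, covariates = NULL) {
  region <- match.arg(region, t1d_regions())
  income_group <- match.arg(income_group, t1d_income_groups())
  stopifnot(inherits(population, "age_year_surface"),
            inherits(background_mortality, "age_year_surface"),
            inherits(incidence, "age_year_surface"))
  if (surface_unit(background_mortality) != "probability")
    stop_validation("background_mortality must have unit 'probability'")
  if (is.null(smr)) {
    if (is.null(care_mix))
      stop_validation("provide either an smr surface or a care_mix")
    if (abs(sum(care_mix$share) - 1) > 1e-8)
      stop_validation("care_mix shares must sum to 1")
    level <- sum(care_mix$share *
                 vapply(care_mix$mean_hba1c, smr_from_hba1c,
                        numeric(1), knots = hba1c_smr_knots))
    smr <- age_year_surface(level, ages = surface_ages(incidence),
                            years = surface_years(incidence),
                            unit = "dimensionless")
  }
  if (any(smr < 1)) {
    warn_t1dsim("smr surface for %s has values < 1 (kept as given)",
                country_id, class = "t1dsim_smr_below_one")
  }
  structure(list(country_id = country_id, region = region,
                 income_group = income_group,
                 population = population,
                 background_mortality = background_mortality,
                 incidence = incidence, smr = smr,
                 nondx = nondx, covariates = covariates),
            class = "country_inputs")
}

#' @export
print.country_inputs <- function(x, ...) {
  cat(sprintf("<country_inputs> %s (%s, %s); years %d-%d\n",
              x$country_id, x$region, x$income_group,
              min(surface_years(x$incidence)), max(surface_years(x$incidence))))
  invisible(x)
}

# Non-diagnosis rate for one (year, age) under this country's inputs, with the
# structural zeros (age >= 25, HIC) enforced on top of whatever was supplied.
get_nondx <- function(inputs, year, age, clamp = FALSE) {
  if (age >= 25L || inputs$income_group == "HIC") return(0)
  src <- inputs$nondx
  if (is.null(src)) return(0)
  if (inherits(src, "age_year_surface")) {
    return(ays_value(src, age, year, clamp = clamp,
                     context = inputs$country_id))
  }
  nondx_rate(src, inputs$region, inputs$income_group, year, age)
}

# A copy of the inputs with the counterfactual of perfect diagnosis and no
# excess mortality: nondx = 0 everywhere, SMR = 1 everywhere.
counterfactual_inputs <- function(inputs) {
  inputs$nondx <- NULL
  inputs$smr <- age_year_surface(1, ages = surface_ages(inputs$smr),
                                 years = surface_years(inputs$smr),
                                 unit = "dimensionless")
  inputs
}

#' Read and write country input bundles as long-format CSV
#'
#' The interchange format is one long CSV with columns
#' `country_id, metric, age, year, value`, where `metric` is one of
#' `population`, `bg_mortality`, `incidence`, `nondx_rate`, `smr`.
#' The `nondx_rate` metric is optional; when present it is read back as a
#' proportion surface over the ages it covers. Region and income group are
#' not part of the long format and are supplied as arguments when reading.
#'
#' @param inputs a [country_inputs()] object.
#' @param path CSV file path.
#' @return `write_country_bundle` returns `path` invisibly;
#'   `read_country_bundle` returns a [country_inputs()] object.
#' @export
write_country_bundle <- function(inputs, path) {
  surf <- function(s, metric) cbind(country_id = inputs$country_id,
                                    metric = metric, as.data.frame(s)[c("age", "year", "value")])
  out <- rbind(surf(inputs$population, "population"),
               surf(inputs$background_mortality, "bg_mortality"),
               surf(inputs$incidence, "incidence"),
               surf(inputs$smr, "smr"))
  if (inherits(inputs$nondx, "age_year_surface")) {
    out <- rbind(out, surf(inputs$nondx, "nondx_rate"))
  } else if (!is.null(inputs$nondx)) {
    yrs <- surface_years(inputs$incidence)
    grid <- expand.grid(age = 0:24, year = yrs)
    grid$value <- mapply(function(a, y) nondx_rate(inputs$nondx, inputs$region,
                                                   inputs$income_group, y, a),
                         grid$age, grid$year)
    out <- rbind(out, cbind(country_id = inputs$country_id,
                            metric = "nondx_rate", grid[c("age", "year", "value")]))
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_country_bundle
#' @param region,income_group country classification (not carried in the CSV).
#' @export
read_country_bundle <- function(path, region, income_group) {
  df <- utils::read.csv(path)
  need <- c("country_id", "metric", "age", "year", "value")
  if (!all(need %in% names(df)))
    stop_validation("bundle CSV must have columns %s", paste(need, collapse = ", "))
  pick <- function(metric, unit) {
    d <- df[df$metric == metric, ]
    if (nrow(d) == 0) {
      if (metric == "nondx_rate") return(NULL)
      stop_coverage("bundle is missing metric '%s'", metric)
    }
    ages <- sort(unique(d$age)); years <- sort(unique(d$year))
    m <- matrix(NA_real_, length(ages), length(years))
    m[cbind(match(d$age, ages), match(d$year, years))] <- d$value
    age_year_surface(m, ages = ages, years = years, unit = unit)
  }
  country_inputs(country_id = df$country_id[1], region = region,
                 income_group = income_group,
                 population = pick("population", "persons"),
                 background_mortality = pick("bg_mortality", "probability"),
                 incidence = pick("incidence", "per100k_py"),
                 smr = pick("smr", "dimensionless"),
                 nondx = pick("nondx_rate", "probability"))
}
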