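#' Country archetypes for the synthetic-data generator
#'
#' Five stylised country profiles spanning the observed global spread of
#' T1D burden: two high-income profiles (high- and low-incidence), an
#' upper-middle, a lower-middle, and a low-income sub-Saharan profile with
#' the later onset-age pattern and high non-diagnosis rates. Parameter
#' ranges bracket the spread seen across real countries (childhood
#' prevalence per 100,000 spanning roughly three orders of magnitude).
#'
#' @return named list of archetype parameter lists.
#' @export
country_archetypes <- function() {
  list(
    `HIC-high-incidence` = list(
      region = "Europe and Central Asia", income_group = "HIC",
      base_incidence = 25, apc = 1.5, onset_variant = "default",
      smr_2000 = 1.6, smr_trend = -1.0,
      q0 = 0.004, q_scale = 1.0, births0 = 60000, birth_growth = 0.2,
      covariates = list(infant_mortality = 3, doctors_per_capita = 4,
                        gdp_per_capita = 45000, under5_mortality = 4,
                        urbanisation = 85)),
    `HIC-low-incidence` = list(
      region = "East Asia and Pacific", income_group = "HIC",
      base_incidence = 2.5, apc = 2.0, onset_variant = "default",
      smr_2000 = 1.8, smr_trend = -0.8,
      q0 = 0.003, q_scale = 0.9, births0 = 90000, birth_growth = 0.0,
      covariates = list(infant_mortality = 2, doctors_per_capita = 2.5,
                        gdp_per_capita = 40000, under5_mortality = 3,
                        urbanisation = 90)),
    UMIC = list(
      region = "Latin America and Caribbean", income_group = "UMIC",
      base_incidence = 8, apc = 2.5, onset_variant = "default",
      smr_2000 = 3.5, smr_trend = -1.2,
      q0 = 0.012, q_scale = 1.4, births0 = 120000, birth_growth = 0.8,
      covariates = list(infant_mortality = 15, doctors_per_capita = 2,
                        gdp_per_capita = 9000, under5_mortality = 18,
                        urbanisation = 75)),
    LMIC = list(
      region = "South Asia", income_group = "LMIC",
      base_incidence = 4, apc = 3.0, onset_variant = "default",
      smr_2000 = 6, smr_trend = -1.5,
      q0 = 0.035, q_scale = 2.0, births0 = 250000, birth_growth = 1.2,
      covariates = list(infant_mortality = 35, doctors_per_capita = 0.8,
                        gdp_per_capita = 2000, under5_mortality = 45,
                        urbanisation = 35)),
    `LIC-SSA` = list(
      region = "Sub-Saharan Africa", income_group = "LIC",
      base_incidence = 1.5, apc = 3.5, onset_variant = "ssa",
      smr_2000 = 10, smr_trend = -1.0,
      q0 = 0.07, q_scale = 3.0, births0 = 180000, birth_growth = 2.2,
      covariates = list(infant_mortality = 60, doctors_per_capita = 0.2,
                        gdp_per_capita = 800, under5_mortality = 90,
                        urbanisation = 30)))
}

# Siler-flavoured background mortality: infant hump, low plateau, Gompertz
# old-age rise; scaled per archetype and improving slowly through time.
background_q <- function(ages, year, q0, q_scale) {
  improve <- 0.995^(year - 1960)
  q <- q0 * exp(-ages) +
    0.0004 * q_scale +
    0.00003 * q_scale * exp(0.085 * ages)
  pmin(0.95, q * ifelse(improve < 0.5, 0.5, improve))
}

#' Generate a complete synthetic country bundle
#'
#' Builds internally consistent inputs for one archetype: births growing at
#' the archetype's demographic rate; a Siler-style background mortality
#' surface improving through time; an incidence surface from the
#' archetype's onset-age variant and an all-age level compounding at its
#' annual percentage change (held constant before 1975); a flat-age SMR
#' surface trending through time; and the packaged non-diagnosis schedule.
#' Deterministic for a fixed seed (the seed perturbs the incidence level by
#' a small lognormal year effect when `noise_sd > 0`).
#'
#' @param archetype name from [country_archetypes()] or a parameter list of
#'   the same shape.
#' @param seed integer seed.
#' @param years calendar years to cover, default `1910:2040` (enough
#'   history to report any year from 2009 at all ages).
#' @param a_max top age of the surfaces.
#' @param noise_sd lognormal sd of the year effect on incidence, default 0.
#' @return a [country_inputs()] bundle.
#' @export
make_country <- function(archetype = "UMIC", seed = 1L, years = 1910:2040,
                         a_max = 99L, noise_sd = 0) {
  p <- if (is.character(archetype)) {
    arcs <- country_archetypes()
    if (!archetype %in% names(arcs))
      stop_validation("unknown archetype '%s'", archetype)
    arcs[[archetype]]
  } else archetype
  ages <- 0:a_max
  nyr <- length(years)

  # reproducible local RNG
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)

  qmat <- outer(ages, years, function(a, y)
    background_q(a, y, p$q0, p$q_scale))
  bg <- age_year_surface(qmat, ages = ages, years = years, unit = "probability")

  births <- p$births0 * (1 + p$birth_growth / 100)^(years - min(years))
  pop <- matrix(0, length(ages), nyr)
  pop[1, ] <- births
  for (i in seq_along(ages)[-1]) {
    pop[i, ] <- c(rep(births[1] * prod(1 - qmat[seq_len(i - 1), 1]), 1),
                  pop[i - 1, -nyr] * (1 - qmat[i - 1, -nyr]))
  }
  population <- age_year_surface(pop, ages = ages, years = years, unit = "persons")

  level <- p$base_incidence * (1 + p$apc / 100)^(pmax(years, 1975) - 2000)
  if (noise_sd > 0) level <- level * exp(stats::rnorm(nyr, 0, noise_sd))
  names(level) <- years
  dist <- onset_age_distribution(p$onset_variant, a_max = a_max)
  incidence <- build_incidence_surface(level, dist,
                                       ref_weights = rowMeans(pop))

  smr_level <- pmax(1, p$smr_2000 * (1 + p$smr_trend / 100)^(years - 2000))
  smr <- age_year_surface(matrix(rep(smr_level, each = length(ages)),
                                 length(ages), nyr),
                          ages = ages, years = years, unit = "dimensionless")

  cov <- do.call(country_covariates,
                 c(list(region = p$region, income_class = p$income_group),
                   p$covariates))
  country_inputs(country_id = if (is.character(archetype)) archetype else "custom",
                 region = p$region, income_group = p$income_group,
                 population = population, background_mortality = bg,
                 incidence = incidence, smr = smr,
                 nondx = default_nondx_schedule(), covariates = cov)
}

#' Generate a synthetic SMR training set with known ground truth
#'
#' Stands in for the sparse real-world scatter of published SMR points (71
#' in the real assembly, the default `n` here). Countries are sampled along
#' a latent development gradient so that the numeric covariates co-vary the
#' way real country statistics do (child mortality falling as GDP, doctors
#' per capita, and urbanisation rise); the SMR is a declared function of
#' the covariates plus optional noise, so that predictor-recovery
#' experiments know the truth.
#'
#' @param n number of points.
#' @param seed integer seed.
#' @param f generating function: takes the covariate data frame, returns
#'   SMR. Default `1 + 0.2 * under5_mortality`.
#' @param noise_sd Gaussian noise sd on the SMR, default 0.
#' @param jitter_sd lognormal jitter of covariates around the development
#'   gradient, default 0.1.
#' @return data frame of SMR training points; the generating function is
#'   attached as attribute `generating_function`.
#' @export
make_smr_training <- function(n = 71L, seed = 1L,
                              f = function(cv) 1 + 0.2 * cv$under5_mortality,
                              noise_sd = 0, jitter_sd = 0.1) {
  if (n < 1) stop_validation("n must be >= 1")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  d <- stats::runif(n)
  jit <- function() exp(stats::rnorm(n, 0, jitter_sd))
  cv <- data.frame(
    country_id = sprintf("SYN%03d", seq_len(n)),
    year = sample(1990:2020, n, replace = TRUE),
    age_low = 0L, age_high = 24L,
    infant_mortality = (2 + 110 * (1 - d)^1.6) * jit(),
    doctors_per_capita = (0.15 + 5 * d^1.3) * jit(),
    gdp_per_capita = 600 * exp(4.4 * d) * jit(),
    under5_mortality = (2.5 + 145 * (1 - d)^1.6) * jit(),
    urbanisation = pmin(100, (18 + 75 * d) * jit()),
    region = sample(t1d_regions(), n, replace = TRUE),
    income_class = t1d_income_groups()[findInterval(d, c(0, .25, .5, .75, 1),
                                                    rightmost.closed = TRUE)])
  cv$smr <- pmax(0.05, f(cv) + stats::rnorm(n, 0, noise_sd))
  attr(cv, "generating_function") <- f
  cv
}
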