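#' Smooth an incidence series with a centred moving average
#'
#' Published incidence series fluctuate from year to year; a centred moving
#' average with edge shrinkage (the window is truncated at the series
#' boundaries) is applied before trend fitting. A window of 1 is the
#' identity.
#'
#' @param series named numeric vector (names are years) or plain vector.
#' @param window odd integer window width, default 5.
#' @return smoothed vector with the same names.
#' @export
smooth_series <- function(series, window = 5L) {
  if (window %% 2 == 0 || window < 1)
    stop_validation("smoothing window must be an odd integer >= 1")
  n <- length(series)
  if (n == 0) stop_validation("series must have at least one point")
  h <- (window - 1L) %/% 2L
  out <- vapply(seq_len(n), function(i) {
    mean(series[max(1L, i - h):min(n, i + h)])
  }, numeric(1))
  names(out) <- names(series)
  out
}

#' Fit annual-percentage-change curves from sparse incidence observations
#'
#' For every country with observations in consecutive years, the
#' year-on-year percentage change is computed and assigned to the later
#' year. Changes are pooled by year over all countries, keeping the years in
#' the support window in which at least two countries contributed, and an
#' ordinary least squares line of change against year is fitted. The same
#' procedure runs per region; a region that does not independently meet the
#' two-country rule gets a fallback curve that evaluates to the global one.
#'
#' @param obs data frame with columns `country_id`, `region`, `mid_year`,
#'   `rate` (per 100,000 person-years).
#' @param support_years years eligible for the fit, default `1985:2015`.
#' @return list with elements `global` (an `apc_curve`) and `regional`
#'   (named list of `apc_curve` objects, one per region present in `obs`).
#' @export
fit_apc_curves <- function(obs, support_years = 1985:2015) {
  stopifnot(all(c("country_id", "region", "mid_year", "rate") %in% names(obs)))
  glob <- fit_one_apc(obs, "global", support_years, fallback_to = NULL)
  regional <- list()
  for (r in unique(obs$region)) {
    sub <- obs[obs$region == r, ]
    regional[[r]] <- tryCatch(
      fit_one_apc(sub, r, support_years, fallback_to = glob),
      t1dsim_validation_error = function(e) {
        structure(list(scope = r, support = range(support_years),
                       slope = glob$slope, intercept = glob$intercept,
                       fallback = TRUE), class = "apc_curve")
      })
  }
  list(global = glob, regional = regional)
}

# pooled year-on-year changes -> OLS line; errors if under-identified
fit_one_apc <- function(obs, scope, support_years, fallback_to = NULL) {
  chg <- do.call(rbind, lapply(split(obs, obs$country_id), function(d) {
    d <- d[order(d$mid_year), ]
    i <- which(diff(d$mid_year) == 1L)
    if (!length(i)) return(NULL)
    data.frame(country_id = d$country_id[1], year = d$mid_year[i + 1L],
               change = (d$rate[i + 1L] / d$rate[i] - 1) * 100)
  }))
  if (!is.null(chg)) {
    chg <- chg[chg$year %in% support_years, ]
    counts <- table(unique(chg[c("country_id", "year")])$year)
    keep <- as.integer(names(counts)[counts >= 2])
    chg <- chg[chg$year %in% keep, ]
  }
  if (is.null(chg) || nrow(chg) == 0)
    stop_validation("insufficient data to fit an APC curve for scope '%s'", scope)
  if (length(unique(chg$year)) == 1L) {
    slope <- 0; intercept <- mean(chg$change)
  } else {
    fit <- stats::lm(change ~ year, data = chg)
    slope <- unname(stats::coef(fit)["year"])
    intercept <- unname(stats::coef(fit)["(Intercept)"])
  }
  structure(list(scope = scope, support = range(support_years),
                 slope = slope, intercept = intercept, fallback = FALSE),
            class = "apc_curve")
}

#' Evaluate an APC curve (percent per year) at given years
#'
#' Linear extension outside the support window.
#'
#' @param curve an `apc_curve` from [fit_apc_curves()].
#' @param year integer vector.
#' @return annual percentage change, in percent.
#' @export
apc_at <- function(curve, year) curve$intercept + curve$slope * year

#' @export
print.apc_curve <- function(x, ...) {
  cat(sprintf("<apc_curve> %s%s: APC(y) = %.4f + %.6f * y (support %d-%d)\n",
              x$scope, if (x$fallback) " [fallback to global]" else "",
              x$intercept, x$slope, x$support[1], x$support[2]))
  invisible(x)
}

#' Extrapolate an incidence level through time by compounding an APC curve
#'
#' The anchor rate is compounded forward and backward: the traversal from
#' year `y - 1` to `y` multiplies by `1 + APC(y)/100`. Years before
#' `floor_year` are held constant at the `floor_year` value, reflecting the
#' near-absence of incidence data before 1975. Forward-then-backward
#' traversal over the same years is exactly reversible.
#'
#' @param anchor_rate observed rate (per 100,000 person-years), > 0.
#' @param anchor_year year of the anchor observation.
#' @param curve an `apc_curve`.
#' @param target_years years at which to evaluate.
#' @param floor_year constant-history floor, default 1975.
#' @return named numeric vector of rates over `target_years`.
#' @export
extrapolate_incidence <- function(anchor_rate, anchor_year, curve,
                                  target_years, floor_year = 1975L) {
  if (anchor_rate <= 0) stop_validation("anchor rate must be > 0")
  lo <- min(c(target_years, anchor_year, floor_year))
  hi <- max(c(target_years, anchor_year))
  yrs <- lo:hi
  val <- numeric(length(yrs)); names(val) <- yrs
  val[as.character(anchor_year)] <- anchor_rate
  if (anchor_year < hi) {
    for (y in (anchor_year + 1L):hi) {
      m <- if (y > floor_year) 1 + apc_at(curve, y) / 100 else 1
      val[as.character(y)] <- val[as.character(y - 1L)] * m
    }
  }
  if (anchor_year > lo) {
    for (y in (anchor_year - 1L):lo) {
      m <- if (y + 1L > floor_year) 1 + apc_at(curve, y + 1L) / 100 else 1
      val[as.character(y)] <- val[as.character(y + 1L)] / m
    }
  }
  if (floor_year >= lo) {
    flo <- val[as.character(min(hi, max(lo, floor_year)))]
    below <- yrs < floor_year
    val[below] <- flo
  }
  val[as.character(target_years)]
}

#' Impute an incidence series for a country without data
#'
#' Donor countries are taken from the narrowest non-empty stratum around the
#' target, widening in the order region-and-income-group, region, global.
#' The imputed series is the per-year arithmetic median over the distinct
#' donor countries, scaled by the ratio of a stratified log-linear
#' regression prediction (log incidence on income group and region) for the
#' target versus the mean prediction over the stratum donors. With a single
#' donor, or whenever the regression cannot distinguish the target from its
#' donors, the scaling is 1 and the median series is returned as is.
#'
#' @param target list or one-row data frame with `region`, `income_group`.
#' @param donors data frame with columns `country_id`, `region`,
#'   `income_group`, `year`, `rate`.
#' @return named numeric vector: imputed rate per year.
#' @export
ratio_impute <- function(target, donors) {
  stopifnot(all(c("country_id", "region", "income_group", "year", "rate")
                %in% names(donors)))
  pool <- donors[donors$region == target$region &
                 donors$income_group == target$income_group, ]
  if (nrow(pool) == 0) pool <- donors[donors$region == target$region, ]
  if (nrow(pool) == 0) pool <- donors
  if (nrow(pool) == 0)
    stop_validation("no donor countries at any stratum widening level")

  # dedupe: one series per distinct country (first occurrence wins)
  med <- tapply(pool$rate, list(pool$year, pool$country_id), mean)
  series <- apply(med, 1, stats::median, na.rm = TRUE)

  scale <- 1
  if (length(unique(donors$country_id)) >= 3 &&
      (length(unique(donors$income_group)) > 1 || length(unique(donors$region)) > 1)) {
    cl <- unique(donors[c("country_id", "region", "income_group")])
    cl$mlog <- log(pmax(1e-12, tapply(donors$rate, donors$country_id, mean)[cl$country_id]))
    fit <- tryCatch(stats::lm(mlog ~ income_group + region, data = cl),
                    error = function(e) NULL)
    if (!is.null(fit)) {
      pred <- function(reg, inc) {
        nd <- data.frame(income_group = inc, region = reg)
        ok <- (!("income_group" %in% names(fit$xlevels)) ||
                 inc %in% fit$xlevels$income_group) &&
              (!("region" %in% names(fit$xlevels)) || reg %in% fit$xlevels$region)
        if (!ok) return(NA_real_)
        unname(suppressWarnings(stats::predict(fit, nd)))
      }
      pt <- pred(target$region, target$income_group)
      pd <- mapply(pred, cl$region[cl$country_id %in% pool$country_id],
                   cl$income_group[cl$country_id %in% pool$country_id])
      if (!is.na(pt) && all(!is.na(pd))) scale <- exp(pt) / mean(exp(pd))
    }
  }
  series * scale
}

#' Age-of-onset distributions
#'
#' A discrete density over ages 0 to `a_max` for the age at symptomatic T1D
#' onset. The default variant mixes a childhood bump peaking in the 10-14
#' band with a broad adult component, so that the modal onset age is 10-14
#' while the majority of onsets are in adults (median onset in the late
#' twenties). The sub-Saharan Africa (`"ssa"`) variant shifts the childhood
#' bump later, giving a strictly later mode.
#'
#' @param variant `"default"` or `"ssa"`.
#' @param a_max top age of the support.
#' @return numeric vector of length `a_max + 1` summing to 1.
#' @export
onset_age_distribution <- function(variant = c("default", "ssa"), a_max = 99L) {
  variant <- match.arg(variant)
  ages <- 0:a_max
  p <- switch(variant,
    default = 0.30 * stats::dnorm(ages, mean = 12, sd = 3.5) +
              0.70 * stats::dnorm(ages, mean = 35, sd = 15),
    ssa     = 0.35 * stats::dnorm(ages, mean = 18, sd = 4.0) +
              0.65 * stats::dnorm(ages, mean = 38, sd = 15))
  p / sum(p)
}

#' Expand an all-age incidence level into a full age-by-year surface
#'
#' The surface cell `(a, y)` is `level(y) * shape(a)`, where `shape` rescales
#' the onset-age density so that its mean over ages, weighted by a reference
#' age structure, is exactly 1; the population-weighted mean of each year's
#' column then equals that year's all-age level.
#'
#' @param level named numeric vector: all-age incidence per 100,000
#'   person-years by year (names are years).
#' @param onset_dist density from [onset_age_distribution()].
#' @param ref_weights reference age structure (non-negative, same length as
#'   `onset_dist`); default uniform.
#' @return an [age_year_surface()] with unit `per100k_py`.
#' @export
build_incidence_surface <- function(level, onset_dist,
                                    ref_weights = rep(1, length(onset_dist))) {
  if (abs(sum(onset_dist) - 1) > 1e-9 || any(onset_dist < 0))
    stop_validation("onset_dist must be a non-negative density summing to 1")
  w <- ref_weights / sum(ref_weights)
  shape <- onset_dist / sum(w * onset_dist)
  years <- as.integer(names(level))
  if (!length(years) || anyNA(years))
    stop_validation("level must be a named vector with year names")
  age_year_surface(outer(shape, unname(level)),
                   ages = seq_along(onset_dist) - 1L, years = years,
                   unit = "per100k_py")
}
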