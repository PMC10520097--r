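#' Survey-based non-diagnosis death rates
#'
#' `default_nondx_schedule()` loads the packaged region-by-era schedule of
#' the proportion of incident symptomatic T1D cases under age 25 who die
#' soon after onset without ever being diagnosed. Rates are bucketed into
#' three eras: before 2000, 2000-2010 (closed interval), and after 2010.
#' Only the Sub-Saharan-Africa pre-2010 value (60%) is an externally
#' reported survey mean; the remaining cells of the packaged file are
#' synthetic placeholders chosen for regional plausibility, and the file is
#' named accordingly.
#'
#' @return data frame with columns `region`, `era`, `rate`.
#' @export
default_nondx_schedule <- function() {
  path <- system.file("extdata", "nondx_survey_synthetic.csv",
                      package = "t1dsim", mustWork = TRUE)
  df <- utils::read.csv(path)
  if (any(df$rate < 0 | df$rate > 1))
    stop_integrity("non-diagnosis schedule rates must lie in [0, 1]")
  df
}

#' Look up a non-diagnosis death rate
#'
#' Returns 0 for high-income countries and for ages 25 and over regardless
#' of the schedule; otherwise the era-bucketed survey value for the region.
#'
#' @param schedule data frame `(region, era, rate)`, eras
#'   `pre2000`, `2000-2010`, `post2010`.
#' @param region one of [t1d_regions()].
#' @param income_class one of [t1d_income_groups()].
#' @param year calendar year (selects the era).
#' @param age completed years.
#' @return proportion in \[0, 1\].
#' @examples
#' sched <- default_nondx_schedule()
#' nondx_rate(sched, "Sub-Saharan Africa", "LIC", 2005, 12)  # 0.6
#' @export
nondx_rate <- function(schedule, region, income_class, year, age) {
  if (income_class == "HIC" || age >= 25) return(0)
  era <- if (year < 2000) "pre2000" else if (year <= 2010) "2000-2010" else "post2010"
  hit <- schedule$rate[schedule$region == region & schedule$era == era]
  if (length(hit) != 1)
    stop_validation("no non-diagnosis rate for region '%s', era '%s'", region, era)
  hit
}

#' Country covariates for SMR prediction
#'
#' @param region,income_class classification labels.
#' @param infant_mortality per 1,000 live births.
#' @param doctors_per_capita physicians per 1,000 population.
#' @param gdp_per_capita currency units.
#' @param under5_mortality per 1,000 live births.
#' @param urbanisation percent of the population living in urban areas.
#' @return a one-row data frame of class `country_covariates`.
#' @export
country_covariates <- function(region, income_class, infant_mortality,
                               doctors_per_capita, gdp_per_capita,
                               under5_mortality, urbanisation) {
  num <- c(infant_mortality, doctors_per_capita, gdp_per_capita,
           under5_mortality, urbanisation)
  if (any(num < 0)) stop_validation("covariates must be non-negative")
  if (urbanisation > 100) stop_validation("urbanisation is a percentage <= 100")
  structure(data.frame(region = match.arg(region, t1d_regions()),
                       income_class = match.arg(income_class, t1d_income_groups()),
                       infant_mortality = infant_mortality,
                       doctors_per_capita = doctors_per_capita,
                       gdp_per_capita = gdp_per_capita,
                       under5_mortality = under5_mortality,
                       urbanisation = urbanisation),
            class = c("country_covariates", "data.frame"))
}

smr_numeric_covariates <- c("infant_mortality", "doctors_per_capita",
                            "gdp_per_capita", "under5_mortality",
                            "urbanisation", "year")

#' Fit a predictor of SMR from country covariates
#'
#' Published standardised mortality ratios for T1D exist only as a sparse
#' scatter of country-year-age points; for everywhere else the SMR must be
#' predicted from country characteristics. The default learner is
#' distance-weighted k-nearest-neighbours on standardised numeric
#' covariates (infant mortality, doctors per capita, GDP per capita,
#' under-5 mortality, urbanisation, year), with a fixed distance penalty
#' per mismatched categorical label (region, income class). It interpolates
#' exactly at its support points, which makes it transparent and easy to
#' test; a linear least-squares learner is available behind the same
#' interface. Predictions are clipped to `[1, max_smr]`: an SMR below 1 for
#' T1D is implausible and the model's framing is excess mortality.
#'
#' @param training data frame with column `smr` (> 0), the numeric
#'   covariates above, and `region`, `income_class`.
#' @param k neighbours, default 3.
#' @param max_smr upper clip, default 30.
#' @param learner `"knn"` (default) or `"linear"`.
#' @param cat_penalty squared-distance penalty added per mismatched
#'   categorical covariate, default 1.
#' @return an object of class `smr_predictor`; use [predict()] with a data
#'   frame of covariates (and optionally `year`).
#' @export
fit_smr_predictor <- function(training, k = 3L, max_smr = 30,
                              learner = c("knn", "linear"), cat_penalty = 1) {
  learner <- match.arg(learner)
  if (nrow(training) < 5) stop_validation("need at least 5 SMR training points")
  if (any(training$smr <= 0)) stop_validation("training SMRs must be > 0")
  num <- smr_numeric_covariates[smr_numeric_covariates %in% names(training)]
  X <- as.matrix(training[num])
  mu <- colMeans(X); sdv <- apply(X, 2, stats::sd)
  degenerate <- all(sdv < 1e-12)
  if (degenerate && stats::sd(training$smr) > 1e-12) {
    warn_t1dsim("degenerate SMR training set (identical covariates, differing SMRs); falling back to the mean")
  }
  sdv[sdv < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  fit <- NULL
  if (learner == "linear") {
    dat <- data.frame(smr = training$smr, Xs)
    fit <- stats::lm(smr ~ ., data = dat)
  }
  structure(list(learner = learner, k = as.integer(k), max_smr = max_smr,
                 cat_penalty = cat_penalty, num = num, mu = mu, sd = sdv,
                 Xs = Xs, y = training$smr,
                 region = training$region, income_class = training$income_class,
                 degenerate = degenerate, lmfit = fit),
            class = "smr_predictor")
}

#' @rdname fit_smr_predictor
#' @param object a fitted `smr_predictor`.
#' @param newdata data frame with the same covariate columns.
#' @param ... unused.
#' @export
predict.smr_predictor <- function(object, newdata, ...) {
  Xq <- as.matrix(newdata[object$num])
  Xq <- sweep(sweep(Xq, 2, object$mu), 2, object$sd, "/")
  n <- nrow(Xq)
  out <- numeric(n)
  if (object$degenerate) {
    out[] <- mean(object$y)
  } else if (object$learner == "linear") {
    out <- unname(stats::predict(object$lmfit, data.frame(Xq)))
  } else {
    for (i in seq_len(n)) {
      d2 <- colSums((t(object$Xs) - Xq[i, ])^2)
      if (!is.null(object$region) && "region" %in% names(newdata))
        d2 <- d2 + object$cat_penalty * (object$region != newdata$region[i])
      if (!is.null(object$income_class) && "income_class" %in% names(newdata))
        d2 <- d2 + object$cat_penalty * (object$income_class != newdata$income_class[i])
      ord <- order(d2)[seq_len(min(object$k, length(d2)))]
      if (d2[ord[1]] < 1e-24) {
        out[i] <- object$y[ord[1]]
      } else {
        w <- 1 / d2[ord]
        out[i] <- sum(w * object$y[ord]) / sum(w)
      }
    }
  }
  pmin(pmax(out, 1), object$max_smr)
}

#' Map mean HbA1c to an SMR by piecewise-linear interpolation
#'
#' The care-level chain assumes a given level of care achieves a given mean
#' HbA1c, which in turn maps to an SMR via a monotone knot table taken from
#' published excess-mortality work; the table is a configuration input, not
#' something this package re-estimates. Queries outside the knot range are
#' clamped to the end knots.
#'
#' @param knots data frame with columns `hba1c` (strictly increasing) and
#'   `smr` (non-decreasing).
#' @param hba1c query, percent units.
#' @return interpolated SMR.
#' @examples
#' smr_from_hba1c(data.frame(hba1c = c(7, 9), smr = c(1.5, 3.5)), 8)  # 2.5
#' @export
smr_from_hba1c <- function(knots, hba1c) {
  if (nrow(knots) < 2) stop_validation("need at least 2 HbA1c-SMR knots")
  if (any(diff(knots$hba1c) <= 0))
    stop_validation("knot HbA1c values must be strictly increasing")
  if (any(diff(knots$smr) < 0))
    stop_validation("knot SMR values must be non-decreasing")
  stats::approx(knots$hba1c, knots$smr, xout = hba1c, rule = 2)$y
}

#' Default HbA1c-to-SMR knot table and care levels
#'
#' Plausible defaults for the care-level chain: they are configuration
#' values meant to be replaced by published fits, not estimates of this
#' package.
#'
#' @return `default_hba1c_smr_knots()`: data frame `(hba1c, smr)`;
#'   `default_care_levels()`: data frame `(name, mean_hba1c)`.
#' @export
default_hba1c_smr_knots <- function() {
  data.frame(hba1c = c(6.5, 7, 8, 9, 10, 12, 14),
             smr = c(1.2, 1.5, 2.3, 3.5, 5.0, 9.0, 14.0))
}

#' @rdname default_hba1c_smr_knots
#' @export
default_care_levels <- function() {
  data.frame(name = c("minimal", "intermediate", "best"),
             mean_hba1c = c(12.0, 9.0, 7.0))
}

#' Apply a life-course shape to an all-age SMR
#'
#' The age pattern of SMR is assumed constant across countries and years;
#' an all-age SMR level is spread over ages by an age-specific multiplier
#' whose mean, weighted by a reference age structure, is 1 (the shape is
#' renormalised, with a warning, if it is not). The reference-weighted mean
#' of the result equals the all-age input.
#'
#' @param all_age_smr scalar SMR level.
#' @param shape numeric vector of age multipliers (one per age).
#' @param ref_weights reference age structure; default uniform.
#' @return numeric vector: SMR by age.
#' @export
apply_smr_shape <- function(all_age_smr, shape,
                            ref_weights = rep(1, length(shape))) {
  w <- ref_weights / sum(ref_weights)
  m <- sum(w * shape)
  if (abs(m - 1) > 1e-9) {
    warn_t1dsim("SMR age shape renormalised (reference-weighted mean was %.6f)", m)
    shape <- shape / m
  }
  all_age_smr * shape
}
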