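test_that("moving-average smoothing truncates at the edges and preserves constants", {
  expect_equal(smooth_series(rep(7, 10), 5), rep(7, 10))
  expect_equal(smooth_series(1:5, 3), c(1.5, 2, 3, 4, 4.5))
  expect_equal(smooth_series(c(3, 9, 1), 1), c(3, 9, 1))
  expect_error(smooth_series(1:5, 4), class = "t1dsim_validation_error")
  # never widens the range
  set.seed(1)
  x <- runif(30, 2, 9)
  sm <- smooth_series(x, 7)
  expect_true(min(sm) >= min(x) && max(sm) <= max(x))
})

make_obs <- function(countries, years, rate_fn, region = "Europe and Central Asia") {
  do.call(rbind, lapply(seq_along(countries), function(i) {
    data.frame(country_id = countries[i], region = region,
               mid_year = years, rate = rate_fn(i, years))
  }))
}

test_that("constant incidence in every country yields a zero APC curve", {
  obs <- make_obs(c("A", "B", "C"), 1990:2010, function(i, y) 10 * i)
  fit <- fit_apc_curves(obs)
  expect_equal(apc_at(fit$global, 1995), 0, tolerance = 1e-12)
  expect_equal(apc_at(fit$global, 2015), 0, tolerance = 1e-12)
})

test_that("a known 3% annual growth is recovered within 0.1 points", {
  obs <- make_obs(paste0("C", 1:5), 1985:2015,
                  function(i, y) (5 + i) * 1.03^(y - 1985))
  fit <- fit_apc_curves(obs)
  for (y in c(1985, 1995, 2005, 2015)) {
    expect_equal(apc_at(fit$global, y), 3, tolerance = 0.1)
  }
})

test_that("regions without enough countries fall back to the global curve", {
  obs <- rbind(
    make_obs(c("A", "B", "C"), 1990:2010, function(i, y) 10 * 1.02^(y - 1990),
             region = "Europe and Central Asia"),
    make_obs("Z", 1990:2010, function(i, y) 5 * 1.05^(y - 1990),
             region = "South Asia"))
  fit <- fit_apc_curves(obs)
  expect_false(fit$regional[["Europe and Central Asia"]]$fallback)
  expect_true(fit$regional[["South Asia"]]$fallback)
  expect_equal(apc_at(fit$regional[["South Asia"]], 2000),
               apc_at(fit$global, 2000))
})

flat_curve <- function(apc) structure(list(scope = "global",
                                           support = c(1985, 2015),
                                           slope = 0, intercept = apc,
                                           fallback = FALSE),
                                      class = "apc_curve")

test_that("extrapolation compounds the APC and respects the pre-1975 floor", {
  expect_equal(unname(extrapolate_incidence(10, 2000, flat_curve(0), 1980:2010)),
               rep(10, 31))
  expect_equal(unname(extrapolate_incidence(10, 2000, flat_curve(7), 2010)),
               10 * 1.07^10, tolerance = 1e-12)
  v <- extrapolate_incidence(10, 2000, flat_curve(7), 1970:1976)
  expect_equal(unname(v[as.character(1970:1974)]), rep(unname(v["1975"]), 5))
  expect_equal(unname(v["1975"]), 10 / 1.07^25, tolerance = 1e-12)
})

test_that("forward then backward extrapolation returns exactly to the anchor", {
  crv <- structure(list(scope = "global", support = c(1985, 2015),
                        slope = 0.12, intercept = -237, fallback = FALSE),
                   class = "apc_curve")
  fwd <- extrapolate_incidence(8.5, 1990, crv, 2015)
  back <- extrapolate_incidence(unname(fwd), 2015, crv, 1990)
  expect_equal(unname(back), 8.5, tolerance = 1e-12)
})

test_that("ratio imputation follows the stratum-widening and median contracts", {
  donor <- function(id, region, income, rate) {
    data.frame(country_id = id, region = region, income_group = income,
               year = 2000:2005, rate = rate)
  }
  target <- list(region = "South Asia", income_group = "LMIC")
  # single donor in the stratum: its series comes back unchanged
  d1 <- donor("A", "South Asia", "LMIC", 12)
  expect_equal(unname(ratio_impute(target, d1)), rep(12, 6))
  # two donors: arithmetic median, not upper-median
  d2 <- rbind(donor("A", "South Asia", "LMIC", 10),
              donor("B", "South Asia", "LMIC", 30))
  expect_equal(unname(ratio_impute(target, d2)), rep(20, 6))
  # duplicated donor rows do not shift the median
  expect_equal(unname(ratio_impute(target, rbind(d2, donor("A", "South Asia", "LMIC", 10)))),
               rep(20, 6))
  # stratum widening: no LMIC donor in region -> regional pool
  d3 <- rbind(donor("A", "South Asia", "LIC", 8),
              donor("B", "Sub-Saharan Africa", "LMIC", 50))
  expect_equal(unname(ratio_impute(target, d3)), rep(8, 6))
  expect_error(ratio_impute(target, d1[0, ]), class = "t1dsim_validation_error")
})

test_that("onset-age densities satisfy their structural constraints", {
  for (v in c("default", "ssa")) {
    d <- onset_age_distribution(v)
    expect_equal(sum(d), 1, tolerance = 1e-9)
    expect_true(all(d >= 0))
  }
  dd <- onset_age_distribution("default")
  ds <- onset_age_distribution("ssa")
  expect_true((which.max(dd) - 1) %in% 10:14)
  expect_gt(which.max(ds), which.max(dd))
  # adult-onset majority: median onset age at least 20
  expect_gte(which(cumsum(dd) >= 0.5)[1] - 1, 20)
})

test_that("incidence surfaces scale the onset shape to the all-age level", {
  lvl <- c(`2000` = 10, `2001` = 12)
  flat <- rep(1 / 100, 100)
  s <- build_incidence_surface(lvl, flat)
  expect_equal(ays_value(s, 0, 2000), 10)
  expect_equal(ays_value(s, 73, 2001), 12)
  d <- onset_age_distribution("default")
  s2 <- build_incidence_surface(lvl, d)
  col <- vapply(0:99, function(a) ays_value(s2, a, 2000), numeric(1))
  expect_true((which.max(col) - 1) %in% 10:14)
  # population-weighted mean equals the level under the reference structure
  expect_equal(mean(col), 10, tolerance = 1e-9)
})
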