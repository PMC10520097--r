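test_that("the annual hazard is the inverse-logit of its linear predictor", {
  spec <- toy_registry(1, intercept = 0, hcoef = 0, dcoef = 0)[1, ]
  expect_equal(annual_hazard(spec, 8, 5), 0.5)
  spec$intercept <- qlogis(0.02)
  expect_equal(annual_hazard(spec, 8, 5), 0.02, tolerance = 1e-12)
  spec$hba1c_coef <- 0.4
  h <- vapply(6:12, function(x) annual_hazard(spec, x, 5), numeric(1))
  expect_true(all(diff(h) > 0))
  # beyond the 30-year horizon the hazard is held (default) or zeroed
  spec$duration_coef <- 0.1
  expect_equal(annual_hazard(spec, 8, 45), annual_hazard(spec, 8, 30))
  expect_equal(annual_hazard(spec, 8, 45, extrapolation = "zero"), 0)
})

test_that("zero hazards leave the cohort complication-free", {
  reg <- toy_registry(3, intercept = -Inf)
  prof <- prevalence_profile(reg, NULL, hba1c = 9, D = 10)
  expect_true(all(prof$marginals == 0))
  expect_equal(unname(prof$joint[, 1]), rep(1, 11))
})

test_that("a single constant hazard gives the complement-of-survival closed form", {
  reg <- toy_registry(1, intercept = qlogis(0.02), hcoef = 0, dcoef = 0)
  prof <- prevalence_profile(reg, NULL, hba1c = 9, D = 30)
  expect_equal(unname(prof$marginals[31, 1]), 1 - 0.98^30, tolerance = 1e-12)
  expect_equal(unname(prof$marginals[11, 1]), 1 - 0.98^10, tolerance = 1e-12)
})

test_that("the joint distribution is a proper distribution with matching marginals", {
  reg <- toy_registry(4, intercept = -2.5, hcoef = 0.1, dcoef = 0.04)
  prof <- prevalence_profile(reg, NULL, hba1c = 9, D = 12)
  expect_equal(unname(rowSums(prof$joint)), rep(1, 13), tolerance = 1e-9)
  # no journeys: marginals equal independent single-complication recursions
  for (k in 1:4) {
    single <- prevalence_profile(reg[k, ], NULL, hba1c = 9, D = 12)
    expect_equal(prof$marginals[, k], single$marginals[, 1], tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("impermissible journeys block de-novo occurrence exactly", {
  reg <- default_complication_registry()
  jn <- default_impermissible_journeys()
  prof <- prevalence_profile(reg, jn, hba1c = 12, D = 25)
  bits <- 2^(0:(nrow(reg) - 1))
  for (i in seq_len(nrow(jn))) {
    b <- bits[match(jn$blocker[i], reg$name)]
    v <- bits[match(jn$blocked[i], reg$name)]
    # starting from a blocker-only state, the blocked bit must never turn on
    joint <- brute_profile(reg, jn, 12, 3, start = b)
    on_v <- bitwAnd(0:(2^nrow(reg) - 1), v) > 0
    expect_equal(sum(joint[4, on_v]), 0)
  }
})

test_that("the recursion equals exhaustive path enumeration with and without journeys", {
  reg <- toy_registry(3, intercept = -0.5, hcoef = 0.05, dcoef = 0.2)
  jn <- data.frame(blocker = reg$name[1], blocked = reg$name[2])
  for (journeys in list(NULL, jn)) {
    prof <- prevalence_profile(reg, journeys, hba1c = 10, D = 4)
    oracle <- brute_profile(reg, journeys, 10, 4)
    expect_equal(unclass(prof$joint), oracle, tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
  # two complications, heavy hazards, one journey: 2-year exhaustive check
  reg2 <- toy_registry(2, intercept = 0, hcoef = 0, dcoef = 0)  # h = 0.5
  jn2 <- data.frame(blocker = reg2$name[1], blocked = reg2$name[2])
  prof2 <- prevalence_profile(reg2, jn2, hba1c = 8, D = 2)
  expect_equal(unclass(prof2$joint), brute_profile(reg2, jn2, 8, 2),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("no excess mortality and no complications cost no healthy life years", {
  ci <- tiny_inputs(q = 0.01, smr = 1, ages = 0:40, years = 1990:2040,
                    income = "HIC", region = "North America")
  reg <- toy_registry(2, intercept = -Inf)
  knots <- data.frame(hba1c = c(6, 10), smr = c(1, 1))
  out <- halys_lost(ci, 10, 2000, care = list(mean_hba1c = 7),
                    registry = reg, journeys = NULL,
                    hba1c_smr_knots = knots, a_max = 40)
  expect_equal(unname(out), c(0, 0, 0), tolerance = 1e-9)
})

test_that("disability person-years follow the direct expectation arithmetic", {
  # near-certain single complication with weight w: disability ~ w * person-years
  ci <- tiny_inputs(q = 0.1, smr = 1, ages = 0:20, years = 1990:2040,
                    income = "HIC", region = "North America")
  reg <- toy_registry(1, intercept = 30, hcoef = 0, dcoef = 0, weight = 0.2)
  knots <- data.frame(hba1c = c(6, 10), smr = c(1, 1))
  out <- halys_lost(ci, 0, 2000, care = list(mean_hba1c = 7), registry = reg,
                    journeys = NULL, hba1c_smr_knots = knots, a_max = 2000)
  le <- (1 - 0.1) / 0.1 + 0.5            # 9.5 years, of which the first is
  py0 <- 1 - 0.1 / 2                     # complication-free (duration 0)
  expect_equal(unname(out["disability"]), 0.2 * (le - py0), tolerance = 1e-6)
  expect_equal(unname(out["death"]), 0, tolerance = 1e-9)
})

test_that("healthy life years lost rise with worsening glycaemic control", {
  ci <- tiny_inputs(q = 0.01, smr = 1, ages = 0:40, years = 1990:2060)
  totals <- vapply(c(7, 9, 11, 13), function(h) {
    halys_lost(ci, 10, 2000, care = list(mean_hba1c = h), a_max = 40)[["total"]]
  }, numeric(1))
  expect_true(all(diff(totals) > 0))
  expect_true(all(totals >= 0))
})

test_that("the care-level chain feeds the death component through the SMR", {
  ci <- tiny_inputs(q = 0.02, smr = 1, ages = 0:40, years = 1990:2060,
                    income = "HIC", region = "North America")
  reg <- toy_registry(1, intercept = -Inf)
  out_best <- halys_lost(ci, 10, 2000, care = list(mean_hba1c = 7),
                         registry = reg, journeys = NULL, a_max = 40)
  out_min <- halys_lost(ci, 10, 2000, care = list(mean_hba1c = 12),
                        registry = reg, journeys = NULL, a_max = 40)
  expect_gt(out_min[["death"]], out_best[["death"]])
  expect_equal(out_best[["disability"]], 0)
})
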