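#' The eight modelled long-term complications
#'
#' Complication occurrence is modelled as a conditionally independent annual
#' de-novo event per complication, given glycaemic control: the annual
#' hazard is a logistic function of mean HbA1c and diabetes duration, and
#' complications persist once acquired. The registry fixes the eight
#' complication names; the hazard coefficients (log-odds scale) and
#' disability weights are configuration inputs with plausible defaults, to
#' be replaced by published cohort fits where available.
#'
#' @return data frame with columns `name`, `intercept`, `hba1c_coef`,
#'   `duration_coef`, `disability_weight`, `persistent`.
#' @export
default_complication_registry <- function() {
  data.frame(
    name = c("distal symmetric polyneuropathy", "ulcer or amputation",
             "hypertension or microalbuminuria", "overt nephropathy",
             "proliferative retinopathy", "blindness",
             "non-fatal myocardial infarction",
             "non-fatal cerebrovascular disease"),
    intercept = c(-7.2, -9.5, -6.8, -9.0, -8.0, -10.5, -9.8, -10.2),
    hba1c_coef = c(0.38, 0.40, 0.35, 0.42, 0.45, 0.40, 0.30, 0.30),
    duration_coef = c(0.05, 0.06, 0.04, 0.06, 0.07, 0.06, 0.07, 0.07),
    disability_weight = c(0.13, 0.20, 0.05, 0.25, 0.08, 0.19, 0.08, 0.32),
    persistent = TRUE)
}

#' Default impermissible journeys
#'
#' Two de-novo transitions are disallowed: proliferative retinopathy in an
#' already blind individual, and hypertension/microalbuminuria in an
#' individual with overt nephropathy.
#'
#' @return data frame with columns `blocker`, `blocked`.
#' @export
default_impermissible_journeys <- function() {
  data.frame(blocker = c("blindness", "overt nephropathy"),
             blocked = c("proliferative retinopathy",
                         "hypertension or microalbuminuria"))
}

#' Annual de-novo hazard of one complication
#'
#' Inverse-logit of `intercept + hba1c_coef * hba1c + duration_coef *
#' duration`. Durations beyond `max_duration` (default 30 years, the horizon
#' of the underlying cohort evidence) reuse the `max_duration` hazard under
#' the default `"hold"` extrapolation; `"zero"` switches the hazard off
#' beyond the horizon.
#'
#' @param spec one row of the complication registry.
#' @param hba1c mean HbA1c, percent.
#' @param duration years since diagnosis (>= 0), possibly a vector.
#' @param max_duration evidence horizon, default 30.
#' @param extrapolation `"hold"` or `"zero"`.
#' @return probability in (0, 1).
#' @export
annual_hazard <- function(spec, hba1c, duration, max_duration = 30,
                          extrapolation = c("hold", "zero")) {
  extrapolation <- match.arg(extrapolation)
  if (any(duration < 0)) stop_validation("duration must be >= 0")
  d <- pmin(duration, max_duration)
  h <- stats::plogis(spec$intercept + spec$hba1c_coef * hba1c +
                     spec$duration_coef * d)
  if (extrapolation == "zero") h[duration > max_duration] <- 0
  h
}

#' Joint complication prevalence by duration of diabetes
#'
#' Forward recursion over the joint state space of the registry's
#' complications (at most 2^8 = 256 states). Each model year, every absent
#' complication occurs independently with its annual hazard unless an
#' impermissible journey blocks it (the blocker being present); acquired
#' complications persist. Returns the joint distribution and its
#' per-complication marginals at every duration 0..D, with duration 0 the
#' complication-free start.
#'
#' @param registry complication registry (see
#'   [default_complication_registry()]).
#' @param journeys impermissible journeys, data frame `(blocker, blocked)`;
#'   `NULL` for none.
#' @param hba1c mean HbA1c, percent.
#' @param D number of duration years to follow (>= 1).
#' @param max_duration,extrapolation passed to [annual_hazard()].
#' @return list with `joint` (matrix `(D+1) x n_states`), `marginals`
#'   (matrix `(D+1) x n_complications`), `state_masks`, `names`.
#' @export
prevalence_profile <- function(registry, journeys = default_impermissible_journeys(),
                               hba1c, D, max_duration = 30,
                               extrapolation = "hold") {
  if (D < 1) stop_validation("D must be >= 1")
  K <- nrow(registry)
  if (K > 12) stop_validation("state space too large (%d complications)", K)
  nm <- registry$name
  nstate <- 2L^K
  bits <- 2L^(0:(K - 1L))
  block_mask <- integer(K)  # block_mask[c]: states blocking de-novo c
  if (!is.null(journeys) && nrow(journeys)) {
    for (i in seq_len(nrow(journeys))) {
      b <- match(journeys$blocker[i], nm); v <- match(journeys$blocked[i], nm)
      if (is.na(b) || is.na(v))
        stop_validation("journey names must match the registry")
      if (b == v) stop_validation("a complication cannot block itself")
      block_mask[v] <- bitwOr(block_mask[v], bits[b])
    }
  }
  # Occurrences are independent given the start-of-year state, so the yearly
  # transition factorises into one vectorised pass per complication. Passes
  # run with blocked complications before their blockers, so that a blocker's
  # bit in the evolving state still reflects the start of the year when the
  # blocked complication's pass reads it.
  ord <- seq_len(K)
  if (any(block_mask > 0L)) {
    prec <- lapply(seq_len(K), function(c)           # c must come after these
      which(bitwAnd(block_mask, bits[c]) > 0L))      # i.e. after all v blocked by c
    ord <- integer(0); left <- seq_len(K)
    while (length(left)) {
      ready <- left[vapply(left, function(c) all(prec[[c]] %in% ord), logical(1))]
      if (!length(ready))
        stop_validation("impermissible journeys form a cycle")
      ord <- c(ord, ready); left <- setdiff(left, ready)
    }
  }
  states <- 0:(nstate - 1L)
  joint <- matrix(0, D + 1L, nstate)
  joint[1L, 1L] <- 1
  p <- numeric(nstate); p[1L] <- 1
  can_occur <- lapply(seq_len(K), function(c)
    which(bitwAnd(states, bits[c]) == 0L & bitwAnd(states, block_mask[c]) == 0L))
  for (t in seq_len(D)) {
    h <- vapply(seq_len(K), function(c)
      annual_hazard(registry[c, ], hba1c, t - 1L, max_duration, extrapolation),
      numeric(1))
    for (c in ord) {
      idx <- can_occur[[c]]
      move <- p[idx] * h[c]
      p[idx] <- p[idx] - move
      tgt <- idx + bits[c]
      p[tgt] <- p[tgt] + move
    }
    joint[t + 1L, ] <- p
  }
  marg <- sapply(seq_len(K), function(c)
    joint %*% as.numeric(bitwAnd(0:(nstate - 1L), bits[c]) > 0L))
  colnames(marg) <- nm
  list(joint = joint, marginals = marg, state_masks = 0:(nstate - 1L),
       names = nm)
}

# expected disability weight of each joint state
state_disability_weights <- function(registry, state_masks,
                                     combine = c("multiplicative", "additive")) {
  combine <- match.arg(combine)
  K <- nrow(registry); bits <- 2L^(0:(K - 1L))
  vapply(state_masks, function(s) {
    w <- registry$disability_weight[bitwAnd(s, bits) > 0L]
    if (!length(w)) return(0)
    if (combine == "multiplicative") 1 - prod(1 - w) else min(1, sum(w))
  }, numeric(1))
}

#' Healthy life years lost at onset, split by death and disability
#'
#' The two-stage computation: a care level fixes a mean HbA1c, which maps to
#' an SMR feeding the Markov survival of a person diagnosed at
#' `(onset_age, onset_year)`; complication prevalence by duration then
#' weights each survived person-year by the expected disability of the
#' joint complication state. HALYs lost are reported as
#' `death + disability`, where the death component is the shortfall of the
#' model life expectancy against the background reference, and the
#' disability component is the disability-weighted sum of survived
#' person-years (weights combined multiplicatively across coexisting
#' complications on the joint distribution).
#'
#' @param inputs a [country_inputs()] bundle (for background mortality and
#'   the non-diagnosis schedule).
#' @param onset_age,onset_year age and year of diagnosis.
#' @param care one row of [default_care_levels()] (or any list with
#'   `mean_hba1c`).
#' @param registry,journeys complication model configuration.
#' @param hba1c_smr_knots knot table for [smr_from_hba1c()].
#' @param a_max terminal age.
#' @param combine disability combination rule across coexisting
#'   complications, `"multiplicative"` (default) or `"additive"` (capped at
#'   1).
#' @return named numeric vector `c(total = , death = , disability = )`, in
#'   years.
#' @export
halys_lost <- function(inputs, onset_age, onset_year,
                       care = default_care_levels()[2, ],
                       registry = default_complication_registry(),
                       journeys = default_impermissible_journeys(),
                       hba1c_smr_knots = default_hba1c_smr_knots(),
                       a_max = 99L, combine = "multiplicative") {
  hba1c <- care$mean_hba1c
  smr <- smr_from_hba1c(hba1c_smr_knots, hba1c)
  tr <- survival_trace(inputs, onset_age, onset_year, a_max,
                       smr_override = smr)
  le_model <- tr$nondx_at_onset * 0.5 +
    (1 - tr$nondx_at_onset) * sum(tr$person_years)
  le_ref <- background_life_expectancy(inputs, onset_age, onset_year, a_max)
  death <- le_ref - le_model

  D <- length(tr$duration) - 1L
  prof <- prevalence_profile(registry, journeys, hba1c, max(1L, D))
  sw <- state_disability_weights(registry, prof$state_masks, combine)
  dw_by_duration <- as.vector(prof$joint %*% sw)   # index 1 = duration 0
  py <- (1 - tr$nondx_at_onset) * tr$person_years
  disability <- sum(py * dw_by_duration[seq_along(py)])
  c(total = death + disability, death = death, disability = disability)
}
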