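# Shared fixtures and independent oracles, built in code at test time.

# A small fully constant country: every surface flat over the grid.
tiny_inputs <- function(ages = 0:19, years = 1990:2010,
                        inc = 100, q = 0.01, smr = 3,
                        nondx = NULL, births = 1000,
                        region = "South Asia", income = "LMIC") {
  mk <- function(v, unit) age_year_surface(v, ages = ages, years = years,
                                           unit = unit)
  nd <- if (is.null(nondx)) NULL else mk(nondx, "probability")
  suppressWarnings(country_inputs(
    "toy", region, income,
    population = mk(births, "persons"),
    background_mortality = mk(q, "probability"),
    incidence = mk(inc, "per100k_py"),
    smr = mk(smr, "dimensionless"),
    nondx = nd))
}

# Per-individual Monte-Carlo microsimulation of one birth cohort under the
# same rates as the Markov engine; the independent stochastic oracle.
# Returns end-of-age state counts per age plus the per-age flow of new
# diagnoses.
microsim_cohort <- function(inputs, birth_year, n, a_max, seed, absorb = TRUE) {
  set.seed(seed)
  state <- rep(0L, n)  # 0 susceptible, 1 diagnosed, 2 dead@onset, 3 dead bg, 4 dead after dx
  out <- data.frame(age = 0:a_max, alive_no_t1d = NA_real_,
                    alive_dx = NA_real_, dead_onset = NA_real_,
                    dead_bg = NA_real_, dead_dx = NA_real_, new_dx = NA_real_)
  for (a in 0:a_max) {
    y <- birth_year + a
    p_onset <- min(1, ays_value(inputs$incidence, a, y) / 1e5)
    q <- ays_value(inputs$background_mortality, a, y)
    if (absorb && a == a_max) q <- 1
    smr <- ays_value(inputs$smr, a, y)
    ndx <- t1dsim:::get_nondx(inputs, y, a)
    qd <- min(1, 1 - (1 - q)^smr)
    onset <- state == 0L & stats::runif(n) < p_onset
    die_onset <- onset & stats::runif(n) < ndx
    state[onset] <- 1L
    state[die_onset] <- 2L
    bg <- state == 0L & stats::runif(n) < q
    state[bg] <- 3L
    dd <- state == 1L & stats::runif(n) < qd
    new_dx <- sum(onset & !die_onset)
    state[dd] <- 4L
    out[a + 1, 2:7] <- c(sum(state == 0L), sum(state == 1L), sum(state == 2L),
                         sum(state == 3L), sum(state == 4L), new_dx)
  }
  out
}

# binomial 3-standard-error band for a count out of n at proportion p
within_3se <- function(count, n, p) {
  se <- sqrt(n * p * (1 - p))
  abs(count - n * p) <= 3 * max(se, 1e-12)
}

# Exhaustive path-enumeration oracle for the joint complication recursion:
# per year, loop over start states and all subsets of the allowed de-novo
# events. Deliberately the slow, obvious implementation.
brute_profile <- function(registry, journeys, hba1c, D, start = 0) {
  K <- nrow(registry)
  nm <- registry$name
  nstate <- 2^K
  bits <- 2^(0:(K - 1))
  p <- rep(0, nstate); p[start + 1] <- 1
  joint <- matrix(0, D + 1, nstate)
  joint[1, start + 1] <- 1
  for (t in 1:D) {
    h <- stats::plogis(registry$intercept + registry$hba1c_coef * hba1c +
                       registry$duration_coef * min(t - 1, 30))
    pn <- rep(0, nstate)
    for (s in 0:(nstate - 1)) {
      if (p[s + 1] == 0) next
      present <- bitwAnd(s, bits) > 0
      blocked <- vapply(seq_len(K), function(c) {
        if (is.null(journeys) || !nrow(journeys)) return(FALSE)
        any(present[match(journeys$blocker[journeys$blocked == nm[c]], nm)])
      }, logical(1))
      allowed <- which(!present & !blocked)
      L <- length(allowed)
      if (L == 0) { pn[s + 1] <- pn[s + 1] + p[s + 1]; next }
      for (sub in 0:(2^L - 1)) {
        occ <- bitwAnd(sub, 2^(0:(L - 1))) > 0
        pr <- prod(ifelse(occ, h[allowed], 1 - h[allowed]))
        ns <- s + sum(bits[allowed[occ]])
        pn[ns + 1] <- pn[ns + 1] + p[s + 1] * pr
      }
    }
    p <- pn
    joint[t + 1, ] <- p
  }
  joint
}

# small registry builder for complication tests
toy_registry <- function(K, intercept = -4, hcoef = 0.3, dcoef = 0.05,
                         weight = 0.2) {
  reg <- default_complication_registry()[seq_len(K), ]
  reg$intercept <- rep_len(intercept, K)
  reg$hba1c_coef <- rep_len(hcoef, K)
  reg$duration_coef <- rep_len(dcoef, K)
  reg$disability_weight <- rep_len(weight, K)
  reg
}
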