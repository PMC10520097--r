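#' Bounding historical diagnosis rates from observed incidence changes
#'
#' In settings where many onsets are never diagnosed, a rapid rise in
#' *observed* incidence can reflect improving diagnosis rather than rising
#' true incidence: the ratio of observed incidences equals the ratio of
#' true incidences multiplied by the ratio of diagnosis rates. These
#' helpers decompose an observed incidence ratio accordingly and bound the
#' baseline diagnosis rate. The canonical use is the Mali series, where
#' observed incidence under age 25 rose from 0.12 to 0.74 per 100,000
#' between 2007 and 2016.
#'
#' @param i0,i1 observed incidence per 100,000 at the start and end year
#'   (both > 0).
#' @return `observed_ratio()`: the ratio `i1 / i0`.
#' @examples
#' observed_ratio(0.12, 0.74)                    # 6.17 -> printed as 6.2
#' implied_annual_growth(0.74 / 0.12, 9)         # 0.224
#' true_ratio(0.07, 9)                           # 1.84 -> printed as 1.8
#' diagnosis_rate_ratio(6.2, 1.8)                # 3.44
#' baseline_diagnosis_rate(3.44, 1)              # about 0.30
#' @name diagnosis_inference
NULL

#' @rdname diagnosis_inference
#' @export
observed_ratio <- function(i0, i1) {
  if (i0 <= 0)
    stop_validation(paste0("i0 must be > 0: a zero observed incidence usually ",
                           "means onsets are fully masked by non-diagnosis"))
  if (i1 <= 0) stop_validation("i1 must be > 0")
  i1 / i0
}

#' @rdname diagnosis_inference
#' @param ratio an incidence ratio (> 0).
#' @param n_years elapsed years between the two observations (>= 1).
#' @return `implied_annual_growth()`: the constant annual growth rate (as a
#'   proportion per year) that compounds to `ratio` over `n_years`.
#' @export
implied_annual_growth <- function(ratio, n_years) {
  if (ratio <= 0) stop_validation("ratio must be > 0")
  if (n_years < 1) stop_validation("n_years must be >= 1")
  ratio^(1 / n_years) - 1
}

#' @rdname diagnosis_inference
#' @param apc assumed true annual incidence growth, proportion per year
#'   (> -1).
#' @return `true_ratio()`: `(1 + apc)^n_years`.
#' @export
true_ratio <- function(apc, n_years) {
  if (apc <= -1) stop_validation("apc must be > -1")
  (1 + apc)^n_years
}

#' @rdname diagnosis_inference
#' @param observed,true_r observed and assumed-true incidence ratios (> 0).
#' @return `diagnosis_rate_ratio()`: `observed / true_r`, the implied ratio
#'   of end-year to start-year diagnosis rates. A value below 1 (observed
#'   growth slower than assumed true growth) is returned with a
#'   "diagnosis deterioration" warning.
#' @export
diagnosis_rate_ratio <- function(observed, true_r) {
  if (observed <= 0 || true_r <= 0) stop_validation("ratios must be > 0")
  out <- observed / true_r
  if (out < 1)
    warn_t1dsim("diagnosis deterioration: implied diagnosis-rate ratio %.3f < 1",
                out, class = "t1dsim_dx_deterioration")
  out
}

#' @rdname diagnosis_inference
#' @param dx_ratio implied diagnosis-rate ratio (end vs start).
#' @param final_rate assumed diagnosis rate at the end year, in (0, 1\];
#'   with `final_rate = 1` the result is an upper bound on the baseline
#'   rate.
#' @return `baseline_diagnosis_rate()`: `final_rate / dx_ratio`.
#' @export
baseline_diagnosis_rate <- function(dx_ratio, final_rate = 1) {
  if (final_rate <= 0 || final_rate > 1)
    stop_validation("final_rate must lie in (0, 1]")
  out <- final_rate / dx_ratio
  if (out > 1)
    stop_validation("inconsistent inputs: implied baseline diagnosis rate %.3f > 1", out)
  out
}

#' Run the whole diagnosis-rate decomposition
#'
#' Chains the five steps on unrounded values and reports both the
#' unrounded chain and the conventionally printed one (ratios at one
#' decimal, growth in percent at one decimal, baseline rate as a whole
#' percent). The elapsed time is the calendar difference `y1 - y0`.
#'
#' @param i0,i1 observed incidence per 100,000 at years `y0` and `y1`.
#' @param y0,y1 observation years, `y1 > y0`.
#' @param true_apc assumed true annual incidence growth (proportion/yr),
#'   default 0.07.
#' @param final_rate assumed diagnosis rate at `y1`, default 1.
#' @return list with `unrounded` and `printed` chains.
#' @examples
#' diagnosis_chain(0.12, 2007, 0.74, 2016)$printed
#' @export
diagnosis_chain <- function(i0, y0, i1, y1, true_apc = 0.07, final_rate = 1) {
  if (y1 <= y0) stop_validation("y1 must be after y0")
  n <- y1 - y0
  obs <- observed_ratio(i0, i1)
  growth <- implied_annual_growth(obs, n)
  tr <- true_ratio(true_apc, n)
  dxr <- diagnosis_rate_ratio(obs, tr)
  base <- baseline_diagnosis_rate(dxr, final_rate)
  list(n_years = n,
       unrounded = list(observed_ratio = obs,
                        implied_annual_growth = growth,
                        true_ratio = tr,
                        diagnosis_rate_ratio = dxr,
                        baseline_diagnosis_rate = base),
       printed = list(observed_ratio = round(obs, 1),
                      implied_annual_growth_pct = round(100 * growth, 1),
                      true_ratio = round(tr, 1),
                      diagnosis_rate_ratio = round(round(obs, 1) / round(tr, 1), 1),
                      baseline_diagnosis_rate_pct = round(100 * base)))
}
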