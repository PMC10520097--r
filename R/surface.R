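#' Age-by-year surfaces
#'
#' An `age_year_surface` is the engine's carrier for any quantity indexed by
#' completed age and calendar year: population counts, incidence rates per
#' 100,000 person-years, annual death probabilities, or dimensionless
#' standardised mortality ratios (SMRs). It is a dense numeric matrix (ages in
#' rows, years in columns) tagged with a unit, and is required to be
#' rectangular: every (age, year) cell on the declared grid holds a
#' non-negative value.
#'
#' @param values numeric matrix with `length(ages)` rows and `length(years)`
#'   columns, or a single number recycled over the whole grid, or a function
#'   `f(age, year)` evaluated on the grid (vectorised over age).
#' @param ages integer vector of completed ages, default `0:99`.
#' @param years integer vector of calendar years (consecutive).
#' @param unit one of `"persons"`, `"per100k_py"`, `"probability"`,
#'   `"dimensionless"`. Probabilities must lie in \[0, 1\].
#' @return an object of class `age_year_surface`.
#' @examples
#' q <- age_year_surface(0.01, years = 2000:2010, unit = "probability")
#' ays_value(q, age = 50, year = 2005)
#' @export
age_year_surface <- function(values, ages = 0:99, years,
                             unit = c("persons", "per100k_py", "probability",
                                      "dimensionless")) {
  unit <- match.arg(unit)
  ages <- as.integer(ages)
  years <- as.integer(years)
  if (is.function(values)) {
    values <- outer(ages, years, values)
  }
  if (length(values) == 1L) {
    values <- matrix(as.numeric(values), length(ages), length(years))
  }
  if (!is.matrix(values) || nrow(values) != length(ages) ||
      ncol(values) != length(years)) {
    stop_validation("surface values must be a %d x %d matrix (ages x years)",
                    length(ages), length(years))
  }
  if (anyNA(values)) {
    stop_validation("surface contains missing cells; the grid must be rectangular")
  }
  if (any(values < 0)) {
    stop_validation("surface values must be non-negative")
  }
  if (unit == "probability" && any(values > 1)) {
    stop_validation("probability surface has values > 1")
  }
  dimnames(values) <- list(age = ages, year = years)
  structure(values, ages = ages, years = years, unit = unit,
            class = c("age_year_surface", "matrix", "array"))
}

#' @export
print.age_year_surface <- function(x, ...) {
  a <- attr(x, "ages"); y <- attr(x, "years")
  cat(sprintf("<age_year_surface> %s, ages %d-%d, years %d-%d, range [%g, %g]\n",
              attr(x, "unit"), min(a), max(a), min(y), max(y),
              min(x), max(x)))
  invisible(x)
}

surface_ages <- function(s) attr(s, "ages")
surface_years <- function(s) attr(s, "years")
surface_unit <- function(s) attr(s, "unit")

#' Look up surface cells
#'
#' @param s an [age_year_surface()].
#' @param age,year integer scalars or vectors of equal length.
#' @param clamp if `TRUE`, ages and years outside the grid are clamped to the
#'   nearest covered value (last-value carry-forward beyond the data horizon,
#'   used when following recent-onset cohorts past the last data year). If
#'   `FALSE` (default) an out-of-grid query is a coverage error.
#' @param context optional label (e.g. a country id) included in coverage
#'   error messages.
#' @return numeric vector of cell values.
#' @export
ays_value <- function(s, age, year, clamp = FALSE, context = NULL) {
  ages <- attr(s, "ages"); years <- attr(s, "years")
  if (clamp) {
    age <- pmin(pmax(age, min(ages)), max(ages))
    year <- pmin(pmax(year, min(years)), max(years))
  }
  i <- match(age, ages); j <- match(year, years)
  if (anyNA(i) || anyNA(j)) {
    bad <- which(is.na(i) | is.na(j))[1L]
    stop_coverage("input coverage: no %s value for %sage %s, year %s",
                  attr(s, "unit"),
                  if (is.null(context)) "" else paste0(context, ", "),
                  age[bad], year[bad])
  }
  s[cbind(i, j)]
}

#' Extend a surface through later (or earlier) years by carrying edge values
#'
#' @param s an [age_year_surface()].
#' @param to_year extend the year grid to include this year.
#' @return a surface on the widened year grid.
#' @export
ays_extend <- function(s, to_year) {
  years <- attr(s, "years")
  if (to_year >= min(years) && to_year <= max(years)) return(s)
  if (to_year > max(years)) {
    extra <- (max(years) + 1L):to_year
    vals <- cbind(unclass(s)[, , drop = FALSE],
                  matrix(s[, ncol(s)], nrow(s), length(extra)))
    yrs <- c(years, extra)
  } else {
    extra <- to_year:(min(years) - 1L)
    vals <- cbind(matrix(s[, 1L], nrow(s), length(extra)),
                  unclass(s)[, , drop = FALSE])
    yrs <- c(extra, years)
  }
  age_year_surface(vals, ages = attr(s, "ages"), years = yrs,
                   unit = attr(s, "unit"))
}

#' @export
as.data.frame.age_year_surface <- function(x, ...) {
  data.frame(age = rep(attr(x, "ages"), times = ncol(x)),
             year = rep(attr(x, "years"), each = nrow(x)),
             value = as.vector(unclass(x)))
}
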