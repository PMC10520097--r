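#' Packaged country-estimate and minimal-care tables
#'
#' Two published summary tables ship with the package as plain CSV,
#' transcribed from their source rendering into clean columns (country
#' names were fused with the numbers there; borrowed-country annotations
#' such as "2009 (Uzbekistan)" became a `source_country` field, and
#' parenthesised entries in the percent-difference column decode as
#' negative). `load_table1_fixture()` returns the per-country 2021
#' prevalence/incidence estimates with the IDF Atlas comparison;
#' `load_table2_fixture()` returns the counts of people under 25 receiving
#' minimal care by region and income group. Rows with transcription
#' ambiguity in the source carry a `note`. File checksums are verified on
#' load.
#'
#' @return data frames; see column names.
#' @export
load_table1_fixture <- function() {
  read_fixture("table1_country_estimates.csv",
               "874ba5f3479593a6009f937501198269")
}

#' @rdname load_table1_fixture
#' @export
load_table2_fixture <- function() {
  read_fixture("table2_minimal_care.csv",
               "8d247532a7cd569cc0882eeab6e0da8a")
}

read_fixture <- function(file, md5) {
  path <- system.file("extdata", file, package = "t1dsim")
  if (path == "" || !file.exists(path))
    stop_integrity("packaged fixture '%s' is missing", file)
  got <- unname(tools::md5sum(path))
  if (!identical(got, md5))
    stop_integrity("fixture '%s' failed its checksum (got %s)", file, got)
  utils::read.csv(path)
}

#' Internal-consistency checks on the packaged tables
#'
#' Three families of checks, all recomputable from the shipped CSVs alone:
#'
#' * Atlas comparison. Per country, the percent by which the Atlas
#'   incidence estimate differs from the index estimate. Two summaries are
#'   reported: the median percent by which the Atlas estimate is lower
#'   than the index estimate, `(index - atlas) / index * 100`, over
#'   countries with their own Atlas data (the headline comparison), and
#'   the median of the per-row column convention
#'   `(index - atlas) / atlas * 100` over all rows.
#' * Per-row recomputation. The printed percent-difference column is
#'   recomputed from the incidence columns. Because the printed column was
#'   evidently derived from unrounded rates, each row's tolerance is the
#'   propagated half-ulp of the two one-decimal columns (never below 1
#'   point); rows outside that band are flagged.
#' * Minimal-care totals. Regional counts and income-group counts are
#'   summed and compared with the printed global total.
#'
#' @param table1,table2 data frames as returned by the loaders.
#' @return list of class `t1d_table_checks` with components
#'   `atlas_median_pct_lower_of_index`, `atlas_median_pct_vs_atlas`,
#'   `rows` (per-row recomputation), `n_rows_flagged`,
#'   `table2_region_sum`, `table2_income_sum`, `table2_printed_total`,
#'   `table2_consistent`.
#' @export
table_checks <- function(table1 = load_table1_fixture(),
                         table2 = load_table2_fixture()) {
  idx <- table1$index_incidence_under15_per100k
  atl <- table1$atlas_incidence_under15_per100k
  own <- is.na(table1$source_country) | table1$source_country == ""
  pct_of_index <- (idx - atl) / idx * 100
  pct_vs_atlas <- (idx - atl) / atl * 100
  # rounding propagation: both columns printed to one decimal (half-ulp 0.05)
  tol <- pmax(1, 100 * 0.05 * (idx + atl) / atl^2)
  rows <- data.frame(country = table1$country,
                     recomputed_pct = pct_vs_atlas,
                     printed_pct = table1$pct_atlas_lower_printed,
                     tolerance = tol,
                     consistent = abs(pct_vs_atlas - table1$pct_atlas_lower_printed) <= tol)
  reg <- table2[table2$group_type == "region", ]
  inc <- table2[table2$group_type == "income", ]
  total <- table2$n_minimal_care[table2$group_type == "global"][1]
  out <- list(
    atlas_median_pct_lower_of_index = stats::median(pct_of_index[own]),
    atlas_median_pct_vs_atlas = stats::median(pct_vs_atlas),
    n_countries = nrow(table1), n_own_atlas = sum(own),
    rows = rows, n_rows_flagged = sum(!rows$consistent),
    table2_region_sum = sum(reg$n_minimal_care),
    table2_income_sum = sum(inc$n_minimal_care),
    table2_printed_total = total)
  out$table2_consistent <- out$table2_region_sum == total &&
    out$table2_income_sum == total
  class(out) <- "t1d_table_checks"
  out
}

#' @export
print.t1d_table_checks <- function(x, ...) {
  cat(sprintf(paste0(
    "<t1d_table_checks> %d countries (%d with own Atlas data)\n",
    "  Atlas lower than index, median %% of index (own data): %.1f%%\n",
    "  median of per-row %% vs Atlas (all rows):              %.1f%%\n",
    "  per-row recomputation: %d/%d rows outside tolerance\n",
    "  minimal care: regions %s, income groups %s, printed total %s -> %s\n"),
    x$n_countries, x$n_own_atlas,
    x$atlas_median_pct_lower_of_index, x$atlas_median_pct_vs_atlas,
    x$n_rows_flagged, nrow(x$rows),
    format(x$table2_region_sum, big.mark = ","),
    format(x$table2_income_sum, big.mark = ","),
    format(x$table2_printed_total, big.mark = ","),
    if (x$table2_consistent) "consistent" else "INCONSISTENT"))
  invisible(x)
}
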