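# Cause-share proportions, percent-change statistics, and summary tables.
#
# Proportions use the all-age number metric (global person-year sums);
# percent changes use age-standardized rates. Everything is computed at full
# precision; present_round() is applied only when printing.

#' Relative change between two values, in percent
#'
#' `100 * (v_end - v_start) / v_start`. The exact negative of
#' [percent_decline()].
#'
#' @param v_start baseline value (> 0).
#' @param v_end final value (>= 0).
#' @return Relative change in percent (positive = increase).
#' @export
#' @examples
#' relative_change(14.78, 17.25)  # 16.71% at 2 dp
relative_change <- function(v_start, v_end) {
  .assert_scalar_number(v_start, "v_start")
  .assert_scalar_number(v_end, "v_end")
  if (v_start < 0 || v_end < 0) stop("values must be non-negative", call. = FALSE)
  if (v_start == 0) {
    stop("relative change is undefined for a zero baseline", call. = FALSE)
  }
  100 * (v_end - v_start) / v_start
}

#' Percent decline between two values
#'
#' `100 * (v_start - v_end) / v_start`, the sign convention used when a
#' burden indicator falls over time.
#'
#' @inheritParams relative_change
#' @return Decline in percent (positive = decrease).
#' @export
#' @examples
#' percent_decline(1492.64, 940.66)  # 36.98% at 2 dp
percent_decline <- function(v_start, v_end) {
  -relative_change(v_start, v_end)
}

#' Ratio of two burden values
#'
#' @param v_a numerator (>= 0).
#' @param v_b denominator (> 0).
#' @return `v_a / v_b`.
#' @export
burden_ratio <- function(v_a, v_b) {
  .assert_scalar_number(v_a, "v_a")
  .assert_scalar_number(v_b, "v_b")
  if (v_a < 0) stop("v_a must be non-negative", call. = FALSE)
  if (v_b <= 0) stop("v_b must be positive", call. = FALSE)
  v_a / v_b
}

#' Cause shares of all-cause burden
#'
#' For each requested cause, the percentage of global all-cause burden it
#' accounts for in one year:
#' `100 * sum_locations number(cause) / sum_locations number(All causes)`,
#' computed from the all-age number metric (person or person-year totals),
#' never from rates.
#'
#' @param panel a `gbd_panel`.
#' @param causes character vector of cause names.
#' @param year calendar year.
#' @param measure `"dalys"` or `"deaths"`.
#' @return Data frame with columns `cause`, `year`, `measure`, `share`
#'   (percent of all-cause burden).
#' @export
cause_proportion <- function(panel, causes, year, measure = "dalys") {
  stopifnot(inherits(panel, "gbd_panel"))
  b <- panel$burden
  base <- b$year == year & b$measure == measure &
    b$metric == "number" & b$age_type == "all_age"
  total_rows <- base & b$cause == "All causes"
  if (!any(total_rows)) {
    stop(sprintf("no 'All causes' number records for year %s, measure %s",
                 year, measure), call. = FALSE)
  }
  total <- sum(b$value[total_rows])
  if (total <= 0) stop("all-cause total is zero", call. = FALSE)
  share <- vapply(causes, function(cs) {
    rows <- base & b$cause == cs
    if (!any(rows)) {
      stop(sprintf("no number records for cause '%s' in year %s", cs, year),
           call. = FALSE)
    }
    100 * sum(b$value[rows]) / total
  }, numeric(1))
  data.frame(cause = causes, year = year, measure = measure,
             share = unname(share), row.names = NULL, stringsAsFactors = FALSE)
}

#' Start/end summary table of group-level rates
#'
#' Builds a published-table-style summary from pre-aggregated group rate rows
#' (Global plus SDI quintile bands): one row per (group, cause, measure) with
#' start and end age-standardized rates, their uncertainty intervals, and
#' both change statistics. Group rows are consumed as given - they are not
#' re-derived by pooling countries, since age-standardized aggregation needs
#' age-specific data this pipeline does not model; [sdi_group_rates()] emits
#' compatible rows for synthetic panels.
#'
#' @param group_rates data frame with columns `group`, `cause`, `measure`,
#'   `year`, `value`, `lower`, `upper` (e.g. from [table1_rates()] or
#'   [sdi_group_rates()]).
#' @param years length-2 vector: start and end year.
#' @param groups,causes,measures optional subsets; default everything present.
#' @return Data frame with one row per (group, cause, measure): start/end
#'   values with UIs, `relative_change`, `percent_decline`.
#' @export
summary_table <- function(group_rates, years, groups = NULL, causes = NULL,
                          measures = NULL) {
  need <- c("group", "cause", "measure", "year", "value", "lower", "upper")
  if (!all(need %in% names(group_rates))) {
    stop(sprintf("group_rates must have columns: %s", paste(need, collapse = ", ")),
         call. = FALSE)
  }
  if (length(years) != 2) stop("years must be a start/end pair", call. = FALSE)
  if (is.null(groups)) groups <- unique(group_rates$group)
  if (is.null(causes)) causes <- unique(group_rates$cause)
  if (is.null(measures)) measures <- unique(group_rates$measure)

  cell <- function(g, cs, ms, yr) {
    row <- group_rates[group_rates$group == g & group_rates$cause == cs &
                         group_rates$measure == ms & group_rates$year == yr, ]
    if (nrow(row) == 0) {
      stop(sprintf("missing cell: group='%s' cause='%s' measure='%s' year=%s",
                   g, cs, ms, yr), call. = FALSE)
    }
    row[1, c("value", "lower", "upper")]
  }

  grid <- expand.grid(group = groups, cause = causes, measure = measures,
                      stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid$group[i]; cs <- grid$cause[i]; ms <- grid$measure[i]
    s <- cell(g, cs, ms, years[1]); e <- cell(g, cs, ms, years[2])
    data.frame(group = g, cause = cs, measure = ms,
               year_start = years[1], year_end = years[2],
               value_start = s$value, lower_start = s$lower, upper_start = s$upper,
               value_end = e$value, lower_end = e$lower, upper_end = e$upper,
               relative_change = relative_change(s$value, e$value),
               percent_decline = percent_decline(s$value, e$value),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Published GBD 2021 group rates for neoplasms and COPD
#'
#' Returns the transcribed published age-standardized death and DALY rates
#' (per 100,000, with 95% uncertainty intervals) for neoplasms and chronic
#' obstructive pulmonary disease, globally and by SDI quintile band, in 1990
#' and 2021, as estimated by the GBD 2021 study. Shipped as a plain-text
#' fixture so the exact worked examples in the test suite run offline.
#'
#' @return Data frame in [summary_table()] input shape: `group`, `cause`,
#'   `measure`, `year`, `value`, `lower`, `upper`.
#' @export
table1_rates <- function() {
  path <- system.file("extdata", "table1_gbd2021.csv", package = "fibroburden",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
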