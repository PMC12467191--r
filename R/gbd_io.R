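# Readers and validators for GBD-results-tool style CSV exports.
#
# All tables are plain UTF-8 RFC-4180 CSV with a header row. Column names are
# mapped through a configurable "dialect" so exports with renamed headers can
# be ingested without editing files; unknown extra columns are ignored.

#' Column dialect for GBD-style CSV files
#'
#' Maps the logical columns the pipeline needs onto the header names found in
#' a CSV export. The defaults match the GBD results-tool export format
#' (`measure_name`, `location_name`, `cause_name`, `metric_name`, `age_name`,
#' `year`, `val`, `upper`, `lower`).
#'
#' @param location,year,cause,measure,metric,age,value,lower,upper header
#'   names for the corresponding logical columns of a burden table.
#' @param location_id optional header carrying a numeric location id; `NA` if
#'   absent.
#' @param sdi header for the SDI value column (SDI tables only).
#' @param population header for the population column (population tables only).
#' @return A named list of class `gbd_dialect`.
#' @export
#' @examples
#' gbd_dialect()                      # results-tool defaults
#' gbd_dialect(location = "country")  # renamed location header
gbd_dialect <- function(location = "location_name", year = "year",
                        cause = "cause_name", measure = "measure_name",
                        metric = "metric_name", age = "age_name",
                        value = "val", lower = "lower", upper = "upper",
                        location_id = "location_id",
                        sdi = "sdi", population = "population") {
  structure(list(location = location, year = year, cause = cause,
                 measure = measure, metric = metric, age = age,
                 value = value, lower = lower, upper = upper,
                 location_id = location_id, sdi = sdi,
                 population = population),
            class = "gbd_dialect")
}

# read a CSV and check that the dialect's required logical columns are present
.read_mapped_csv <- function(path, dialect, required) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                         colClasses = "character", fileEncoding = "UTF-8")
  for (logical_name in required) {
    header <- dialect[[logical_name]]
    if (is.null(header) || is.na(header) || !header %in% names(raw)) {
      stop(sprintf("required column `%s` (logical field '%s') is missing from %s",
                   header, logical_name, path), call. = FALSE)
    }
  }
  raw
}

# strict decimal parser: rejects thousands separators and non-numeric tokens
.parse_numeric <- function(x, column, allow_na = FALSE) {
  x <- trimws(x)
  bad_sep <- grepl(",", x, fixed = TRUE)
  if (any(bad_sep)) {
    stop(sprintf("column `%s`: value '%s' at row %d contains a grouping separator; plain decimals required",
                 column, x[which(bad_sep)[1]], which(bad_sep)[1]), call. = FALSE)
  }
  out <- suppressWarnings(as.numeric(x))
  bad <- is.na(out) & !(allow_na & (is.na(x) | x == ""))
  if (any(bad)) {
    stop(sprintf("column `%s`: non-numeric value '%s' at row %d",
                 column, x[which(bad)[1]], which(bad)[1]), call. = FALSE)
  }
  out
}

# canonical measure / metric / age labels; tolerant of results-tool spellings
.canon_measure <- function(x) {
  key <- tolower(trimws(x))
  out <- rep(NA_character_, length(key))
  out[key %in% c("deaths", "death")] <- "deaths"
  out[grepl("^dalys", key)] <- "dalys"
  out
}

.canon_metric <- function(x) {
  key <- tolower(trimws(x))
  out <- rep(NA_character_, length(key))
  out[key == "rate"] <- "rate"
  out[key == "number"] <- "number"
  out[key == "percent"] <- "percent"
  out
}

.canon_age <- function(x) {
  key <- tolower(trimws(x))
  key <- gsub("[ _-]", "", key)
  out <- rep(NA_character_, length(key))
  out[key %in% c("agestandardized", "agestd")] <- "age_standardized"
  out[key %in% c("allages", "allage")] <- "all_age"
  out
}

#' Read a burden estimate table
#'
#' Reads a GBD-style CSV of location-year-cause burden estimates into the
#' pipeline's canonical record layout, validating every row. Rows whose
#' measure, metric, or age-group labels are not recognised are rejected with
#' their row numbers, as are rows violating the record invariants
#' (`lower <= value <= upper`, percent values within \[0, 100\], year within
#' `year_span`).
#'
#' @param path path to a CSV file.
#' @param dialect a [gbd_dialect()] mapping logical columns to headers.
#' @param year_span closed integer interval of admissible calendar years.
#' @return A data frame with columns `location`, `location_id`, `year`,
#'   `cause`, `measure` (`"deaths"`/`"dalys"`), `metric`
#'   (`"rate"`/`"number"`/`"percent"`), `age_type`
#'   (`"age_standardized"`/`"all_age"`), `value`, `ui_lower`, `ui_upper`.
#' @export
read_burden_csv <- function(path, dialect = gbd_dialect(),
                            year_span = c(1990L, 2021L)) {
  required <- c("location", "year", "cause", "measure", "metric", "age",
                "value", "lower", "upper")
  raw <- .read_mapped_csv(path, dialect, required)
  n <- nrow(raw)
  if (n == 0L) stop(sprintf("no data rows in %s", path), call. = FALSE)

  measure <- .canon_measure(raw[[dialect$measure]])
  if (anyNA(measure)) {
    i <- which(is.na(measure))[1]
    stop(sprintf("row %d: unmapped measure '%s'", i, raw[[dialect$measure]][i]),
         call. = FALSE)
  }
  metric <- .canon_metric(raw[[dialect$metric]])
  if (anyNA(metric)) {
    i <- which(is.na(metric))[1]
    stop(sprintf("row %d: unmapped metric '%s'", i, raw[[dialect$metric]][i]),
         call. = FALSE)
  }
  age_type <- .canon_age(raw[[dialect$age]])
  if (anyNA(age_type)) {
    i <- which(is.na(age_type))[1]
    stop(sprintf("row %d: unmapped age group '%s'", i, raw[[dialect$age]][i]),
         call. = FALSE)
  }

  year <- .parse_numeric(raw[[dialect$year]], dialect$year)
  value <- .parse_numeric(raw[[dialect$value]], dialect$value)
  lower <- .parse_numeric(raw[[dialect$lower]], dialect$lower)
  upper <- .parse_numeric(raw[[dialect$upper]], dialect$upper)

  loc_id <- if (!is.na(dialect$location_id) &&
                dialect$location_id %in% names(raw)) {
    .parse_numeric(raw[[dialect$location_id]], dialect$location_id,
                   allow_na = TRUE)
  } else {
    rep(NA_real_, n)
  }

  bad <- which(year != round(year) | year < year_span[1] | year > year_span[2])
  if (length(bad)) {
    stop(sprintf("row %d: year %s outside span [%d, %d]",
                 bad[1], format(year[bad[1]]), year_span[1], year_span[2]),
         call. = FALSE)
  }
  bad <- which(value < 0 | lower < 0 | upper < 0)
  if (length(bad)) {
    stop(sprintf("row %d: negative burden value", bad[1]), call. = FALSE)
  }
  bad <- which(lower > value | value > upper)
  if (length(bad)) {
    stop(sprintf("row %d: uncertainty interval violated (lower %.6g, value %.6g, upper %.6g)",
                 bad[1], lower[bad[1]], value[bad[1]], upper[bad[1]]),
         call. = FALSE)
  }
  bad <- which(metric == "percent" & value > 100)
  if (length(bad)) {
    stop(sprintf("row %d: percent value %.6g exceeds 100", bad[1], value[bad[1]]),
         call. = FALSE)
  }

  data.frame(location = trimws(raw[[dialect$location]]),
             location_id = loc_id,
             year = as.integer(year),
             cause = trimws(raw[[dialect$cause]]),
             measure = measure, metric = metric, age_type = age_type,
             value = value, ui_lower = lower, ui_upper = upper,
             stringsAsFactors = FALSE)
}

#' Read an SDI table
#'
#' @param path path to a CSV with location, year, and SDI columns.
#' @param dialect a [gbd_dialect()]; uses its `location`, `year`, `sdi` fields.
#' @return A data frame with columns `location`, `year`, `sdi` (in \[0, 1\]).
#' @export
read_sdi_csv <- function(path, dialect = gbd_dialect()) {
  raw <- .read_mapped_csv(path, dialect, c("location", "year", "sdi"))
  if (nrow(raw) == 0L) stop(sprintf("no data rows in %s", path), call. = FALSE)
  sdi <- .parse_numeric(raw[[dialect$sdi]], dialect$sdi)
  bad <- which(sdi < 0 | sdi > 1)
  if (length(bad)) {
    stop(sprintf("row %d: SDI %.6g outside [0, 1]", bad[1], sdi[bad[1]]),
         call. = FALSE)
  }
  data.frame(location = trimws(raw[[dialect$location]]),
             year = as.integer(.parse_numeric(raw[[dialect$year]], dialect$year)),
             sdi = sdi, stringsAsFactors = FALSE)
}

#' Read a population table
#'
#' @param path path to a CSV with location, year, and population columns.
#' @param dialect a [gbd_dialect()]; uses its `location`, `year`, `population`
#'   fields.
#' @return A data frame with columns `location`, `year`, `population` (> 0).
#' @export
read_population_csv <- function(path, dialect = gbd_dialect()) {
  raw <- .read_mapped_csv(path, dialect, c("location", "year", "population"))
  if (nrow(raw) == 0L) stop(sprintf("no data rows in %s", path), call. = FALSE)
  pop <- .parse_numeric(raw[[dialect$population]], dialect$population)
  bad <- which(pop <= 0)
  if (length(bad)) {
    stop(sprintf("row %d: non-positive population %.6g", bad[1], pop[bad[1]]),
         call. = FALSE)
  }
  data.frame(location = trimws(raw[[dialect$location]]),
             year = as.integer(.parse_numeric(raw[[dialect$year]], dialect$year)),
             population = pop, stringsAsFactors = FALSE)
}

#' Assemble a cross-referenced burden panel
#'
#' Joins validated burden, SDI, and population tables into a `gbd_panel`
#' object, checking for duplicate burden keys and reporting any
#' (location, year) combination present in the burden table but lacking an
#' SDI or population record. Location name is the join key throughout.
#'
#' @param burden data frame from [read_burden_csv()] (or the generator).
#' @param sdi data frame from [read_sdi_csv()].
#' @param population data frame from [read_population_csv()].
#' @param expected_locations if non-`NULL`, assert this many distinct
#'   locations in the burden table.
#' @param expected_years if non-`NULL`, an integer vector of years that must
#'   all be present.
#' @return A `gbd_panel`: a list with elements `burden`, `sdi`, `population`,
#'   `locations`, `years`, `causes`, and `missing` (the completeness report,
#'   a data frame of location-years without SDI or population coverage).
#' @export
assemble_panel <- function(burden, sdi, population,
                           expected_locations = NULL, expected_years = NULL) {
  stopifnot(is.data.frame(burden), is.data.frame(sdi), is.data.frame(population))
  if (nrow(burden) == 0L || nrow(sdi) == 0L || nrow(population) == 0L) {
    stop("burden, sdi, and population tables must all be non-empty", call. = FALSE)
  }

  key <- do.call(paste, c(burden[c("location", "year", "cause", "measure",
                                   "metric", "age_type")], sep = "\r"))
  dup <- duplicated(key)
  if (any(dup)) {
    first <- burden[which(dup)[1], ]
    stop(sprintf("duplicate burden key: %s / %d / %s / %s / %s / %s",
                 first$location, first$year, first$cause, first$measure,
                 first$metric, first$age_type), call. = FALSE)
  }

  locations <- sort(unique(burden$location))
  if (!length(intersect(locations, unique(sdi$location)))) {
    stop("no location is shared between the burden and SDI tables", call. = FALSE)
  }
  if (!is.null(expected_locations) && length(locations) != expected_locations) {
    stop(sprintf("expected %d locations, found %d",
                 expected_locations, length(locations)), call. = FALSE)
  }
  years <- sort(unique(burden$year))
  if (!is.null(expected_years) && !all(expected_years %in% years)) {
    miss <- setdiff(expected_years, years)
    stop(sprintf("years missing from the burden table: %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }

  ly <- unique(burden[c("location", "year")])
  sdi_key <- paste(sdi$location, sdi$year, sep = "\r")
  pop_key <- paste(population$location, population$year, sep = "\r")
  ly_key <- paste(ly$location, ly$year, sep = "\r")
  ly$missing_sdi <- !(ly_key %in% sdi_key)
  ly$missing_population <- !(ly_key %in% pop_key)
  missing <- ly[ly$missing_sdi | ly$missing_population, , drop = FALSE]
  rownames(missing) <- NULL

  structure(list(burden = burden, sdi = sdi, population = population,
                 locations = locations, years = years,
                 causes = sort(unique(burden$cause)),
                 missing = missing),
            class = "gbd_panel")
}

#' @export
print.gbd_panel <- function(x, ...) {
  cat(sprintf("<gbd_panel> %d locations x %d years, %d causes, %d burden records\n",
              length(x$locations), length(x$years), length(x$causes),
              nrow(x$burden)))
  cat(sprintf("  years %d-%d; %d location-years missing SDI or population\n",
              min(x$years), max(x$years), nrow(x$missing)))
  invisible(x)
}

#' Extract a cross-sectional slice of a panel
#'
#' Returns, for one (year, cause, measure, metric, age type) cell, every
#' location carrying all three components (burden value, SDI, population).
#' Rows are sorted by ascending SDI with ties broken by location name, the
#' deterministic order every rank-based computation downstream relies on.
#'
#' @param panel a `gbd_panel` from [assemble_panel()].
#' @param year calendar year.
#' @param cause cause name.
#' @param measure `"dalys"` or `"deaths"`.
#' @param metric `"rate"`, `"number"`, or `"percent"`.
#' @param age_type `"age_standardized"` or `"all_age"`.
#' @return A data frame with columns `location`, `value`, `sdi`, `population`,
#'   ordered by (`sdi`, `location`).
#' @export
slice_panel <- function(panel, year, cause, measure = "dalys",
                        metric = "rate", age_type = "age_standardized") {
  stopifnot(inherits(panel, "gbd_panel"))
  b <- panel$burden
  sel <- b$year == year & b$cause == cause & b$measure == measure &
    b$metric == metric & b$age_type == age_type
  if (!any(sel)) {
    stop(sprintf("empty slice: year=%s cause='%s' measure=%s metric=%s age_type=%s",
                 year, cause, measure, metric, age_type), call. = FALSE)
  }
  b <- b[sel, c("location", "value")]
  s <- panel$sdi[panel$sdi$year == year, c("location", "sdi")]
  p <- panel$population[panel$population$year == year, c("location", "population")]
  out <- merge(merge(b, s, by = "location"), p, by = "location")
  out <- out[order(out$sdi, out$location), c("location", "value", "sdi", "population")]
  rownames(out) <- NULL
  out
}
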