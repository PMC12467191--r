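# Seeded synthetic GBD-like panel generator.
#
# The generator builds a country-year-cause panel with the statistical
# structure the downstream analyses assume: a smooth per-cause burden
# frontier g(s) = max(0, a + b*s) in SDI, one-sided exponential country
# inefficiency offsets above it, monotone SDI trajectories, and truncated
# Gaussian observation noise that never takes an observation below its
# frontier. Alongside the panel it returns the generating truth (offsets,
# frontier values, gradient slopes) for parameter-recovery tests.

#' Default fibrosis-related cause list
#'
#' The six major fibrosis-associated causes analysed throughout the package.
#'
#' @return Character vector of six cause names.
#' @export
fibrosis_causes <- function() {
  c("Neoplasms",
    "Chronic obstructive pulmonary disease",
    "Chronic kidney disease",
    "Cirrhosis and other chronic liver diseases",
    "Hypertensive heart disease",
    "Tuberculosis")
}

# per-cause, per-measure frontier intercept/slope (rate units; per-100k) and
# the mean of the exponential inefficiency offset. Magnitudes are chosen to
# sit in the range of published GBD 2021 age-standardized rates for these
# causes (DALYs in the hundreds-to-thousands, deaths in the tens-to-hundreds).
.default_frontier_params <- function(causes) {
  base <- data.frame(
    cause = rep(fibrosis_causes(), each = 2),
    measure = rep(c("dalys", "deaths"), times = 6),
    a = c(3000, 150, 1800, 90, 900, 35, 1100, 40, 500, 30, 1400, 60),
    b = c(-800, -40, -1300, -65, -500, -20, -800, -28, -350, -20, -1350, -58),
    inefficiency_scale = c(600, 30, 400, 20, 250, 10, 300, 12, 150, 8, 350, 15),
    stringsAsFactors = FALSE)
  extra <- setdiff(causes, base$cause)
  if (length(extra)) {
    add <- data.frame(cause = rep(extra, each = 2),
                      measure = rep(c("dalys", "deaths"), times = length(extra)),
                      a = rep(c(1000, 50), length(extra)),
                      b = rep(c(-600, -30), length(extra)),
                      inefficiency_scale = rep(c(250, 12), length(extra)),
                      stringsAsFactors = FALSE)
    base <- rbind(base, add)
  }
  base[base$cause %in% causes, , drop = FALSE]
}

#' Specify a synthetic panel
#'
#' Full parameterization of [generate_panel()]. Defaults emulate the shape of
#' a GBD 2021 export: 204 locations, years 1990-2021, the six fibrosis-related
#' causes, a decreasing burden frontier in SDI, exponential country
#' inefficiency offsets, and mild observation noise.
#'
#' @param n_locations number of countries (>= 3).
#' @param years integer vector of calendar years.
#' @param causes character vector of cause names.
#' @param frontier_params data frame with columns `cause`, `measure`, `a`,
#'   `b`, `inefficiency_scale`; the frontier is `g(s) = max(0, a + b*s)` and
#'   the country offset `delta_c ~ Exponential(mean = inefficiency_scale)`.
#'   `inefficiency_scale = 0` is the degenerate frontier-only limit
#'   (`delta_c` fixed at 0).
#' @param gradient_mode `"frontier_only"` (burden = frontier + offset + noise)
#'   or `"linear_gradient"` (burden linear in the population-weighted midpoint
#'   SDI rank, for slope-recovery studies; slope taken from `frontier_params$b`
#'   and intercept from `a`).
#' @param noise_sd standard deviation of observation noise, rate units; noise
#'   is truncated below so no observation falls under its frontier value.
#' @param sdi_start_range interval from which 1990 SDI values are drawn.
#' @param sdi_growth `c(mean, sd)` of the per-country annual SDI increment
#'   (increments are floored at 0 so trajectories are monotone, and paths are
#'   clipped to \[0, 1\]).
#' @param population_lognormal `c(meanlog, sdlog)` of country populations.
#' @param all_cause_inflation factor (> 1) by which the all-cause total
#'   exceeds the sum of the modelled causes, so cause shares stay below 100%.
#'   The default 6 puts the six-cause share near 1/6 of total burden.
#' @param seed integer seed driving every random draw.
#' @return An object of class `panel_spec`.
#' @export
panel_spec <- function(n_locations = 204, years = 1990:2021,
                       causes = fibrosis_causes(),
                       frontier_params = NULL,
                       gradient_mode = c("frontier_only", "linear_gradient"),
                       noise_sd = 10,
                       sdi_start_range = c(0.05, 0.85),
                       sdi_growth = c(mean = 0.006, sd = 0.003),
                       population_lognormal = c(meanlog = 15.5, sdlog = 1.5),
                       all_cause_inflation = 6,
                       seed = 1L) {
  gradient_mode <- match.arg(gradient_mode)
  if (is.null(frontier_params)) frontier_params <- .default_frontier_params(causes)
  if (n_locations < 3) stop("n_locations must be >= 3", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (any(frontier_params$inefficiency_scale < 0)) {
    stop("inefficiency_scale must be >= 0", call. = FALSE)
  }
  if (all_cause_inflation <= 1) stop("all_cause_inflation must exceed 1", call. = FALSE)
  if (length(sdi_start_range) != 2 || any(sdi_start_range < 0) ||
      any(sdi_start_range > 1) || diff(sdi_start_range) < 0) {
    stop("sdi_start_range must be an interval within [0, 1]", call. = FALSE)
  }
  missing_pairs <- setdiff(paste(rep(causes, each = 2), c("dalys", "deaths")),
                           paste(frontier_params$cause, frontier_params$measure))
  if (length(missing_pairs)) {
    stop(sprintf("frontier_params lacks rows for: %s",
                 paste(missing_pairs, collapse = "; ")), call. = FALSE)
  }
  structure(list(n_locations = as.integer(n_locations),
                 years = as.integer(sort(years)), causes = causes,
                 frontier_params = frontier_params,
                 gradient_mode = gradient_mode, noise_sd = noise_sd,
                 sdi_start_range = sdi_start_range,
                 sdi_growth = c(mean = unname(sdi_growth[1]),
                                sd = unname(sdi_growth[2])),
                 population_lognormal = c(meanlog = unname(population_lognormal[1]),
                                          sdlog = unname(population_lognormal[2])),
                 all_cause_inflation = all_cause_inflation,
                 seed = as.integer(seed)),
            class = "panel_spec")
}

#' @export
print.panel_spec <- function(x, ...) {
  cat(sprintf("<panel_spec> %d locations, years %d-%d, %d causes, mode '%s', noise_sd %.3g, seed %d\n",
              x$n_locations, min(x$years), max(x$years), length(x$causes),
              x$gradient_mode, x$noise_sd, x$seed))
  invisible(x)
}

# population-weighted midpoint cumulative ranks for a (sdi, population) set
# already sorted by (sdi, location); shared with inequality_metrics
.midpoint_rank_core <- function(population) {
  share <- population / sum(population)
  after <- cumsum(share)
  before <- after - share
  (before + after) / 2
}

#' Generate a synthetic burden panel
#'
#' Draws a full panel under a [panel_spec()]: monotone SDI paths, lognormal
#' populations, and per-(location, year, cause, measure) age-standardized
#' rates `ASR = g(SDI) + delta_c + eps` with `eps` truncated at `-delta_c`
#' so observations never beat the frontier. Number-metric records are derived
#' as `rate * population / 1e5`, and an "All causes" record per
#' (location, year, measure) carries the cause sum times the configured
#' inflation factor. Uncertainty intervals are +/-10% bands.
#'
#' Identical specs (including seed) produce identical panels.
#'
#' @param spec a [panel_spec()].
#' @return A list with elements `panel` (a `gbd_panel`) and `truth` (a list
#'   with `delta` per location-cause-measure, `frontier` values per record,
#'   `gradient` slopes per cause-measure, and the `sdi_paths` used), of class
#'   `panel_truth`.
#' @export
generate_panel <- function(spec) {
  stopifnot(inherits(spec, "panel_spec"))
  n <- spec$n_locations
  years <- spec$years
  ny <- length(years)
  locs <- sprintf("Country %03d", seq_len(n))

  # independent sub-streams per component: regeneration of one component
  # does not perturb the draws of another
  with_seed <- function(offset, expr) {
    set.seed(spec$seed + offset)
    expr
  }

  sdi0 <- with_seed(1L, stats::runif(n, spec$sdi_start_range[1], spec$sdi_start_range[2]))
  growth <- with_seed(2L, pmax(0, stats::rnorm(n, spec$sdi_growth["mean"],
                                               spec$sdi_growth["sd"])))
  sdi_mat <- outer(sdi0, rep(1, ny)) + outer(growth, seq_len(ny) - 1L)
  sdi_mat <- pmin(pmax(sdi_mat, 0), 1)   # arg order keeps the dim attribute
  population <- with_seed(3L, stats::rlnorm(n, spec$population_lognormal["meanlog"],
                                            spec$population_lognormal["sdlog"]))

  fp <- spec$frontier_params
  cm <- fp[fp$cause %in% spec$causes, , drop = FALSE]
  ncm <- nrow(cm)

  delta <- with_seed(4L, {
    d <- matrix(0, n, ncm)
    for (j in seq_len(ncm)) {
      if (cm$inefficiency_scale[j] > 0) {
        d[, j] <- stats::rexp(n, rate = 1 / cm$inefficiency_scale[j])
      }
    }
    d
  })
  noise <- with_seed(5L, {
    if (spec$noise_sd > 0) {
      array(stats::rnorm(n * ny * ncm, 0, spec$noise_sd), dim = c(n, ny, ncm))
    } else {
      array(0, dim = c(n, ny, ncm))
    }
  })

  # midpoint ranks per year (population constant over years here, but ranks
  # still shift as SDI orderings change)
  rank_mat <- matrix(NA_real_, n, ny)
  for (t in seq_len(ny)) {
    ord <- order(sdi_mat[, t], locs)
    rank_mat[ord, t] <- .midpoint_rank_core(population[ord])
  }

  rows <- vector("list", ncm)
  truth_rows <- vector("list", ncm)
  for (j in seq_len(ncm)) {
    g <- pmax(0, cm$a[j] + cm$b[j] * sdi_mat)           # n x ny frontier values
    if (spec$gradient_mode == "linear_gradient") {
      asr <- cm$a[j] + cm$b[j] * rank_mat + delta[, j] + pmax(noise[, , j], -delta[, j])
      asr <- pmax(asr, 0)
    } else {
      eps <- pmax(noise[, , j], -delta[, j])            # observed never beats frontier
      asr <- g + delta[, j] + eps
    }
    rows[[j]] <- data.frame(
      location = rep(locs, times = ny),
      year = rep(years, each = n),
      cause = cm$cause[j], measure = cm$measure[j],
      value = as.vector(asr),
      stringsAsFactors = FALSE)
    truth_rows[[j]] <- data.frame(
      location = rep(locs, times = ny),
      year = rep(years, each = n),
      cause = cm$cause[j], measure = cm$measure[j],
      frontier = as.vector(g),
      stringsAsFactors = FALSE)
  }
  asr_long <- do.call(rbind, rows)

  pop_long <- data.frame(location = rep(locs, times = ny),
                         year = rep(years, each = n),
                         population = rep(population, times = ny),
                         stringsAsFactors = FALSE)

  rate_rec <- data.frame(asr_long[c("location", "year", "cause", "measure")],
                         metric = "rate", age_type = "age_standardized",
                         value = asr_long$value,
                         stringsAsFactors = FALSE)
  num_val <- asr_long$value * rep(population, times = ny * ncm) / 1e5
  num_rec <- data.frame(asr_long[c("location", "year", "cause", "measure")],
                        metric = "number", age_type = "all_age",
                        value = num_val, stringsAsFactors = FALSE)

  # all-cause totals: cause sum inflated so fibrosis shares stay below 100%
  all_rec <- do.call(rbind, lapply(c("dalys", "deaths"), function(m) {
    sub <- num_rec[num_rec$measure == m, ]
    agg <- stats::aggregate(value ~ location + year, data = sub, FUN = sum)
    data.frame(location = agg$location, year = agg$year, cause = "All causes",
               measure = m, metric = "number", age_type = "all_age",
               value = agg$value * spec$all_cause_inflation,
               stringsAsFactors = FALSE)
  }))

  burden <- rbind(rate_rec, num_rec, all_rec)
  burden$ui_lower <- burden$value * 0.9
  burden$ui_upper <- burden$value * 1.1
  burden$location_id <- match(burden$location, locs)
  burden <- burden[c("location", "location_id", "year", "cause", "measure",
                     "metric", "age_type", "value", "ui_lower", "ui_upper")]

  sdi_long <- data.frame(location = rep(locs, times = ny),
                         year = rep(years, each = n),
                         sdi = as.vector(sdi_mat), stringsAsFactors = FALSE)

  panel <- assemble_panel(burden, sdi_long, pop_long,
                          expected_locations = n, expected_years = years)

  truth <- structure(list(
    delta = data.frame(location = rep(locs, times = ncm),
                       cause = rep(cm$cause, each = n),
                       measure = rep(cm$measure, each = n),
                       delta = as.vector(delta), stringsAsFactors = FALSE),
    frontier = do.call(rbind, truth_rows),
    gradient = data.frame(cause = cm$cause, measure = cm$measure,
                          intercept = cm$a, slope = cm$b,
                          mode = spec$gradient_mode, stringsAsFactors = FALSE),
    sdi_paths = sdi_long,
    spec = spec), class = "panel_truth")

  list(panel = panel, truth = truth)
}

#' Write a panel to CSV files
#'
#' Writes `burden.csv`, `sdi.csv`, and `population.csv` into `directory`
#' using the default [gbd_dialect()] headers. Numeric fields are written at
#' 17 significant digits so a read-back round-trips to full precision.
#'
#' @param panel a `gbd_panel`.
#' @param directory output directory (created if absent).
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_panel_csvs <- function(panel, directory) {
  stopifnot(inherits(panel, "gbd_panel"))
  if (nrow(panel$burden) == 0L) stop("refusing to write an empty panel", call. = FALSE)
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(directory)) stop(sprintf("cannot create directory %s", directory), call. = FALSE)

  fmt <- function(x) sprintf("%.17g", x)
  d <- gbd_dialect()
  measure_label <- c(dalys = "DALYs (Disability-Adjusted Life Years)",
                     deaths = "Deaths")
  age_label <- c(age_standardized = "Age-standardized", all_age = "All ages")

  b <- panel$burden
  burden_out <- data.frame(measure_label[b$measure], b$location, b$location_id,
                           b$cause, b$metric, age_label[b$age_type], b$year,
                           fmt(b$value), fmt(b$ui_upper), fmt(b$ui_lower),
                           stringsAsFactors = FALSE)
  names(burden_out) <- c(d$measure, d$location, d$location_id, d$cause,
                         d$metric, d$age, d$year, d$value, d$upper, d$lower)
  sdi_out <- data.frame(panel$sdi$location, panel$sdi$year, fmt(panel$sdi$sdi),
                        stringsAsFactors = FALSE)
  names(sdi_out) <- c(d$location, d$year, d$sdi)
  pop_out <- data.frame(panel$population$location, panel$population$year,
                        fmt(panel$population$population), stringsAsFactors = FALSE)
  names(pop_out) <- c(d$location, d$year, d$population)

  paths <- c(burden = file.path(directory, "burden.csv"),
             sdi = file.path(directory, "sdi.csv"),
             population = file.path(directory, "population.csv"))
  utils::write.csv(burden_out, paths["burden"], row.names = FALSE, quote = TRUE)
  utils::write.csv(sdi_out, paths["sdi"], row.names = FALSE, quote = TRUE)
  utils::write.csv(pop_out, paths["population"], row.names = FALSE, quote = TRUE)
  invisible(paths)
}

#' Read a panel back from a directory written by [write_panel_csvs()]
#'
#' @param directory directory holding `burden.csv`, `sdi.csv`, `population.csv`.
#' @param dialect column dialect, default [gbd_dialect()].
#' @return A `gbd_panel`.
#' @export
read_panel_csvs <- function(directory, dialect = gbd_dialect()) {
  assemble_panel(read_burden_csv(file.path(directory, "burden.csv"), dialect),
                 read_sdi_csv(file.path(directory, "sdi.csv"), dialect),
                 read_population_csv(file.path(directory, "population.csv"), dialect))
}

#' Pre-aggregated SDI-group rate rows
#'
#' Emits Global and SDI-quintile group rows of population-weighted mean
#' age-standardized rates, the shape consumed by [summary_table()]. Quintile
#' membership is assigned per year from population-weighted SDI quintile
#' cut-points, mirroring how published tables stratify countries into Low to
#' High SDI bands.
#'
#' @param panel a `gbd_panel`.
#' @param causes causes to aggregate (default: all in the panel except
#'   "All causes").
#' @param measures measures to aggregate.
#' @param years years to aggregate (default: all panel years).
#' @return Data frame with columns `group`, `cause`, `measure`, `year`,
#'   `value`, `lower`, `upper`.
#' @export
sdi_group_rates <- function(panel, causes = NULL,
                            measures = c("deaths", "dalys"), years = NULL) {
  stopifnot(inherits(panel, "gbd_panel"))
  if (is.null(causes)) causes <- setdiff(panel$causes, "All causes")
  if (is.null(years)) years <- panel$years
  groups <- c("Low SDI", "Low-middle SDI", "Middle SDI",
              "High-middle SDI", "High SDI")
  out <- list()
  for (yr in years) for (ms in measures) for (cs in causes) {
    sl <- slice_panel(panel, yr, cs, ms)      # sorted ascending SDI
    cum <- cumsum(sl$population) / sum(sl$population)
    mid <- cum - sl$population / sum(sl$population) / 2
    band <- pmin(5L, findInterval(mid, seq(0.2, 0.8, by = 0.2)) + 1L)
    wmean <- function(v, w) sum(v * w) / sum(w)
    for (g in seq_along(groups)) {
      idx <- band == g
      if (!any(idx)) next
      v <- wmean(sl$value[idx], sl$population[idx])
      out[[length(out) + 1L]] <- data.frame(
        group = groups[g], cause = cs, measure = ms, year = yr,
        value = v, lower = v * 0.9, upper = v * 1.1, stringsAsFactors = FALSE)
    }
    v <- wmean(sl$value, sl$population)
    out[[length(out) + 1L]] <- data.frame(
      group = "Global", cause = cs, measure = ms, year = yr,
      value = v, lower = v * 0.9, upper = v * 1.1, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
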