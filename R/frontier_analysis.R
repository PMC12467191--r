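# Frontier (efficiency-gap) analysis: the minimum achievable age-standardized
# rate as a function of SDI, and each country-year's vertical deviation above
# it.
#
# Construction: equal-width bins over the observed SDI span -> per-bin
# minimum ASR at the bin midpoint -> locally weighted linear regression
# (tricube weights) through the minima -> clamp the smooth at each bin to
# that bin's observed minimum and floor at zero. The clamp makes the curve a
# true lower envelope: no observed point lies below the frontier within its
# bin, so every effective difference is non-negative.

#' Fit the minimum-achievable-burden frontier
#'
#' Estimates the empirical frontier relating the lowest observed
#' age-standardized rate to SDI from country-year points pooled across
#' years.
#'
#' @param points data frame with columns `sdi` and `asr` (all country-years
#'   pooled; >= 10 rows, `asr >= 0`).
#' @param n_bins number of equal-width SDI bins over the observed span
#'   (default 100).
#' @param bandwidth LOESS span in (0, 1] (default 0.3). When fewer bins are
#'   occupied than the span can support, the effective span is widened to
#'   cover at least four bins and recorded in the result.
#' @param clamp if `TRUE` (default) clamp the smoothed curve at each bin's
#'   observed minimum; `FALSE` gives the pure LOESS-through-minima curve for
#'   sensitivity checks (it may cross observed points).
#' @return Object of class `frontier_curve`: `grid` (midpoints of occupied
#'   bins, ascending), `value` (frontier ASR per grid point), `bin_min`
#'   (observed minima), `bandwidth`, `span_used`, `n_bins`, `sdi_span`
#'   (fitted span; the curve is never evaluated outside it).
#' @export
fit_frontier <- function(points, n_bins = 100, bandwidth = 0.3, clamp = TRUE) {
  if (!all(c("sdi", "asr") %in% names(points))) {
    stop("points must have columns sdi and asr", call. = FALSE)
  }
  points <- points[stats::complete.cases(points[c("sdi", "asr")]), ]
  if (nrow(points) < 10) stop("at least 10 points are required", call. = FALSE)
  if (any(points$asr < 0)) stop("asr must be non-negative", call. = FALSE)
  if (bandwidth <= 0 || bandwidth > 1) {
    stop("bandwidth must lie in (0, 1]", call. = FALSE)
  }
  lo <- min(points$sdi); hi <- max(points$sdi)
  if (hi <= lo) stop("SDI values are all identical; no span to bin", call. = FALSE)

  breaks <- seq(lo, hi, length.out = n_bins + 1)
  bin <- pmin(pmax(findInterval(points$sdi, breaks, rightmost.closed = TRUE), 1L),
              n_bins)
  mins <- tapply(points$asr, factor(bin, levels = seq_len(n_bins)), min)
  occupied <- which(!is.na(mins))
  if (length(occupied) < 3) {
    stop("fewer than 3 non-empty SDI bins; reduce n_bins or add data",
         call. = FALSE)
  }
  mids <- (breaks[occupied] + breaks[occupied + 1]) / 2
  bin_min <- as.numeric(mins[occupied])

  m <- length(occupied)
  span_used <- max(bandwidth, min(1, 4 / m))
  fit <- stats::loess(bin_min ~ mids, span = span_used, degree = 1,
                      family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  smooth <- as.numeric(stats::predict(fit, newdata = data.frame(mids = mids)))
  value <- if (clamp) pmin(smooth, bin_min) else smooth
  value <- pmax(value, 0)

  structure(list(grid = mids, value = value, bin_min = bin_min,
                 bandwidth = bandwidth, span_used = span_used,
                 n_bins = n_bins, sdi_span = c(lo, hi), clamp = clamp),
            class = "frontier_curve")
}

#' @export
print.frontier_curve <- function(x, ...) {
  cat(sprintf("<frontier_curve> %d grid points over SDI [%.3f, %.3f], %d bins, span %.2f%s\n",
              length(x$grid), x$sdi_span[1], x$sdi_span[2], x$n_bins,
              x$span_used, if (x$clamp) ", clamped" else ""))
  invisible(x)
}

#' Evaluate a frontier curve at SDI values
#'
#' Linear interpolation on the occupied-bin-midpoint grid; `NA` outside the
#' interpolable range (no extrapolation).
#'
#' @param curve a `frontier_curve`.
#' @param sdi numeric vector of SDI values.
#' @return Frontier ASR values, `NA` where `sdi` falls outside the grid.
#' @export
frontier_at <- function(curve, sdi) {
  stopifnot(inherits(curve, "frontier_curve"))
  stats::approx(curve$grid, curve$value, xout = sdi, rule = 1)$y
}

#' Effective differences from the frontier
#'
#' For each country-year, the vertical gap between the observed
#' age-standardized rate and the frontier value at that SDI,
#' `max(0, observed - frontier)` - the unrealized improvement potential.
#' Records whose SDI falls outside the interpolable span are flagged
#' (`excluded = TRUE`, gap `NA`) rather than failing.
#'
#' @param curve a `frontier_curve` from [fit_frontier()].
#' @param slice data frame with columns `location`, `year`, `sdi`, `asr`.
#' @return Data frame with `location`, `year`, `sdi`, `observed_asr`,
#'   `frontier_asr`, `effective_difference`, `excluded`.
#' @export
effective_differences <- function(curve, slice) {
  stopifnot(inherits(curve, "frontier_curve"))
  need <- c("location", "year", "sdi", "asr")
  if (!all(need %in% names(slice))) {
    stop("slice must have columns location, year, sdi, asr", call. = FALSE)
  }
  front <- frontier_at(curve, slice$sdi)
  excluded <- is.na(front)
  gap <- ifelse(excluded, NA_real_, pmax(0, slice$asr - front))
  data.frame(location = slice$location, year = slice$year, sdi = slice$sdi,
             observed_asr = slice$asr, frontier_asr = front,
             effective_difference = gap, excluded = excluded,
             stringsAsFactors = FALSE)
}

#' Rank countries by deviation from the frontier
#'
#' Returns the top-`k` largest effective differences for one year (ties
#' broken alphabetically), together with the exemplary low-SDI countries
#' closest to the frontier and the high-SDI countries furthest from it -
#' the labelling convention of frontier scatter plots.
#'
#' @param gaps data frame from [effective_differences()].
#' @param year year to rank within.
#' @param k number of top deviators (default 15).
#' @param sdi_low,sdi_high SDI cutoffs defining "low-SDI" (`< sdi_low`) and
#'   "high-SDI" (`> sdi_high`) countries for the exemplar lists.
#' @param n_exemplars length of each exemplar list (default `k`).
#' @return List with `top` (data frame, `k` rows, descending gap),
#'   `best_low_sdi` (low-SDI countries with the smallest gaps, ascending),
#'   `worst_high_sdi` (high-SDI countries with the largest gaps, descending).
#' @export
rank_deviators <- function(gaps, year, k = 15, sdi_low = 0.45,
                           sdi_high = 0.80, n_exemplars = k) {
  if (k < 1) stop("k must be at least 1", call. = FALSE)
  g <- gaps[gaps$year == year & !gaps$excluded, , drop = FALSE]
  if (nrow(g) == 0) stop(sprintf("no gaps available for year %s", year), call. = FALSE)

  desc <- g[order(-g$effective_difference, g$location), , drop = FALSE]
  asc <- g[order(g$effective_difference, g$location), , drop = FALSE]
  top <- utils::head(desc, k)
  low <- asc[asc$sdi < sdi_low, , drop = FALSE]
  high <- desc[desc$sdi > sdi_high, , drop = FALSE]
  rownames(top) <- NULL
  list(top = top,
       best_low_sdi = utils::head(low, n_exemplars),
       worst_high_sdi = utils::head(high, n_exemplars))
}

#' Pool a panel's country-year points for frontier fitting
#'
#' Gathers every (SDI, age-standardized rate) country-year pair for one cause
#' and measure across the panel's years - the pooled cloud the frontier is
#' fitted to.
#'
#' @param panel a `gbd_panel`.
#' @param cause cause name.
#' @param measure `"dalys"` (the conventional frontier measure) or
#'   `"deaths"`.
#' @param years years to pool (default: all).
#' @return Data frame with `location`, `year`, `sdi`, `asr`.
#' @export
frontier_points <- function(panel, cause, measure = "dalys", years = NULL) {
  stopifnot(inherits(panel, "gbd_panel"))
  if (is.null(years)) years <- panel$years
  out <- lapply(years, function(yr) {
    sl <- slice_panel(panel, yr, cause, measure)
    data.frame(location = sl$location, year = yr, sdi = sl$sdi,
               asr = sl$value, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
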