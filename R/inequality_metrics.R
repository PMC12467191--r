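# Slope index of inequality (SII) and concentration index of inequality (CII)
# over SDI-ranked country panels.
#
# Both metrics operate on countries sorted by ascending SDI (ties broken by
# location name) with population-weighted midpoint cumulative ranks. The SII
# is the fitted slope of the age-standardized rate on that rank, expressed
# per full rank span (rank 0 -> 1); the CII is one minus twice the trapezoid
# area under the Lorenz-type concentration curve of cumulative burden share
# against cumulative population share.

#' Population-weighted midpoint SDI ranks
#'
#' Sorts countries by ascending SDI (ties broken by location name) and
#' assigns each the midpoint of its interval on the cumulative
#' population-share axis: `midpoint_rank = cum_share_before + pop_share / 2`.
#'
#' @param countries data frame with columns `location`, `sdi`, `population`.
#' @return Data frame of class `country_ranks` with the inputs plus
#'   `pop_share`, `cum_before`, `cum_after`, `midpoint_rank`, sorted by
#'   (`sdi`, `location`).
#' @export
#' @examples
#' midpoint_ranks(data.frame(location = c("A", "B", "C"),
#'                           sdi = c(0.2, 0.5, 0.8), population = rep(1, 3)))
midpoint_ranks <- function(countries) {
  need <- c("location", "sdi", "population")
  if (!all(need %in% names(countries))) {
    stop("countries must have columns location, sdi, population", call. = FALSE)
  }
  if (nrow(countries) < 2) stop("at least 2 countries are required", call. = FALSE)
  if (anyDuplicated(countries$location)) {
    stop(sprintf("duplicate location name: %s",
                 countries$location[anyDuplicated(countries$location)]),
         call. = FALSE)
  }
  if (any(countries$population <= 0)) {
    stop("populations must be positive", call. = FALSE)
  }
  if (any(countries$sdi < 0 | countries$sdi > 1)) {
    stop("sdi must lie in [0, 1]", call. = FALSE)
  }
  out <- countries[order(countries$sdi, countries$location), , drop = FALSE]
  out$pop_share <- out$population / sum(out$population)
  out$cum_after <- cumsum(out$pop_share)
  out$cum_before <- out$cum_after - out$pop_share
  out$midpoint_rank <- (out$cum_before + out$cum_after) / 2
  rownames(out) <- NULL
  class(out) <- c("country_ranks", "data.frame")
  out
}

# rank construction without the duplicate-name guard, for bootstrap resamples
.ranks_unchecked <- function(sdi, population, location, rates) {
  ord <- order(sdi, location)
  share <- population[ord] / sum(population[ord])
  after <- cumsum(share)
  list(rank = after - share / 2, share = share,
       rate = rates[ord], population = population[ord])
}

.fit_sii <- function(rank, rate, weight, method) {
  if (method == "wls") {
    unname(coef(stats::lm(rate ~ rank, weights = weight))[2])
  } else {
    fit <- suppressWarnings(
      MASS::rlm(rate ~ rank, weights = weight, psi = MASS::psi.huber,
                k = 1.345, maxit = 100))
    unname(coef(fit)[2])
  }
}

#' Slope index of inequality
#'
#' Regresses per-country age-standardized rates on population-weighted
#' midpoint SDI ranks and reports the fitted slope over the full rank span
#' (rank 0 at the least-developed end, 1 at the most developed). A negative
#' SII means the burden falls with development, i.e. is higher in low-SDI
#' countries. `method = "wls"` fits weighted least squares with
#' population-share weights; `method = "huber"` fits a Huber M-estimator
#' (tuning constant 1.345) with the same weights, robust to outlying
#' countries. Confidence intervals come from a seeded nonparametric
#' bootstrap resampling countries with replacement (percentile method),
#' re-deriving ranks within each resample.
#'
#' @param ranks a `country_ranks` data frame from [midpoint_ranks()].
#' @param rates numeric vector of age-standardized rates aligned to the rows
#'   of `ranks`.
#' @param method `"wls"` (default) or `"huber"`.
#' @param n_bootstrap bootstrap replicates for the CI (0 disables; default
#'   1000).
#' @param seed integer seed for the bootstrap.
#' @param conf_level CI coverage, default 0.95.
#' @return List of class `sii_result`: `sii`, `ci_lower`, `ci_upper`,
#'   `method`, `n_countries`, `n_bootstrap`, `seed`.
#' @export
slope_index <- function(ranks, rates, method = c("wls", "huber"),
                        n_bootstrap = 1000, seed = NULL, conf_level = 0.95) {
  method <- match.arg(method)
  stopifnot(inherits(ranks, "country_ranks"))
  n <- nrow(ranks)
  if (length(rates) != n) stop("rates must align with ranks", call. = FALSE)
  if (n < 3) stop("at least 3 countries are required", call. = FALSE)
  if (stats::var(ranks$midpoint_rank) == 0) {
    stop("zero variance in midpoint ranks", call. = FALSE)
  }

  sii <- .fit_sii(ranks$midpoint_rank, rates, ranks$pop_share, method)

  ci <- c(NA_real_, NA_real_)
  if (n_bootstrap > 0) {
    if (!is.null(seed)) {
      old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
      on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
      set.seed(seed)
    }
    reps <- vapply(seq_len(n_bootstrap), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      rs <- .ranks_unchecked(ranks$sdi[idx], ranks$population[idx],
                             ranks$location[idx], rates[idx])
      .fit_sii(rs$rank, rs$rate, rs$share, method)
    }, numeric(1))
    alpha <- (1 - conf_level) / 2
    ci <- unname(stats::quantile(reps, c(alpha, 1 - alpha), na.rm = TRUE))
  }

  structure(list(sii = sii, ci_lower = ci[1], ci_upper = ci[2],
                 method = method, n_countries = n,
                 n_bootstrap = n_bootstrap, seed = seed),
            class = "sii_result")
}

#' @export
print.sii_result <- function(x, ...) {
  cat(sprintf("SII = %.4g [%.4g, %.4g] (%s, n = %d, %d bootstrap reps)\n",
              x$sii, x$ci_lower, x$ci_upper, x$method, x$n_countries,
              x$n_bootstrap))
  invisible(x)
}

# trapezoid CII over cumulative (population share, burden share) points
# anchored at (0, 0); the final point is (1, 1) by construction
.cii_core <- function(pop_share, burden) {
  w <- burden / sum(burden)
  p <- c(0, cumsum(pop_share))
  L <- c(0, cumsum(w))
  area <- sum(diff(p) * (utils::head(L, -1) + utils::tail(L, -1)) / 2)
  1 - 2 * area
}

#' Concentration index of inequality
#'
#' Computes the concentration index from the Lorenz-type concentration curve:
#' countries are taken in ascending SDI order, each contributing a burden
#' share `rate * population / sum(rate * population)` (per-capita rates
#' converted to totals); the curve joins (0, 0) to the cumulative
#' (population share, burden share) points and the index is
#' `1 - 2 * integral` of the curve by the trapezoid rule. Positive values
#' mean burden concentrated in high-SDI countries; negative values mean
#' burden concentrated in low-SDI countries; 0 when all rates are equal.
#'
#' @inheritParams slope_index
#' @param n_bootstrap bootstrap replicates for a percentile CI (default 0,
#'   point estimate only).
#' @return List of class `cii_result`: `cii` (in \[-1, 1\]), `ci_lower`,
#'   `ci_upper`, `integration_rule` (`"trapezoid"`), `n_countries`.
#' @export
concentration_index <- function(ranks, rates, n_bootstrap = 0, seed = NULL,
                                conf_level = 0.95) {
  stopifnot(inherits(ranks, "country_ranks"))
  n <- nrow(ranks)
  if (length(rates) != n) stop("rates must align with ranks", call. = FALSE)
  if (any(rates < 0)) stop("rates must be non-negative", call. = FALSE)
  if (all(rates == 0)) stop("at least one rate must be positive", call. = FALSE)

  cii <- .cii_core(ranks$pop_share, rates * ranks$population)

  ci <- c(NA_real_, NA_real_)
  if (n_bootstrap > 0) {
    if (!is.null(seed)) {
      old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
      on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
      set.seed(seed)
    }
    reps <- vapply(seq_len(n_bootstrap), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      if (all(rates[idx] == 0)) return(NA_real_)
      rs <- .ranks_unchecked(ranks$sdi[idx], ranks$population[idx],
                             ranks$location[idx], rates[idx])
      .cii_core(rs$share, rs$rate * rs$population)
    }, numeric(1))
    alpha <- (1 - conf_level) / 2
    ci <- unname(stats::quantile(reps, c(alpha, 1 - alpha), na.rm = TRUE))
  }

  structure(list(cii = cii, ci_lower = ci[1], ci_upper = ci[2],
                 integration_rule = "trapezoid", n_countries = n,
                 n_bootstrap = n_bootstrap, seed = seed),
            class = "cii_result")
}

#' @export
print.cii_result <- function(x, ...) {
  cat(sprintf("CII = %.4f (trapezoid, n = %d)\n", x$cii, x$n_countries))
  invisible(x)
}

#' Yearly inequality metric series for a cause
#'
#' Computes SII and CII for each requested year of a panel, using that year's
#' SDI and population to rank countries. Bootstrap seeds are derived
#' deterministically per year from `seed`, so repeated runs give identical
#' intervals.
#'
#' @param panel a `gbd_panel`.
#' @param cause cause name.
#' @param measure `"dalys"` or `"deaths"`.
#' @param years years to evaluate (default: all panel years).
#' @param method SII regression method, `"wls"` or `"huber"`.
#' @param n_bootstrap bootstrap replicates for both metrics' CIs.
#' @param seed integer base seed.
#' @return Data frame with one row per year: `year`, `sii`, `sii_lower`,
#'   `sii_upper`, `cii`, `cii_lower`, `cii_upper`, `n`.
#' @export
inequality_timeseries <- function(panel, cause, measure = "dalys",
                                  years = NULL, method = "wls",
                                  n_bootstrap = 1000, seed = 1L) {
  stopifnot(inherits(panel, "gbd_panel"))
  if (is.null(years)) years <- panel$years
  out <- lapply(seq_along(years), function(i) {
    yr <- years[i]
    sl <- slice_panel(panel, yr, cause, measure)
    rk <- midpoint_ranks(sl[c("location", "sdi", "population")])
    # slice and ranks share the (sdi, location) sort order, so values align
    sii <- slope_index(rk, sl$value, method = method,
                       n_bootstrap = n_bootstrap, seed = seed + i)
    cii <- concentration_index(rk, sl$value, n_bootstrap = n_bootstrap,
                               seed = seed + 10000L + i)
    data.frame(year = yr, sii = sii$sii, sii_lower = sii$ci_lower,
               sii_upper = sii$ci_upper, cii = cii$cii,
               cii_lower = cii$ci_lower, cii_upper = cii$ci_upper,
               n = nrow(sl))
  })
  do.call(rbind, out)
}
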