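# independent closed-form OLS oracle: slope = S_xy / S_xx
ols_slope <- function(x, y, w = rep(1, length(x))) {
  xb <- sum(w * x) / sum(w)
  yb <- sum(w * y) / sum(w)
  sum(w * (x - xb) * (y - yb)) / sum(w * (x - xb)^2)
}

# independent trapezoid oracle over explicit concentration-curve points
trapezoid_cii <- function(p, L) {
  p <- c(0, p); L <- c(0, L)
  1 - 2 * sum(diff(p) * (head(L, -1) + tail(L, -1)) / 2)
}

test_that("midpoint ranks follow the closed forms and cumulate to one", {
  rk <- three_country_ranks()
  expect_equal(rk$midpoint_rank, c(1 / 6, 1 / 2, 5 / 6))
  expect_equal(sum(rk$pop_share), 1)

  rk2 <- midpoint_ranks(data.frame(location = c("A", "B"), sdi = c(0.2, 0.7),
                                   population = c(9, 1)))
  expect_equal(rk2$midpoint_rank, c(0.45, 0.95))

  set.seed(5)
  rk3 <- midpoint_ranks(data.frame(location = sprintf("L%02d", 1:40),
                                   sdi = runif(40),
                                   population = rlnorm(40, 12, 1)))
  expect_true(all(diff(rk3$midpoint_rank) > 0))
  expect_equal(rk3$cum_after[40], 1)

  expect_error(midpoint_ranks(data.frame(location = c("A", "A"),
                                         sdi = c(0.1, 0.2), population = 1)),
               "duplicate location")
  expect_error(midpoint_ranks(data.frame(location = c("A", "B"),
                                         sdi = c(0.1, 0.2),
                                         population = c(1, -1))),
               "positive")
})

test_that("WLS slope index matches the closed-form oracle", {
  rk <- three_country_ranks()
  rates <- c(100, 80, 60)
  expect_equal(ols_slope(rk$midpoint_rank, rates), -60)  # oracle first
  res <- slope_index(rk, rates, method = "wls", n_bootstrap = 0)
  expect_equal(res$sii, -60)

  # with unequal populations, WLS must match the weighted oracle
  rku <- three_country_ranks(pop = c(5, 2, 1))
  rates2 <- c(120, 70, 20)
  expect_equal(slope_index(rku, rates2, n_bootstrap = 0)$sii,
               ols_slope(rku$midpoint_rank, rates2, rku$pop_share))
})

test_that("flat rates give SII of zero with a CI containing zero", {
  rk <- three_country_ranks()
  res <- slope_index(rk, c(50, 50, 50), n_bootstrap = 100, seed = 1)
  expect_equal(res$sii, 0, tolerance = 1e-12)
  expect_lte(res$ci_lower, 1e-10)
  expect_gte(res$ci_upper, -1e-10)
})

test_that("SII scales linearly in the rates and errors on degenerate input", {
  set.seed(2)
  rk <- midpoint_ranks(data.frame(location = sprintf("L%02d", 1:30),
                                  sdi = runif(30), population = rlnorm(30)))
  rates <- 500 + 300 * rk$sdi + rnorm(30, 0, 30)
  s1 <- slope_index(rk, rates, n_bootstrap = 0)$sii
  s2 <- slope_index(rk, rates * 3.5, n_bootstrap = 0)$sii
  expect_equal(s2, 3.5 * s1)
  expect_error(slope_index(three_country_ranks()[1:2, ], c(1, 2)), "at least 3")
})

test_that("huber and WLS agree on outlier-free data and diverge under outliers", {
  set.seed(3)
  n <- 60
  rk <- midpoint_ranks(data.frame(location = sprintf("L%02d", 1:n),
                                  sdi = runif(n), population = rep(1, n)))
  clean <- 1000 - 400 * rk$midpoint_rank + rnorm(n, 0, 5)
  wls <- slope_index(rk, clean, method = "wls", n_bootstrap = 0)$sii
  hub <- slope_index(rk, clean, method = "huber", n_bootstrap = 0)$sii
  expect_equal(hub, wls, tolerance = 0.01)

  dirty <- clean
  dirty[n] <- dirty[n] + 5000  # one grossly deviating high-SDI country
  wls_d <- slope_index(rk, dirty, method = "wls", n_bootstrap = 0)$sii
  hub_d <- slope_index(rk, dirty, method = "huber", n_bootstrap = 0)$sii
  expect_lt(abs(hub_d - wls), abs(wls_d - wls))
})

test_that("bootstrap intervals are seeded and bracket the point estimate", {
  set.seed(4)
  rk <- midpoint_ranks(data.frame(location = sprintf("L%02d", 1:40),
                                  sdi = runif(40), population = rlnorm(40)))
  rates <- 800 - 300 * rk$midpoint_rank + rnorm(40, 0, 40)
  a <- slope_index(rk, rates, n_bootstrap = 200, seed = 99)
  b <- slope_index(rk, rates, n_bootstrap = 200, seed = 99)
  expect_identical(c(a$ci_lower, a$ci_upper), c(b$ci_lower, b$ci_upper))
  expect_true(a$ci_lower <= a$sii && a$sii <= a$ci_upper)
})

test_that("concentration index matches the hand trapezoid oracle", {
  # equal populations, rates (100, 80, 60) in ascending SDI order:
  # curve points (1/3, 5/12), (2/3, 3/4), (1, 1)
  expect_equal(trapezoid_cii(c(1, 2, 3) / 3, c(5 / 12, 3 / 4, 1)), -1 / 9)
  rk <- three_country_ranks()
  expect_equal(concentration_index(rk, c(100, 80, 60))$cii, -1 / 9)
  expect_equal(concentration_index(rk, c(50, 50, 50))$cii, 0)
})

test_that("reversing the SDI order flips the CII sign exactly", {
  set.seed(6)
  n <- 25
  df <- data.frame(location = sprintf("L%02d", 1:n), sdi = runif(n),
                   population = rlnorm(n, 11, 0.8))
  rates <- rlnorm(n, 6, 0.5)
  fwd <- concentration_index(midpoint_ranks(df), rates[order(df$sdi, df$location)])
  rev_df <- df
  rev_df$sdi <- 1 - df$sdi
  bwd <- concentration_index(midpoint_ranks(rev_df),
                             rates[order(rev_df$sdi, rev_df$location)])
  expect_equal(bwd$cii, -fwd$cii, tolerance = 1e-12)
})

test_that("CII is scale-invariant, bounded, and centred under exchangeability", {
  set.seed(7)
  n <- 30
  rk <- midpoint_ranks(data.frame(location = sprintf("L%02d", 1:n),
                                  sdi = runif(n), population = rlnorm(n)))
  rates <- rlnorm(n, 5, 1)
  c1 <- concentration_index(rk, rates)$cii
  expect_equal(concentration_index(rk, rates * 123.4)$cii, c1)
  expect_true(abs(c1) <= 1)

  # permuting rates w.r.t. rank: mean CII over permutations ~ 0
  perm <- replicate(200, concentration_index(rk, sample(rates))$cii)
  expect_true(all(abs(perm) <= 1))
  expect_lt(abs(mean(perm)), 0.02)

  expect_error(concentration_index(rk, rep(0, n)), "positive")
})

test_that("burden loaded onto low-SDI countries yields a negative CII", {
  # the direction convention for a burden concentrated in poor countries
  set.seed(8)
  n <- 40
  df <- data.frame(location = sprintf("L%02d", 1:n), sdi = sort(runif(n)),
                   population = rep(1, n))
  rk <- midpoint_ranks(df)
  falling <- 2000 - 1500 * rk$midpoint_rank
  expect_lt(concentration_index(rk, falling)$cii, 0)
  expect_gt(concentration_index(rk, rev(falling))$cii, 0)
})

test_that("inequality_timeseries tracks a shrinking gradient and is reproducible", {
  # hand-built panel: rates linear in rank with slope shrinking over years
  n <- 30
  years <- 2000:2004
  locs <- sprintf("L%02d", 1:n)
  sdi <- seq(0.05, 0.95, length.out = n)
  slope_by_year <- seq(-900, -100, length.out = length(years))
  burden <- do.call(rbind, lapply(seq_along(years), function(i) {
    rank <- (seq_len(n) - 0.5) / n
    data.frame(location = locs, location_id = NA, year = years[i], cause = "X",
               measure = "dalys", metric = "rate", age_type = "age_standardized",
               value = 1500 + slope_by_year[i] * rank,
               ui_lower = 0, ui_upper = 1e6)
  }))
  burden$ui_lower <- burden$value * 0.9
  burden$ui_upper <- burden$value * 1.1
  sdi_df <- expand.grid(location = locs, year = years, stringsAsFactors = FALSE)
  sdi_df$sdi <- sdi[match(sdi_df$location, locs)]
  pop_df <- data.frame(sdi_df[c("location", "year")], population = 1e6)
  panel <- assemble_panel(burden, sdi_df, pop_df)

  ts1 <- inequality_timeseries(panel, "X", "dalys", method = "wls",
                               n_bootstrap = 50, seed = 11)
  expect_equal(ts1$sii, slope_by_year, tolerance = 1e-9)
  expect_true(all(diff(abs(ts1$sii)) < 0))

  ts2 <- inequality_timeseries(panel, "X", "dalys", method = "wls",
                               n_bootstrap = 50, seed = 11)
  expect_identical(ts1, ts2)
})
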