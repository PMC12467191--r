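write_csv_text <- function(text) {
  path <- tempfile(fileext = ".csv")
  writeLines(text, path)
  path
}

test_that("a well-formed burden CSV parses row-for-row", {
  path <- write_csv_text(c(
    "measure_name,location_name,cause_name,metric_name,age_name,year,val,upper,lower",
    "Deaths,Afghanistan,Neoplasms,Rate,Age-standardized,1990,98.5,110.2,87.1",
    "DALYs (Disability-Adjusted Life Years),Afghanistan,Neoplasms,Number,All ages,1990,52000,60000,45000",
    "Deaths,Albania,Tuberculosis,Percent,All ages,2021,1.5,2.0,1.0"))
  rec <- read_burden_csv(path)
  expect_equal(nrow(rec), 3)
  expect_equal(rec$measure, c("deaths", "dalys", "deaths"))
  expect_equal(rec$metric, c("rate", "number", "percent"))
  expect_equal(rec$age_type, c("age_standardized", "all_age", "all_age"))
  expect_equal(rec$value, c(98.5, 52000, 1.5))
  expect_equal(rec$ui_lower, c(87.1, 45000, 1.0))
})

test_that("invariant violations are rejected with their row number", {
  bad_ui <- write_csv_text(c(
    "measure_name,location_name,cause_name,metric_name,age_name,year,val,upper,lower",
    "Deaths,X,Neoplasms,Rate,Age-standardized,1990,50,60,55"))
  expect_error(read_burden_csv(bad_ui), "row 1.*uncertainty interval")

  bad_pct <- write_csv_text(c(
    "measure_name,location_name,cause_name,metric_name,age_name,year,val,upper,lower",
    "Deaths,X,Neoplasms,Rate,Age-standardized,1990,50,60,40",
    "Deaths,X,Neoplasms,Percent,All ages,1990,120,130,110"))
  expect_error(read_burden_csv(bad_pct), "row 2.*percent.*exceeds 100")

  bad_measure <- write_csv_text(c(
    "measure_name,location_name,cause_name,metric_name,age_name,year,val,upper,lower",
    "Incidence,X,Neoplasms,Rate,Age-standardized,1990,50,60,40"))
  expect_error(read_burden_csv(bad_measure), "row 1.*unmapped measure")

  grouped <- write_csv_text(c(
    "measure_name,location_name,cause_name,metric_name,age_name,year,val,upper,lower",
    "Deaths,X,Neoplasms,Number,All ages,1990,\"1,234\",2000,1000"))
  expect_error(read_burden_csv(grouped), "grouping separator")
})

test_that("missing required columns name the column; dialects remap headers", {
  path <- write_csv_text(c("location_name,year,val", "X,1990,1"))
  expect_error(read_burden_csv(path), "column `cause_name`.*missing")

  renamed <- write_csv_text(c(
    "mes,country,cs,met,ag,year,val,upper,lower",
    "Deaths,X,Neoplasms,Rate,Age-standardized,1990,50,60,40"))
  d <- gbd_dialect(measure = "mes", location = "country", cause = "cs",
                   metric = "met", age = "ag")
  expect_equal(read_burden_csv(renamed, d)$location, "X")
})

test_that("SDI values outside [0, 1] are rejected; valid rows parse", {
  ok <- write_csv_text(c("location_name,year,sdi", "X,2000,0.5"))
  expect_equal(read_sdi_csv(ok)$sdi, 0.5)
  bad <- write_csv_text(c("location_name,year,sdi", "X,2000,1.2"))
  expect_error(read_sdi_csv(bad), "outside \\[0, 1\\]")
  expect_error(
    read_population_csv(write_csv_text(c("location_name,year,population",
                                         "X,2000,0"))),
    "non-positive population")
})

test_that("assemble_panel reports completeness and rejects duplicates", {
  gen <- generate_panel(small_spec())
  p <- gen$panel
  expect_equal(nrow(p$missing), 0)
  expect_length(p$locations, 25)
  expect_length(p$years, 5)

  # drop one SDI record -> one named missing location-year
  sdi2 <- p$sdi[-5, ]
  dropped <- p$sdi[5, ]
  p2 <- assemble_panel(p$burden, sdi2, p$population)
  expect_equal(nrow(p2$missing), 1)
  expect_equal(p2$missing$location, dropped$location)
  expect_equal(p2$missing$year, dropped$year)

  # duplicated burden row -> error naming the key
  expect_error(assemble_panel(rbind(p$burden, p$burden[1, ]), p$sdi, p$population),
               "duplicate burden key")
  # disjoint locations -> error
  sdi3 <- p$sdi
  sdi3$location <- paste0("Z", sdi3$location)
  expect_error(assemble_panel(p$burden, sdi3, p$population),
               "no location is shared")
})

test_that("slice_panel is complete, deterministically ordered, and matches truth", {
  gen <- generate_panel(small_spec())
  sl <- slice_panel(gen$panel, 1992, "Neoplasms", "dalys")
  expect_equal(nrow(sl), 25)
  expect_true(!is.unsorted(sl$sdi))

  # SDI ties break alphabetically by location
  burden <- data.frame(location = c("B", "A"), location_id = NA, year = 2000,
                       cause = "X", measure = "dalys", metric = "rate",
                       age_type = "age_standardized", value = c(1, 2),
                       ui_lower = c(1, 2), ui_upper = c(1, 2))
  sdi <- data.frame(location = c("A", "B"), year = 2000, sdi = 0.5)
  pop <- data.frame(location = c("A", "B"), year = 2000, population = 1)
  sl2 <- slice_panel(assemble_panel(burden, sdi, pop), 2000, "X", "dalys")
  expect_equal(sl2$location, c("A", "B"))

  expect_error(slice_panel(gen$panel, 1992, "Nonexistent cause"), "empty slice")

  # values equal the generator's stored truth (frontier + offset, no noise)
  fp <- frontier_params_no_offset()
  g0 <- generate_panel(panel_spec(n_locations = 20, years = 1990:1991,
                                  noise_sd = 0, frontier_params = fp, seed = 9))
  sl3 <- slice_panel(g0$panel, 1991, "Tuberculosis", "deaths")
  tr <- g0$truth$frontier
  tr <- tr[tr$cause == "Tuberculosis" & tr$measure == "deaths" & tr$year == 1991, ]
  expect_equal(sl3$value[order(sl3$location)],
               tr$frontier[order(tr$location)], tolerance = 1e-12)
})

test_that("write-then-read round-trips every numeric field exactly", {
  gen <- generate_panel(small_spec())
  dir <- tempfile("panel")
  paths <- write_panel_csvs(gen$panel, dir)
  expect_length(paths, 3)
  back <- read_panel_csvs(dir)

  key_cols <- c("location", "year", "cause", "measure", "metric", "age_type")
  a <- gen$panel$burden[do.call(order, gen$panel$burden[key_cols]), ]
  b <- back$burden[do.call(order, back$burden[key_cols]), ]
  expect_identical(a$value, b$value)
  expect_identical(a$ui_lower, b$ui_lower)
  expect_identical(a$ui_upper, b$ui_upper)
  s_a <- gen$panel$sdi[order(gen$panel$sdi$location, gen$panel$sdi$year), ]
  s_b <- back$sdi[order(back$sdi$location, back$sdi$year), ]
  expect_identical(s_a$sdi, s_b$sdi)
})
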