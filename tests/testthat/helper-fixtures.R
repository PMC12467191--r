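# Shared fixtures, all built in code at test time.

# three equal-population countries in ascending SDI order; the closed-form
# oracle configuration used across the inequality tests
three_country_ranks <- function(pop = c(1, 1, 1), sdi = c(0.2, 0.5, 0.8)) {
  midpoint_ranks(data.frame(location = c("A", "B", "C"), sdi = sdi,
                            population = pop))
}

# minimal hand-built panel: `n` countries, one year, one cause plus an
# all-cause total, with number and rate records
toy_panel <- function(values = c(100, 80, 60), all_cause_mult = 2,
                      year = 2021, cause = "Neoplasms") {
  n <- length(values)
  locs <- LETTERS[seq_len(n)]
  num <- data.frame(location = locs, location_id = seq_len(n), year = year,
                    cause = cause, measure = "dalys", metric = "number",
                    age_type = "all_age", value = values,
                    ui_lower = values * 0.9, ui_upper = values * 1.1,
                    stringsAsFactors = FALSE)
  allc <- num
  allc$cause <- "All causes"
  allc$value <- allc$value * all_cause_mult
  allc$ui_lower <- allc$value * 0.9
  allc$ui_upper <- allc$value * 1.1
  rate <- num
  rate$metric <- "rate"
  rate$age_type <- "age_standardized"
  burden <- rbind(num, allc, rate)
  sdi <- data.frame(location = locs, year = year,
                    sdi = seq(0.1, 0.9, length.out = n))
  pop <- data.frame(location = locs, year = year, population = rep(1e6, n))
  assemble_panel(burden, sdi, pop)
}

# small generator spec used where panel scale is irrelevant
small_spec <- function(...) {
  panel_spec(n_locations = 25, years = 1990:1994, seed = 42, ...)
}

# frontier params with the inefficiency offset switched off
frontier_params_no_offset <- function() {
  fp <- fibroburden:::.default_frontier_params(fibrosis_causes())
  fp$inefficiency_scale <- 0
  fp
}
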