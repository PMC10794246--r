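# Small in-code fixtures shared across test files.

# compact synthetic study: 8x8 grid of 5 km cells, 2 countries, thin sea margin
tiny_spec <- function(seed = 11, gamma = 0, n_rows = 8, n_cols = 8) {
  synthetic_spec(grid = grid_spec(n_rows, n_cols, cell_size = 5),
                 seed = seed, n_countries = 2, n_cities = 3,
                 gamma = gamma, population_total = 5e5, sea_margin = 1)
}

tiny_study <- function(seed = 11, gamma = 0) generate_study(tiny_spec(seed, gamma))

# single TMREL-scaled curve with a convenient closed form above the TMREL
toy_erf <- function(cause = "COPD", age_group = "ALL",
                    knots = c(0, 4.15, 10, 20, 40),
                    rr = c(1, 1, 1.2, 1.35, 1.5)) {
  tabulated_erf(cause, age_group, knots, rr, rr, rr, scaled = TRUE)
}

# near-linear curve set: RR - 1 = beta * conc at two distant knots, for every
# cause, so mortality is (almost) proportional to super-TMREL exposure
linear_erf_set <- function(beta = 5e-4) {
  knots <- c(0, 4.15, 2000)
  mk <- function(cause) {
    raw <- 1 + beta * knots
    scale_to_tmrel(tabulated_erf(cause, "ALL", knots, raw, raw, raw))
  }
  erf_set(lapply(stats::setNames(nm = cause_registry()$code), mk))
}

# uniform baseline mortality: same rates in every country, so the per-cell
# mortality weight is exactly proportional to the population
uniform_bmr <- function(countries, rate = 0.002) {
  g <- expand.grid(country = countries, cause = cause_registry()$code,
                   age_group = adult_age_classes(), stringsAsFactors = FALSE)
  g$rate <- rate
  bmr_table(g, countries)
}

# one-cell mortality result holding a given number of deaths in one stratum
one_cell_result <- function(deaths, scenario = "BASE") {
  g <- grid_spec(1, 1, 5)
  vals <- array(0, dim = c(1, 1, 6, 12, 3),
                dimnames = list(NULL, NULL, cause_registry()$code,
                                adult_age_classes(), c("central", "low", "high")))
  vals[1, 1, 1, 1, ] <- deaths
  mortality_result(g, scenario, vals)
}

const_field <- function(grid, value, species = "PM25", scenario = "BASE")
  conc_field(grid, species, scenario, matrix(value, grid$n_rows, grid$n_cols))
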