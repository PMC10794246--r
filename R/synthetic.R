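#' Specification of a synthetic study
#'
#' Parameters of the synthetic-data generator, which emulates the statistical
#' structure of the real inputs of a gridded health impact assessment:
#' spatially smooth, sector-additive concentration surfaces from a
#' chemical-transport model; population clustered around cities; country-level
#' baseline mortality rates; and monotone, supralinear exposure-response
#' curves. Every generated artifact is a deterministic function of `seed`.
#'
#' Defaults are chosen so that a default study has population-weighted BASE
#' PM2.5 per country of a few to ~20 ug/m3 and countrywide aCA/PM2.5 mass
#' fractions of roughly 4-23%, the ranges typical of wider Europe; sectoral
#' aCA mass shares default to residential 0.45, road transport 0.25, other
#' 0.10, background 0.02 (carbon-rich combustion sectors vs largely inorganic
#' background).
#'
#' @param grid A [grid_spec()]; default 60 x 60 cells of 5 km.
#' @param seed Integer seed fixing all randomness.
#' @param n_countries Number of contiguous countries to carve the land into.
#' @param n_cities Number of population/emission centers.
#' @param sectors `data.frame` with columns `sector`
#'   (`RES`, `TRA`, `OTHER`, `BACKGROUND`), `amplitude` (ug/m3, peak
#'   concentration contributed), `corr_length_km` (spatial correlation
#'   length) and `aca_share` (aCA mass fraction of the sector's PM2.5,
#'   in \[0, 1\]).
#' @param gamma Nonlinearity coefficient (>= 0) of the scenario composition;
#'   0 gives exactly additive sector fields.
#' @param population_total Total adult population of the domain.
#' @param clustering_exponent Exponent applied to the city-kernel density
#'   surface; larger values concentrate population more strongly.
#' @param sea_margin Width (cells) of the out-of-mask margin around the
#'   domain.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(grid = grid_spec(60, 60, cell_size = 5),
                           seed = 1L,
                           n_countries = 4L,
                           n_cities = 8L,
                           sectors = data.frame(
                             sector = c("RES", "TRA", "OTHER", "BACKGROUND"),
                             amplitude = c(7, 4.5, 4, 5),
                             corr_length_km = c(35, 25, 45, 160),
                             aca_share = c(0.45, 0.25, 0.10, 0.02),
                             stringsAsFactors = FALSE),
                           gamma = 0,
                           population_total = 8e6,
                           clustering_exponent = 1.6,
                           sea_margin = 2L) {
  stopifnot(inherits(grid, "grid_spec"),
            all(c("sector", "amplitude", "corr_length_km", "aca_share") %in% names(sectors)),
            all(sectors$amplitude >= 0), all(sectors$corr_length_km > 0),
            all(sectors$aca_share >= 0 & sectors$aca_share <= 1),
            gamma >= 0, population_total > 0, n_countries >= 1, n_cities >= 1)
  if (!"BACKGROUND" %in% sectors$sector) stop("sectors must include BACKGROUND")
  structure(list(grid = grid, seed = as.integer(seed),
                 n_countries = as.integer(n_countries),
                 n_cities = as.integer(n_cities), sectors = sectors,
                 gamma = gamma, population_total = population_total,
                 clustering_exponent = clustering_exponent,
                 sea_margin = as.integer(sea_margin)),
            class = "synthetic_spec")
}

# city centers and weights shared by emissions and population; deterministic
sample_cities <- function(spec) {
  gx <- grid_x(spec$grid); gy <- grid_y(spec$grid)
  m <- spec$sea_margin * spec$grid$cell_size
  withr::with_seed(spec$seed, {
    data.frame(
      x = stats::runif(spec$n_cities, min(gx) + m, max(gx) - m),
      y = stats::runif(spec$n_cities, min(gy) + m, max(gy) - m),
      w = stats::rlnorm(spec$n_cities, meanlog = 0, sdlog = 0.6))
  })
}

# kernel-mixture surface on the grid: sum_c w_c exp(-d^2 / (2 L^2)), max 1
kernel_surface <- function(grid, cities, corr_length_km) {
  gx <- grid_x(grid); gy <- grid_y(grid)
  xm <- matrix(gx, grid$n_rows, grid$n_cols, byrow = TRUE)
  ym <- matrix(gy, grid$n_rows, grid$n_cols)
  s <- matrix(0, grid$n_rows, grid$n_cols)
  for (i in seq_len(nrow(cities))) {
    d2 <- (xm - cities$x[i])^2 + (ym - cities$y[i])^2
    s <- s + cities$w[i] * exp(-d2 / (2 * corr_length_km^2))
  }
  s / max(s)
}

#' Generate per-sector concentration fields
#'
#' Each emission sector contributes a smooth non-negative PM2.5 surface — a
#' Gaussian kernel mixture centered on the sampled city locations with the
#' sector's correlation length, scaled to its amplitude — and an aCA surface
#' equal to `aca_share` times its PM2.5. The `BACKGROUND` sector uses a much
#' longer correlation length plus a floor so the whole domain sits above
#' zero, standing in for long-range transport and natural aerosol.
#'
#' @param spec A [synthetic_spec()].
#' @return Named list, one entry per sector, each a list with [conc_field()]s
#'   `pm` and `aca` (scenario label = sector name).
#' @export
generate_sector_fields <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  cities <- sample_cities(spec)
  out <- list()
  for (i in seq_len(nrow(spec$sectors))) {
    sec <- spec$sectors$sector[i]
    amp <- spec$sectors$amplitude[i]
    L <- spec$sectors$corr_length_km[i]
    s <- kernel_surface(spec$grid, cities, L)
    if (sec == "BACKGROUND") s <- 0.55 + 0.45 * s # broad, never near zero
    pmv <- amp * s
    out[[sec]] <- list(
      pm = conc_field(spec$grid, "PM25", sec, pmv),
      aca = conc_field(spec$grid, "ACA", sec, spec$sectors$aca_share[i] * pmv))
  }
  out
}

#' Compose an emission scenario from sector fields
#'
#' Builds the PM2.5 and aCA fields of a scenario in which a fraction `r_s`
#' of each sector's emissions is removed:
#' `conc = sum_s (1 - r_s) * conc_s + gamma * I`, where the interaction term
#' `I = (sum_s (1 - r_s) * PM25_s)^2`, normalized by its domain maximum under
#' the full-emission composition, emulates non-linear secondary-aerosol
#' chemistry. The interaction is quadratic in each sector's retained
#' fraction, so `gamma = 0` gives exactly additive composition (BASE minus a
#' full removal recovers the sector field identically) while `gamma > 0`
#' breaks additivity by an amount that grows with `gamma`, which is what the
#' scenario-linearity diagnostic measures.
#'
#' @param sectors Output of [generate_sector_fields()].
#' @param reductions Named numeric vector, fraction removed in \[0, 1\] per
#'   sector; sectors not named are kept in full.
#' @param gamma Nonlinearity coefficient (ug/m3 contributed at the
#'   interaction maximum).
#' @param label Scenario label for the returned fields.
#' @return List with [conc_field()]s `pm` and `aca`.
#' @export
compose_scenario <- function(sectors, reductions = numeric(), gamma = 0,
                             label = "BASE") {
  stopifnot(is.list(sectors), length(sectors) >= 1)
  if (length(reductions)) {
    if (is.null(names(reductions)) || !all(names(reductions) %in% names(sectors)))
      stop("reductions must be named by generated sectors")
    if (any(reductions < 0 | reductions > 1))
      stop("reductions must lie in [0, 1]")
  }
  grid <- sectors[[1]]$pm$grid
  keep <- stats::setNames(rep(1, length(sectors)), names(sectors))
  keep[names(reductions)] <- 1 - reductions
  pm <- aca <- matrix(0, grid$n_rows, grid$n_cols)
  pm_full <- matrix(0, grid$n_rows, grid$n_cols)
  for (s in names(sectors)) {
    pm <- pm + keep[s] * sectors[[s]]$pm$values
    aca <- aca + keep[s] * sectors[[s]]$aca$values
    pm_full <- pm_full + sectors[[s]]$pm$values
  }
  if (gamma > 0) {
    norm <- max(pm_full^2)
    inter <- pm^2 / norm
    pm <- pm + gamma * inter
    # the interaction is combustion chemistry: give it the mean sectoral aCA share
    mean_share <- sum(vapply(names(sectors), function(s)
      keep[s] * sum(sectors[[s]]$aca$values), numeric(1))) /
      max(sum(pm - gamma * inter), .Machine$double.eps)
    aca <- aca + gamma * inter * mean_share
  }
  list(pm = conc_field(grid, "PM25", label, pm),
       aca = conc_field(grid, "ACA", label, aca))
}

#' Scenario set
#'
#' A named collection of PM2.5 + aCA field pairs on one grid, with `BASE`
#' required, enabling scenario differencing and the linearity diagnostic.
#'
#' @param fields Named list of lists with elements `pm` and `aca`
#'   ([conc_field()]s); must contain `BASE`.
#' @return Object of class `scenario_set`.
#' @export
scenario_set <- function(fields) {
  if (!"BASE" %in% names(fields)) stop("scenario set must contain BASE")
  g <- fields[[1]]$pm$grid
  for (nm in names(fields)) {
    f <- fields[[nm]]
    stopifnot(inherits(f$pm, "conc_field"), inherits(f$aca, "conc_field"))
    if (!same_grid(f$pm$grid, g) || !same_grid(f$aca$grid, g))
      stop("all scenario fields must share one grid")
  }
  structure(list(fields = fields, grid = g), class = "scenario_set")
}

# land = everything inside the sea margin
land_matrix <- function(spec) {
  g <- spec$grid; m <- spec$sea_margin
  land <- matrix(FALSE, g$n_rows, g$n_cols)
  land[(m + 1):(g$n_rows - m), (m + 1):(g$n_cols - m)] <- TRUE
  land
}

#' Generate a country mask
#'
#' Partitions the land cells (the domain minus a sea margin) into
#' `n_countries` contiguous blocks by nearest-seed (Voronoi) assignment of
#' deterministic seed points; each cell belongs wholly to one country.
#' Synthetic country codes are `XA`, `XB`, ... (a code range without
#' real-world assignments).
#'
#' @param spec A [synthetic_spec()].
#' @return A [country_mask()].
#' @export
generate_country_mask <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"), spec$n_countries <= 26)
  g <- spec$grid
  land <- land_matrix(spec)
  gx <- grid_x(g); gy <- grid_y(g)
  seeds <- withr::with_seed(spec$seed + 1L, {
    data.frame(x = stats::runif(spec$n_countries, min(gx), max(gx)),
               y = stats::runif(spec$n_countries, min(gy), max(gy)))
  })
  codes <- matrix(NA_character_, g$n_rows, g$n_cols)
  xm <- matrix(gx, g$n_rows, g$n_cols, byrow = TRUE)
  ym <- matrix(gy, g$n_rows, g$n_cols)
  d <- vapply(seq_len(spec$n_countries),
              function(i) as.vector((xm - seeds$x[i])^2 + (ym - seeds$y[i])^2),
              numeric(g$n_rows * g$n_cols))
  nearest <- max.col(-d) # ties broken by first seed, deterministic enough on continuous coords
  codes[land] <- paste0("X", LETTERS[nearest[as.vector(land)]])
  country_mask(g, codes)
}

#' Generate a clustered population grid
#'
#' Population density follows the city-kernel surface raised to the
#' clustering exponent, with multiplicative log-normal noise, zero outside
#' land, scaled to the requested total and split across the 12 adult age
#' classes with an old-skewed (European-like) age structure. Per-cell
#' per-age counts are integerized by rounding.
#'
#' @param spec A [synthetic_spec()].
#' @return A [population_grid()].
#' @export
generate_population <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  g <- spec$grid
  cities <- sample_cities(spec)
  base <- kernel_surface(g, cities, 20)^spec$clustering_exponent + 0.01
  noise <- withr::with_seed(spec$seed + 2L,
    matrix(stats::rlnorm(g$n_rows * g$n_cols, 0, 0.35), g$n_rows, g$n_cols))
  dens <- base * noise
  dens[!land_matrix(spec)] <- 0
  total_cell <- dens / sum(dens) * spec$population_total
  shares <- c(0.085, 0.085, 0.085, 0.090, 0.095, 0.095,
              0.090, 0.085, 0.080, 0.075, 0.065, 0.070)
  ages <- adult_age_classes()
  vals <- array(0, dim = c(g$n_rows, g$n_cols, length(ages)),
                dimnames = list(NULL, NULL, ages))
  for (k in seq_along(ages)) vals[, , k] <- round(total_cell * shares[k])
  population_grid(g, vals)
}

#' Generate a baseline mortality table
#'
#' Cause- and age-specific rates (deaths per person per year) for every
#' country in the mask: a per-cause base rate drawn within a plausible
#' range, multiplied by an exponential age gradient (rates rise steeply with
#' age, as for the chronic causes considered) and a per-country level
#' multiplier. Coverage is complete over countries x 6 causes x 12 ages.
#'
#' @param spec A [synthetic_spec()].
#' @param countries Character vector of country codes (normally the mask's
#'   registry).
#' @return A [bmr_table()].
#' @export
generate_bmr <- function(spec, countries) {
  stopifnot(inherits(spec, "synthetic_spec"), length(countries) >= 1)
  ranges <- list( # base rate at ages 60-64, deaths/person/yr
    IHD = c(1.5e-3, 4e-3), STROKE = c(1e-3, 2.5e-3), COPD = c(5e-4, 1.5e-3),
    LC = c(5e-4, 1.2e-3), LRI = c(2e-4, 6e-4), T2D = c(2e-4, 8e-4))
  ages <- adult_age_classes()
  age_mid <- c(seq(27, 77, by = 5), 85)
  withr::with_seed(spec$seed + 3L, {
    rows <- list()
    cmult <- stats::runif(length(countries), 0.8, 1.25)
    names(cmult) <- countries
    for (cause in names(ranges)) {
      base <- stats::runif(1, ranges[[cause]][1], ranges[[cause]][2])
      grad <- exp(0.085 * (age_mid - 62)) # Gompertz-like rise with age
      for (co in countries)
        rows[[paste(cause, co)]] <- data.frame(
          country = co, cause = cause, age_group = ages,
          rate = base * grad * cmult[co], stringsAsFactors = FALSE)
    }
    bmr_table(do.call(rbind, rows), countries = countries)
  })
}

#' Generate a set of exposure-response curves
#'
#' Tabulated curves with the qualitative shape of the MR-BRT splines:
#' monotone non-decreasing, RR = 1 at the TMREL after anchoring, and
#' supralinear (concave) at low-to-moderate concentrations, via the
#' saturating form RR_raw(c) = 1 + a (1 - exp(-c/s)). The low/high branches
#' scale `a` by 0.7 / 1.3. For the age-dependent causes (IHD, stroke) one
#' curve per age class is produced with risk declining with age; other
#' causes get a single `ALL`-age curve.
#'
#' @param spec A [synthetic_spec()].
#' @param tmrel TMREL (ug/m3) used to anchor the curves.
#' @return An [erf_set()] of TMREL-scaled [tabulated_erf()]s.
#' @export
generate_erfs <- function(spec, tmrel = TMREL_DEFAULT) {
  stopifnot(inherits(spec, "synthetic_spec"))
  knots <- c(0, 2, tmrel, 6, 8, 10, 12.5, 15, 20, 25, 30, 40, 50, 75, 100)
  amp <- c(IHD = 1.1, STROKE = 0.9, COPD = 0.55, LC = 0.5, LRI = 0.45, T2D = 0.65)
  sat <- c(IHD = 22, STROKE = 20, COPD = 18, LC = 25, LRI = 16, T2D = 12)
  reg <- cause_registry()
  ages <- adult_age_classes()
  curves <- list()
  withr::with_seed(spec$seed + 4L, {
    jitter_a <- stats::runif(nrow(reg), 0.9, 1.1)
    for (j in seq_len(nrow(reg))) {
      cause <- reg$code[j]
      a0 <- amp[[cause]] * jitter_a[j]
      s <- sat[[cause]]
      mk <- function(a, age_group) {
        raw <- function(f) 1 + f * a * (1 - exp(-knots / s))
        scale_to_tmrel(tabulated_erf(cause, age_group, knots,
                                     raw(1), raw(0.7), raw(1.3), tmrel = tmrel))
      }
      if (reg$age_dependent[j]) {
        for (k in seq_along(ages)) # risk declines with age, as in cardiovascular curves
          curves[[paste(cause, ages[k])]] <- mk(a0 * exp(-0.055 * (k - 1)), ages[k])
      } else {
        curves[[paste(cause, "ALL")]] <- mk(a0, "ALL")
      }
    }
  })
  erf_set(curves)
}

#' Generate a complete synthetic study
#'
#' Produces every input the pipeline needs — the five canonical emission
#' scenarios (BASE, RES100, RES20, TRA100, TRA20) composed from the sector
#' fields, the population grid, country mask, baseline mortality table and
#' exposure-response curves — all deterministic functions of the spec's
#' seed.
#'
#' @param spec A [synthetic_spec()].
#' @return List of class `synthetic_study` with elements `spec`, `sectors`,
#'   `scenarios` (a [scenario_set()]), `population`, `mask`, `bmr`, `erfs`.
#' @export
generate_study <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  sectors <- generate_sector_fields(spec)
  sc <- list(
    BASE = compose_scenario(sectors, gamma = spec$gamma, label = "BASE"),
    RES100 = compose_scenario(sectors, c(RES = 1), spec$gamma, "RES100"),
    RES20 = compose_scenario(sectors, c(RES = 0.2), spec$gamma, "RES20"),
    TRA100 = compose_scenario(sectors, c(TRA = 1), spec$gamma, "TRA100"),
    TRA20 = compose_scenario(sectors, c(TRA = 0.2), spec$gamma, "TRA20"))
  mask <- generate_country_mask(spec)
  structure(list(spec = spec, sectors = sectors, scenarios = scenario_set(sc),
                 population = generate_population(spec), mask = mask,
                 bmr = generate_bmr(spec, mask$countries),
                 erfs = generate_erfs(spec)),
            class = "synthetic_study")
}
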