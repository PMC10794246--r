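#' Baseline mortality rate table
#'
#' Country-level cause- and age-specific baseline mortality rates
#' (deaths per person per year), broadcast to grid cells through the country
#' mask. Rates are country-resolution, as obtained from national burden
#' tables; no sub-national variation.
#'
#' @param df `data.frame` with columns `country`, `cause`, `age_group`,
#'   `rate` (>= 0).
#' @param countries Optional country registry; when given, the table must be
#'   complete over `countries` x 6 causes x 12 age groups.
#' @return The validated `data.frame`, classed `bmr_table`.
#' @export
bmr_table <- function(df, countries = NULL) {
  need <- c("country", "cause", "age_group", "rate")
  if (!all(need %in% names(df))) stop("bmr table needs columns ", paste(need, collapse = ", "))
  if (any(df$rate < 0) || any(!is.finite(df$rate))) stop("rates must be finite and >= 0")
  bad <- !df$cause %in% cause_registry()$code
  if (any(bad)) stop("unknown cause in bmr table: ", paste(unique(df$cause[bad]), collapse = ", "))
  bad <- !df$age_group %in% adult_age_classes()
  if (any(bad)) stop("unknown age group in bmr table: ", paste(unique(df$age_group[bad]), collapse = ", "))
  if (!is.null(countries)) {
    full <- expand.grid(country = countries, cause = cause_registry()$code,
                        age_group = adult_age_classes(), stringsAsFactors = FALSE)
    key <- function(d) paste(d$country, d$cause, d$age_group, sep = "|")
    miss <- setdiff(key(full), key(df))
    if (length(miss))
      stop("bmr table incomplete; missing (country, cause, age): ",
           paste(utils::head(miss, 5), collapse = "; "),
           if (length(miss) > 5) sprintf(" ... and %d more", length(miss) - 5) else "")
  }
  class(df) <- c("bmr_table", "data.frame")
  df
}

rr_branches <- function() c("central", "low", "high")

#' Gridded excess-mortality result
#'
#' Excess deaths per year per cell, stratified by cause, age class and
#' uncertainty branch, for one scenario.
#'
#' @param grid A [grid_spec()].
#' @param scenario Scenario label.
#' @param values 5-d array `[row, col, cause, age, branch]` with dimnames for
#'   the last three dimensions.
#' @return Object of class `mortality_result`.
#' @export
mortality_result <- function(grid, scenario, values) {
  stopifnot(inherits(grid, "grid_spec"), length(dim(values)) == 5)
  dn <- dimnames(values)
  stopifnot(identical(dn[[3]], cause_registry()$code),
            identical(dn[[4]], adult_age_classes()),
            identical(dn[[5]], rr_branches()))
  if (any(values < 0)) stop("excess deaths must be >= 0")
  structure(list(grid = grid, scenario = as.character(scenario), values = values),
            class = "mortality_result")
}

#' @export
print.mortality_result <- function(x, ...) {
  tot <- apply(x$values, 5, sum)
  cat(sprintf("<mortality_result> %s on %d x %d grid: %.0f deaths/yr (central; low %.0f, high %.0f)\n",
              x$scenario, x$grid$n_rows, x$grid$n_cols,
              tot["central"], tot["low"], tot["high"]))
  invisible(x)
}

# per-cell rate matrix for one (cause, age): broadcast country rates via mask
rate_matrix <- function(rates_lookup, mask, cause, age_group) {
  key <- paste(cause, age_group, sep = "|")
  tab <- rates_lookup[[key]]
  m <- matrix(0, mask$grid$n_rows, mask$grid$n_cols)
  inl <- !is.na(mask$codes)
  r <- tab[mask$codes[inl]]
  if (any(is.na(r))) {
    miss <- unique(mask$codes[inl][is.na(r)])
    stop(sprintf("missing baseline mortality rate for (%s, %s, %s)",
                 paste(miss, collapse = ","), cause, age_group))
  }
  m[inl] <- r
  m
}

#' Gridded cause- and age-stratified excess mortality
#'
#' For every cell, cause j, age class k and uncertainty branch, computes
#' deaths = BMR(country(cell), j, k) x POP(cell, k) x AF(RR(conc(cell))),
#' where AF = (RR - 1)/RR and RR comes from the TMREL-anchored
#' exposure-response curve for (j, k). Cells at or below the TMREL, and
#' cells outside the country mask (sea), contribute zero. Accumulation is in
#' double precision; no rounding is applied here.
#'
#' @param conc A [conc_field()] with species `PM25`.
#' @param pop A [population_grid()] on the same grid.
#' @param bmr A [bmr_table()] covering every masked country.
#' @param erfs An [erf_set()] covering all (cause, age) strata
#'   (`ALL`-age curves apply to every age class).
#' @param mask A [country_mask()] on the same grid.
#' @return A [mortality_result()] for the field's scenario.
#' @export
gridded_excess_mortality <- function(conc, pop, bmr, erfs, mask) {
  stopifnot(inherits(conc, "conc_field"), conc$species == "PM25",
            inherits(pop, "population_grid"), inherits(mask, "country_mask"),
            inherits(erfs, "erf_set"))
  if (!same_grid(conc$grid, pop$grid) || !same_grid(conc$grid, mask$grid))
    stop("conc, pop and mask must share one grid")
  bmr <- bmr_table(as.data.frame(bmr))
  causes <- cause_registry()
  ages <- adult_age_classes()
  branches <- rr_branches()

  # fast (cause|age) -> named country rate vector
  rates_lookup <- split(stats::setNames(bmr$rate, bmr$country),
                        paste(bmr$cause, bmr$age_group, sep = "|"))
  rates_lookup <- lapply(rates_lookup, function(v) v[!duplicated(names(v))])

  nr <- conc$grid$n_rows; nc <- conc$grid$n_cols
  vals <- array(0, dim = c(nr, nc, nrow(causes), length(ages), length(branches)),
                dimnames = list(NULL, NULL, causes$code, ages, branches))
  inmask <- !is.na(mask$codes)
  cv <- conc$values

  for (j in seq_len(nrow(causes))) {
    cause <- causes$code[j]
    for (b in seq_along(branches)) {
      af_all <- NULL # cache for age-invariant causes
      for (k in seq_along(ages)) {
        erf <- get_erf(erfs, cause, ages[k])
        if (!causes$age_dependent[j] && !is.null(af_all)) {
          af <- af_all
        } else {
          rr <- risk_rr(erf, as.vector(cv), branches[b])
          af <- matrix(attributable_fraction(rr), nr, nc)
          if (!causes$age_dependent[j]) af_all <- af
        }
        rm_ <- rate_matrix(rates_lookup, mask, cause, ages[k])
        d <- rm_ * pop$values[, , k] * af
        d[!inmask] <- 0
        vals[, , j, k, b] <- d
      }
    }
  }
  mortality_result(conc$grid, conc$scenario, vals)
}

#' Aggregate a mortality result over cells and strata
#'
#' Marginal sums of excess deaths over any combination of country, cause,
#' age class and uncertainty branch. The grand total is invariant under the
#' choice of `by`.
#'
#' @param m A [mortality_result()].
#' @param mask A [country_mask()]; required when `"country" %in% by`.
#' @param by Character subset of `c("country", "cause", "age_group",
#'   "branch")`; empty (the default) gives a single grand-total row.
#' @return `data.frame` with the `by` columns plus `deaths`.
#' @export
aggregate_mortality <- function(m, mask = NULL, by = character()) {
  stopifnot(inherits(m, "mortality_result"))
  ok <- c("country", "cause", "age_group", "branch")
  if (!all(by %in% ok)) stop("by must be a subset of ", paste(ok, collapse = ", "))
  if ("country" %in% by) {
    if (is.null(mask)) stop("aggregating by country requires a mask")
    stopifnot(inherits(mask, "country_mask"))
    if (!same_grid(m$grid, mask$grid)) stop("result and mask grids differ")
  }
  dims <- c(cause = 3L, age_group = 4L, branch = 5L)
  keep <- dims[intersect(c("cause", "age_group", "branch"), by)]
  if ("country" %in% by) {
    # collapse cells within each country, then the retained strata
    cc <- mask$codes
    out <- lapply(mask$countries, function(co) {
      idx <- which(!is.na(cc) & cc == co)
      sub <- apply(m$values, 3:5, function(sl) sum(sl[idx]))
      flat <- if (length(keep)) apply(sub, keep - 2L, sum) else sum(sub)
      cbind(country = co, strata_frame(flat, names(keep)))
    })
    res <- do.call(rbind, out)
  } else {
    flat <- if (length(keep)) apply(m$values, keep, sum) else sum(m$values)
    res <- strata_frame(flat, names(keep))
  }
  rownames(res) <- NULL
  res
}

# turn an n-d named-dim array (or scalar) of sums into a long data.frame
strata_frame <- function(x, dim_names) {
  if (!length(dim_names)) return(data.frame(deaths = as.numeric(x)))
  if (is.null(dim(x))) x <- array(x, dim = length(x), dimnames = list(names(x)))
  g <- expand.grid(dimnames(x), stringsAsFactors = FALSE)
  names(g) <- dim_names
  g$deaths <- as.vector(x)
  g
}
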