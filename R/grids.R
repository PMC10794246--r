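#' Grid specification
#'
#' Defines a regular, axis-aligned raster grid in a single planar projection.
#' Grids are cell-center registered: `origin` is the (x, y) coordinate of the
#' center of the lower-left cell, and cell centers advance by `cell_size`
#' eastwards (columns) and northwards (rows). Values on a grid are stored as an
#' `n_rows x n_cols` matrix whose first row is the southernmost row.
#'
#' @param n_rows,n_cols Number of rows (south to north) and columns (west to
#'   east); both at least 1.
#' @param cell_size Cell edge length in km; must be positive.
#' @param origin Numeric length-2: x and y of the lower-left cell center (km).
#' @return An object of class `grid_spec`.
#' @examples
#' gs <- grid_spec(60, 60, cell_size = 5)
#' @export
grid_spec <- function(n_rows, n_cols, cell_size, origin = c(0, 0)) {
  stopifnot(length(n_rows) == 1, length(n_cols) == 1, length(cell_size) == 1,
            length(origin) == 2, is.numeric(origin))
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (is.na(n_rows) || is.na(n_cols) || n_rows < 1L || n_cols < 1L)
    stop("n_rows and n_cols must be integers >= 1")
  if (!is.finite(cell_size) || cell_size <= 0)
    stop("cell_size must be positive")
  structure(
    list(n_rows = n_rows, n_cols = n_cols,
         cell_size = as.numeric(cell_size), origin = as.numeric(origin)),
    class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells of %g km, lower-left center (%g, %g)\n",
              x$n_rows, x$n_cols, x$cell_size, x$origin[1], x$origin[2]))
  invisible(x)
}

#' @export
`==.grid_spec` <- function(e1, e2) {
  inherits(e1, "grid_spec") && inherits(e2, "grid_spec") &&
    e1$n_rows == e2$n_rows && e1$n_cols == e2$n_cols &&
    isTRUE(all.equal(e1$cell_size, e2$cell_size)) &&
    isTRUE(all.equal(e1$origin, e2$origin))
}

#' Cell-center coordinates of a grid
#'
#' @param grid A [grid_spec()].
#' @return `grid_x`: x coordinates of the `n_cols` column centers;
#'   `grid_y`: y coordinates of the `n_rows` row centers (ascending, row 1
#'   southernmost).
#' @export
grid_x <- function(grid) grid$origin[1] + (seq_len(grid$n_cols) - 1) * grid$cell_size

#' @rdname grid_x
#' @export
grid_y <- function(grid) grid$origin[2] + (seq_len(grid$n_rows) - 1) * grid$cell_size

same_grid <- function(a, b) isTRUE(a == b)

check_values_matrix <- function(values, grid, what = "values") {
  if (!is.matrix(values) || nrow(values) != grid$n_rows || ncol(values) != grid$n_cols)
    stop(sprintf("%s must be a %d x %d matrix matching the grid",
                 what, grid$n_rows, grid$n_cols))
  invisible(values)
}

#' Gridded annual-mean concentration field
#'
#' A per-cell annual-mean mass concentration (ug/m3) of one aerosol species
#' under one emission scenario.
#'
#' @param grid A [grid_spec()].
#' @param species `"PM25"` (total fine particulate matter) or `"ACA"`
#'   (anthropogenic carbonaceous aerosol: black carbon plus primary and
#'   anthropogenic secondary organic aerosol).
#' @param scenario Scenario label; the canonical set is `BASE`, `RES100`,
#'   `RES20`, `TRA100`, `TRA20`, but any label is accepted.
#' @param values `n_rows x n_cols` matrix of non-negative, finite
#'   concentrations (ug/m3); row 1 is the southernmost row.
#' @return An object of class `conc_field`.
#' @export
conc_field <- function(grid, species = c("PM25", "ACA"), scenario, values) {
  stopifnot(inherits(grid, "grid_spec"))
  species <- match.arg(species)
  check_values_matrix(values, grid)
  if (any(!is.finite(values)) || any(values < 0))
    stop("concentration values must be finite and >= 0")
  structure(list(grid = grid, species = species,
                 scenario = as.character(scenario), values = values),
            class = "conc_field")
}

#' @export
print.conc_field <- function(x, ...) {
  cat(sprintf("<conc_field> %s / %s on %d x %d grid; range [%.3g, %.3g] ug/m3\n",
              x$species, x$scenario, x$grid$n_rows, x$grid$n_cols,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Adult age classes
#'
#' The twelve 5-year adult age classes used throughout: 25-29 up to 75-79,
#' then 80plus. Mortality is computed for adults (> 25 years) only.
#'
#' @return Character vector of the 12 ordered class labels.
#' @export
adult_age_classes <- function() {
  c("25-29", "30-34", "35-39", "40-44", "45-49", "50-54",
    "55-59", "60-64", "65-69", "70-74", "75-79", "80plus")
}

#' Gridded population by adult age class
#'
#' @param grid A [grid_spec()].
#' @param values `n_rows x n_cols x 12` array of persons per cell per age
#'   class; the third dimension must be named with [adult_age_classes()].
#' @return An object of class `population_grid`.
#' @export
population_grid <- function(grid, values) {
  stopifnot(inherits(grid, "grid_spec"))
  ages <- adult_age_classes()
  if (!is.array(values) || length(dim(values)) != 3 ||
      !all(dim(values)[1:2] == c(grid$n_rows, grid$n_cols)) ||
      dim(values)[3] != length(ages))
    stop("values must be an n_rows x n_cols x 12 array")
  dn <- dimnames(values)[[3]]
  if (is.null(dn)) dimnames(values)[[3]] <- ages
  else if (!identical(dn, ages)) stop("age classes must be exactly the 12 adult classes, in order")
  if (any(!is.finite(values)) || any(values < 0))
    stop("population values must be finite and >= 0")
  structure(list(grid = grid, values = values), class = "population_grid")
}

#' Total adult population per cell
#'
#' @param pop A [population_grid()].
#' @param ages Optional subset of [adult_age_classes()] to sum over; by
#'   default all twelve classes (total adult population).
#' @return `n_rows x n_cols` matrix of persons.
#' @export
population_total <- function(pop, ages = NULL) {
  stopifnot(inherits(pop, "population_grid"))
  if (is.null(ages)) ages <- adult_age_classes()
  if (!all(ages %in% adult_age_classes())) stop("unknown age class")
  apply(pop$values[, , ages, drop = FALSE], c(1, 2), sum)
}

#' Country mask
#'
#' Assigns each grid cell wholly to one country (two-letter code) or to the
#' sentinel `NA` for sea / out-of-domain cells; no fractional border cells.
#'
#' @param grid A [grid_spec()].
#' @param codes `n_rows x n_cols` character matrix of country codes, `NA`
#'   for cells outside any country.
#' @return An object of class `country_mask` with a `countries` element
#'   listing the codes present (the run's country registry).
#' @export
country_mask <- function(grid, codes) {
  stopifnot(inherits(grid, "grid_spec"))
  check_values_matrix(codes, grid, "codes")
  if (!is.character(codes)) stop("codes must be a character matrix")
  structure(list(grid = grid, codes = codes,
                 countries = sort(unique(codes[!is.na(codes)]))),
            class = "country_mask")
}

#' Regrid a concentration field
#'
#' Interpolates a field from its native grid onto a target grid (typically
#' from a coarse chemical-transport model grid to the finer health-calculation
#' grid). `bilinear` interpolates between the four surrounding source cell
#' centers and is the default for smooth annual-mean concentrations;
#' `nearest` copies the closest source cell and is appropriate for
#' categorical rasters.
#'
#' @param field A [conc_field()].
#' @param target A [grid_spec()] whose cell centers all lie within the
#'   bounding box of the source cell centers.
#' @param method `"bilinear"` or `"nearest"`.
#' @return A [conc_field()] on `target` with the same species and scenario.
#'   Output values are bounded by the range of the input values.
#' @export
regrid_field <- function(field, target, method = c("bilinear", "nearest")) {
  stopifnot(inherits(field, "conc_field"), inherits(target, "grid_spec"))
  method <- match.arg(method)
  sx <- grid_x(field$grid); sy <- grid_y(field$grid)
  tx <- grid_x(target);     ty <- grid_y(target)
  if (min(tx) < min(sx) || max(tx) > max(sx) ||
      min(ty) < min(sy) || max(ty) > max(sy))
    stop("target grid extent exceeds source grid extent")
  if (method == "bilinear") {
    if (length(sx) == 1 && length(sy) == 1) {
      out <- matrix(field$values[1, 1], target$n_rows, target$n_cols)
    } else if (length(sy) == 1) {
      # single source row: linear interpolation along x only
      v <- stats::approx(sx, field$values[1, ], xout = tx)$y
      out <- matrix(v, target$n_rows, target$n_cols, byrow = TRUE)
    } else if (length(sx) == 1) {
      v <- stats::approx(sy, field$values[, 1], xout = ty)$y
      out <- matrix(v, target$n_rows, target$n_cols)
    } else {
      pts <- expand.grid(x = tx, y = ty) # varies x fastest
      v <- pracma::interp2(x = sx, y = sy, Z = field$values,
                           xp = pts$x, yp = pts$y, method = "linear")
      out <- matrix(v, nrow = target$n_rows, ncol = target$n_cols, byrow = TRUE)
    }
  } else {
    ci <- pmin(pmax(round((tx - sx[1]) / field$grid$cell_size) + 1, 1), length(sx))
    ri <- pmin(pmax(round((ty - sy[1]) / field$grid$cell_size) + 1, 1), length(sy))
    out <- field$values[ri, ci, drop = FALSE]
  }
  conc_field(target, field$species, field$scenario, out)
}

mask_cells <- function(mask, country) {
  idx <- which(!is.na(mask$codes) & mask$codes == country)
  if (length(idx) == 0) stop(sprintf("country '%s' has no cells in the mask", country))
  idx
}

#' Population-weighted mean concentration for a country
#'
#' The exposure metric relevant to health burden: the concentration averaged
#' over a country's cells with the (adult) population as weights.
#'
#' @param conc A [conc_field()].
#' @param pop A [population_grid()] on the same grid.
#' @param mask A [country_mask()] on the same grid.
#' @param country Country code present in `mask`.
#' @param ages Optional subset of age classes used as weights; default is the
#'   total adult population.
#' @return Scalar concentration (ug/m3).
#' @export
population_weighted_mean <- function(conc, pop, mask, country, ages = NULL) {
  stopifnot(inherits(conc, "conc_field"), inherits(pop, "population_grid"),
            inherits(mask, "country_mask"))
  if (!same_grid(conc$grid, pop$grid) || !same_grid(conc$grid, mask$grid))
    stop("conc, pop and mask must share one grid")
  idx <- mask_cells(mask, country)
  w <- population_total(pop, ages)[idx]
  if (sum(w) <= 0)
    stop(sprintf("country '%s' has zero total population: weighted mean undefined", country))
  sum(conc$values[idx] * w) / sum(w)
}

#' Mass fraction of carbonaceous aerosol in PM2.5
#'
#' Per-cell ratio aCA / PM2.5, clamped to \[0, 1\]. Cells with zero PM2.5
#' yield a fraction of 0 (with a warning), keeping the attribution
#' well-defined on empty cells.
#'
#' @param aca A [conc_field()] with species `ACA`.
#' @param pm A [conc_field()] with species `PM25`, same grid and scenario.
#' @return `n_rows x n_cols` matrix of fractions in \[0, 1\].
#' @export
aca_fraction <- function(aca, pm) {
  stopifnot(inherits(aca, "conc_field"), inherits(pm, "conc_field"))
  if (aca$species != "ACA" || pm$species != "PM25")
    stop("expected species ACA and PM25")
  if (!same_grid(aca$grid, pm$grid) || !identical(aca$scenario, pm$scenario))
    stop("aca and pm fields are not aligned (grid or scenario mismatch)")
  f <- matrix(0, nrow(pm$values), ncol(pm$values))
  nz <- pm$values > 0
  if (any(!nz & aca$values > 0))
    warning("cells with aCA > 0 but PM2.5 = 0 set to fraction 0")
  f[nz] <- aca$values[nz] / pm$values[nz]
  pmin(pmax(f, 0), 1)
}

#' Aggregate a gridded quantity to countries
#'
#' @param values `n_rows x n_cols` matrix (or a [conc_field()]).
#' @param mask A [country_mask()] on the same grid.
#' @param reducer `"sum"` (for extensive quantities such as deaths) or
#'   `"pop_weighted_mean"` (for intensive quantities such as concentration).
#' @param pop A [population_grid()]; required for `pop_weighted_mean`.
#' @return `data.frame` with columns `country` and `value`, one row per
#'   country present in the mask (countries with no cells are absent, not
#'   zero). With the `sum` reducer the rows add up to the in-mask domain
#'   total.
#' @export
country_aggregate <- function(values, mask, reducer = c("sum", "pop_weighted_mean"),
                              pop = NULL) {
  reducer <- match.arg(reducer)
  stopifnot(inherits(mask, "country_mask"))
  if (inherits(values, "conc_field")) {
    if (!same_grid(values$grid, mask$grid)) stop("field and mask grids differ")
    values <- values$values
  }
  check_values_matrix(values, mask$grid)
  if (reducer == "pop_weighted_mean") {
    if (is.null(pop)) stop("reducer 'pop_weighted_mean' requires pop")
    stopifnot(inherits(pop, "population_grid"))
    if (!same_grid(pop$grid, mask$grid)) stop("pop and mask grids differ")
    w <- population_total(pop)
  }
  out <- lapply(mask$countries, function(cc) {
    idx <- which(!is.na(mask$codes) & mask$codes == cc)
    v <- if (reducer == "sum") sum(values[idx]) else {
      if (sum(w[idx]) <= 0)
        stop(sprintf("country '%s' has zero total population: weighted mean undefined", cc))
      sum(values[idx] * w[idx]) / sum(w[idx])
    }
    data.frame(country = cc, value = v, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
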