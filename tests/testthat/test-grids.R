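test_that("grid_spec validates its fields and compares by value", {
  g <- grid_spec(4, 6, 5, origin = c(10, 20))
  expect_equal(g$n_rows, 4L)
  expect_equal(grid_x(g), 10 + 5 * 0:5)
  expect_equal(grid_y(g), 20 + 5 * 0:3)
  expect_true(g == grid_spec(4, 6, 5, origin = c(10, 20)))
  expect_false(g == grid_spec(4, 6, 5, origin = c(0, 20)))
  expect_false(g == grid_spec(4, 6, 10, origin = c(10, 20)))
  expect_error(grid_spec(0, 6, 5), "n_rows")
  expect_error(grid_spec(4, 6, -1), "cell_size")
})

test_that("conc_field rejects negative, non-finite or misshaped values", {
  g <- grid_spec(2, 2, 5)
  expect_error(conc_field(g, "PM25", "BASE", matrix(-1, 2, 2)), "finite and >= 0")
  expect_error(conc_field(g, "PM25", "BASE", matrix(NA_real_, 2, 2)), "finite")
  expect_error(conc_field(g, "PM25", "BASE", matrix(1, 3, 2)), "matrix")
})

test_that("regridding a constant field is exact for both methods", {
  src <- grid_spec(5, 5, 20)                      # 0..80 km centers
  tgt <- grid_spec(13, 13, 5, origin = c(10, 10)) # 10..70 km, inside source
  f <- const_field(src, 10)
  for (m in c("bilinear", "nearest")) {
    out <- regrid_field(f, tgt, m)
    expect_true(all(out$values == 10))
    expect_equal(out$species, "PM25")
    expect_equal(out$scenario, "BASE")
  }
})

test_that("bilinear regridding matches hand interpolation", {
  # 1 x 2 source cells (10, 20): midway point interpolates to 15
  src <- grid_spec(1, 2, 20)
  f <- conc_field(src, "PM25", "BASE", matrix(c(10, 20), 1, 2))
  tgt <- grid_spec(1, 1, 1, origin = c(10, 0))
  expect_equal(regrid_field(f, tgt, "bilinear")$values[1, 1], 15)

  # affine-in-coordinates field reproduced exactly at target cell centers
  src <- grid_spec(3, 3, 20)
  affine <- function(x, y) 2 + 0.3 * x + 0.1 * y
  vals <- outer(grid_y(src), grid_x(src), function(y, x) affine(x, y))
  f <- conc_field(src, "PM25", "BASE", vals)
  tgt <- grid_spec(7, 7, 5, origin = c(5, 5))
  out <- regrid_field(f, tgt, "bilinear")
  expected <- outer(grid_y(tgt), grid_x(tgt), function(y, x) affine(x, y))
  expect_equal(out$values, expected, tolerance = 1e-12)
  # bounded by the source range
  expect_gte(min(out$values), min(f$values))
  expect_lte(max(out$values), max(f$values))
})

test_that("nearest regridding only emits values present in the source", {
  src <- grid_spec(4, 4, 20)
  f <- conc_field(src, "PM25", "BASE", matrix(runif(16, 0, 30), 4, 4))
  tgt <- grid_spec(9, 9, 6, origin = c(3, 3))
  out <- regrid_field(f, tgt, "nearest")
  expect_true(all(out$values %in% f$values))
})

test_that("regridding outside the source extent is an error", {
  src <- grid_spec(3, 3, 20)
  f <- const_field(src, 1)
  expect_error(regrid_field(f, grid_spec(3, 3, 20, origin = c(-20, 0))), "extent")
  expect_error(regrid_field(f, grid_spec(10, 3, 5, origin = c(0, 0))), "extent")
})

make_pop <- function(grid, per_cell) {
  ages <- adult_age_classes()
  vals <- array(0, dim = c(grid$n_rows, grid$n_cols, 12),
                dimnames = list(NULL, NULL, ages))
  vals[, , 1] <- per_cell
  population_grid(grid, vals)
}

test_that("population-weighted mean follows the weights", {
  g <- grid_spec(1, 2, 5)
  mask <- country_mask(g, matrix("XA", 1, 2))
  pop <- make_pop(g, matrix(c(1, 3), 1, 2))
  c1 <- conc_field(g, "PM25", "BASE", matrix(c(10, 20), 1, 2))
  expect_equal(population_weighted_mean(c1, pop, mask, "XA"), 17.5)
  # constant concentration: weights irrelevant
  expect_equal(population_weighted_mean(const_field(g, 10), pop, mask, "XA"), 10)
  # degenerate weights: population in one cell only
  pop1 <- make_pop(g, matrix(c(0, 5), 1, 2))
  expect_equal(population_weighted_mean(c1, pop1, mask, "XA"), 20)
  # invariant under uniform scaling of population
  popk <- make_pop(g, matrix(c(1, 3) * 1234, 1, 2))
  expect_equal(population_weighted_mean(c1, popk, mask, "XA"),
               population_weighted_mean(c1, pop, mask, "XA"))
  # zero population is undefined, not zero
  pop0 <- make_pop(g, matrix(0, 1, 2))
  expect_error(population_weighted_mean(c1, pop0, mask, "XA"), "undefined")
})

test_that("aca_fraction divides, clamps and zeroes empty cells", {
  g <- grid_spec(1, 3, 5)
  pm <- conc_field(g, "PM25", "BASE", matrix(c(10, 10, 0), 1, 3))
  aca <- conc_field(g, "ACA", "BASE", matrix(c(2, 12, 1), 1, 3))
  f <- suppressWarnings(aca_fraction(aca, pm))
  expect_equal(f[1, 1], 0.2)
  expect_equal(f[1, 2], 1)   # pathological aCA > PM2.5 clamps to 1
  expect_equal(f[1, 3], 0)   # PM2.5 = 0 yields 0
  expect_warning(aca_fraction(aca, pm), "PM2.5 = 0")
  zero <- conc_field(g, "ACA", "BASE", matrix(0, 1, 3))
  expect_true(all(suppressWarnings(aca_fraction(zero, pm)) == 0))
  # alignment and species checks
  expect_error(aca_fraction(pm, pm), "species")
  aca2 <- conc_field(g, "ACA", "RES100", matrix(1, 1, 3))
  expect_error(aca_fraction(aca2, pm), "aligned")
})

test_that("country aggregation partitions the domain", {
  g <- grid_spec(1, 3, 5)
  mask <- country_mask(g, matrix(c("XA", "XA", "XB"), 1, 3))
  vals <- matrix(c(1, 2, 3), 1, 3)
  out <- country_aggregate(vals, mask, "sum")
  expect_equal(out$value[out$country == "XA"], 3)
  expect_equal(out$value[out$country == "XB"], 3)
  expect_equal(sum(out$value), sum(vals)) # partition: no sea cells here

  # with sea cells, in-mask rows plus out-of-mask total equal the grid total
  mask2 <- country_mask(g, matrix(c("XA", NA, "XB"), 1, 3))
  out2 <- country_aggregate(vals, mask2, "sum")
  expect_equal(sum(out2$value) + vals[1, 2], sum(vals), tolerance = 1e-9)
  # an absent country is absent, not zero
  expect_false("XC" %in% out2$country)
  # pop_weighted_mean without pop is an argument error
  expect_error(country_aggregate(vals, mask, "pop_weighted_mean"), "requires pop")
})

test_that("sector fields round-trip through aca_fraction", {
  st <- tiny_study()
  for (s in c("RES", "TRA", "OTHER")) {
    share <- st$spec$sectors$aca_share[st$spec$sectors$sector == s]
    f <- aca_fraction(st$sectors[[s]]$aca, st$sectors[[s]]$pm)
    nz <- st$sectors[[s]]$pm$values > 0
    expect_equal(unname(f[nz]), rep(share, sum(nz)), tolerance = 1e-12)
  }
})
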