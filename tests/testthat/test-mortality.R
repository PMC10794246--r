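test_that("bmr_table validates coverage and names the missing stratum", {
  st <- tiny_study()
  expect_s3_class(st$bmr, "bmr_table")
  cut <- as.data.frame(st$bmr)
  cut <- cut[!(cut$country == st$mask$countries[1] & cut$cause == "LC" &
                 cut$age_group == "60-64"), ]
  expect_error(bmr_table(cut, st$mask$countries), "LC")
  expect_error(bmr_table(transform(cut, rate = -rate)), ">= 0")
})

test_that("concentrations at or below the TMREL produce zero mortality", {
  st <- tiny_study()
  low <- const_field(st$scenarios$grid, TMREL_DEFAULT)
  m <- gridded_excess_mortality(low, st$population, st$bmr, st$erfs, st$mask)
  expect_true(all(m$values == 0))
})

test_that("one-cell mortality is the product BMR x POP x AF", {
  g <- grid_spec(1, 1, 5)
  mask <- country_mask(g, matrix("XA", 1, 1))
  ages <- adult_age_classes()
  pv <- array(0, c(1, 1, 12), dimnames = list(NULL, NULL, ages))
  pv[1, 1, "45-49"] <- 100000
  pop <- population_grid(g, pv)
  # curve hitting RR = 1.25 at 10 ug/m3 -> AF = 0.2
  erfs <- erf_set(lapply(stats::setNames(nm = cause_registry()$code), function(cs)
    toy_erf(cs, "ALL", knots = c(0, 4.15, 10, 40), rr = c(1, 1, 1.25, 1.25))))
  bmr <- uniform_bmr("XA", rate = 0.01)
  conc <- const_field(g, 10)
  m <- gridded_excess_mortality(conc, pop, bmr, erfs, mask)
  expect_equal(m$values[1, 1, "IHD", "45-49", "central"], 100000 * 0.01 * 0.2)
  # all strata with zero population contribute zero
  expect_equal(sum(m$values), 100000 * 0.01 * 0.2 * 6 * 3) # 6 causes x 3 branches
})

test_that("excess mortality is linear in population and baseline rates", {
  st <- tiny_study()
  conc <- st$scenarios$fields$BASE$pm
  m1 <- gridded_excess_mortality(conc, st$population, st$bmr, st$erfs, st$mask)
  pop2 <- population_grid(st$population$grid, st$population$values * 2)
  m2 <- gridded_excess_mortality(conc, pop2, st$bmr, st$erfs, st$mask)
  expect_equal(m2$values, 2 * m1$values, tolerance = 1e-12)
  bmr3 <- bmr_table(transform(as.data.frame(st$bmr), rate = rate * 3))
  m3 <- gridded_excess_mortality(conc, st$population, bmr3, st$erfs, st$mask)
  expect_equal(m3$values, 3 * m1$values, tolerance = 1e-12)
})

test_that("raising concentrations never lowers any stratum total", {
  st <- tiny_study()
  conc <- st$scenarios$fields$BASE$pm
  m1 <- gridded_excess_mortality(conc, st$population, st$bmr, st$erfs, st$mask)
  up <- conc_field(conc$grid, "PM25", "BASE", conc$values + 2.5)
  m2 <- gridded_excess_mortality(up, st$population, st$bmr, st$erfs, st$mask)
  t1 <- aggregate_mortality(m1, by = c("cause", "age_group", "branch"))
  t2 <- aggregate_mortality(m2, by = c("cause", "age_group", "branch"))
  expect_true(all(t2$deaths >= t1$deaths - 1e-12))
})

test_that("sea cells contribute nothing regardless of concentration", {
  st <- tiny_study()
  hot <- conc_field(st$scenarios$grid, "PM25", "BASE",
                    matrix(60, st$scenarios$grid$n_rows, st$scenarios$grid$n_cols))
  m <- gridded_excess_mortality(hot, st$population, st$bmr, st$erfs, st$mask)
  sea <- is.na(st$mask$codes)
  per_cell <- apply(m$values, c(1, 2), sum)
  expect_true(all(per_cell[sea] == 0))
})

test_that("missing curves or rates raise coverage errors naming the stratum", {
  st <- tiny_study()
  conc <- st$scenarios$fields$BASE$pm
  curves <- st$erfs$curves
  curves[["T2D|ALL"]] <- NULL
  expect_error(gridded_excess_mortality(conc, st$population, st$bmr,
                                        erf_set(curves), st$mask),
               "T2D")
})

test_that("aggregation is a partition: grand total invariant under 'by'", {
  st <- tiny_study()
  m <- gridded_excess_mortality(st$scenarios$fields$BASE$pm, st$population,
                                st$bmr, st$erfs, st$mask)
  total <- aggregate_mortality(m)$deaths
  expect_equal(total, sum(m$values))
  for (by in list("cause", "branch", c("cause", "age_group"),
                  c("country", "branch"), c("country", "cause", "age_group", "branch")))
    expect_equal(sum(aggregate_mortality(m, st$mask, by)$deaths), total,
                 tolerance = 1e-9, label = paste("by =", paste(by, collapse = "+")))

  # two-country partition matches a hand computation from the gridded values
  per_ctry <- aggregate_mortality(m, st$mask, by = "country")
  for (co in st$mask$countries) {
    idx <- which(!is.na(st$mask$codes) & st$mask$codes == co)
    hand <- sum(apply(m$values, c(1, 2), sum)[idx])
    expect_equal(per_ctry$deaths[per_ctry$country == co], hand, tolerance = 1e-9)
  }
})

test_that("branch ordering survives aggregation", {
  st <- tiny_study()
  m <- gridded_excess_mortality(st$scenarios$fields$BASE$pm, st$population,
                                st$bmr, st$erfs, st$mask)
  t <- aggregate_mortality(m, st$mask, by = c("country", "cause", "branch"))
  w <- stats::reshape(t, direction = "wide", idvar = c("country", "cause"),
                      timevar = "branch")
  expect_true(all(w$deaths.low <= w$deaths.central + 1e-12))
  expect_true(all(w$deaths.central <= w$deaths.high + 1e-12))
})

test_that("engine matches the brute-force triple-loop oracle", {
  st <- tiny_study(seed = 23)
  m <- gridded_excess_mortality(st$scenarios$fields$BASE$pm, st$population,
                                st$bmr, st$erfs, st$mask)
  oracle <- oracle_excess_mortality(st$scenarios$fields$BASE$pm, st$population,
                                    st$bmr, st$erfs, st$mask)
  expect_equal(m$values, oracle, tolerance = 1e-9)
})
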