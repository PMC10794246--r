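test_that("tabulated_erf enforces curve invariants", {
  expect_error(tabulated_erf("IHD", "ALL", c(0, 0, 10), c(1, 1, 2), c(1, 1, 2), c(1, 1, 2)),
               "ascending")
  expect_error(tabulated_erf("IHD", "ALL", c(5, 10), c(1, 2), c(1, 2), c(1, 2)),
               "first knot")
  expect_error(tabulated_erf("IHD", "ALL", c(0, 10), c(1, 2), c(1, 2.5), c(1, 3)),
               "branch ordering")
  expect_error(tabulated_erf("IHD", "ALL", c(0, 10), c(2, 1), c(2, 1), c(2, 1)),
               "non-decreasing")
  expect_error(tabulated_erf("BAD", "ALL", c(0, 10), c(1, 2), c(1, 2), c(1, 2)),
               "unknown cause")
})

test_that("TMREL anchoring rescales each branch by its value at the TMREL", {
  # RR(4.15) = 1.1, RR(10) = 1.65 -> scaled RR(10) = 1.65/1.1 = 1.5
  raw <- tabulated_erf("COPD", "ALL", c(0, 4.15, 10), c(1.02, 1.1, 1.65),
                       c(1.01, 1.05, 1.3), c(1.03, 1.2, 2.2))
  s <- scale_to_tmrel(raw)
  expect_equal(evaluate_rr(s, 10), 1.65 / 1.1)
  expect_equal(evaluate_rr(s, 10, "low"), 1.3 / 1.05)
  expect_equal(evaluate_rr(s, 10, "high"), 2.2 / 1.2)
  # no excess risk at or below the TMREL
  expect_equal(evaluate_rr(s, 4.15), 1)
  expect_equal(evaluate_rr(s, 2.0), 1)
  expect_equal(evaluate_rr(s, 0), 1)
  # curve already anchored: unchanged above the TMREL
  pre <- tabulated_erf("COPD", "ALL", c(0, 4.15, 10), c(1, 1, 1.5),
                       c(1, 1, 1.4), c(1, 1, 1.6))
  expect_equal(scale_to_tmrel(pre)$rr_central, c(1, 1, 1.5))
})

test_that("evaluate_rr interpolates linearly and extrapolates as a constant", {
  erf <- toy_erf(knots = c(0, 4.15, 10, 40), rr = c(1, 1, 1.2, 1.2))
  # midpoint of (4.15 -> 1.0, 10 -> 1.2)
  expect_equal(evaluate_rr(erf, (4.15 + 10) / 2), 1.1)
  # beyond the last knot: value at the last knot
  expect_equal(evaluate_rr(erf, 50), 1.2)
  # oracle check across a concentration sweep
  for (cc in seq(0, 60, by = 0.7))
    expect_equal(evaluate_rr(erf, cc), oracle_rr(erf, cc, "central"))
  expect_error(evaluate_rr(erf, -1), ">= 0")
  raw <- tabulated_erf("LC", "ALL", c(0, 10), c(1, 2), c(1, 2), c(1, 2))
  expect_error(evaluate_rr(raw, 5), "TMREL-scaled")
})

test_that("gemm_rr implements the four-parameter closed form", {
  p <- gemm_params("IHD", "ALL", theta = 0.1430, theta_se = 0.01807,
                   alpha = 1.6, mu = 15.5, nu = 36.8)
  # at or below the counterfactual: exactly 1
  expect_equal(gemm_rr(p, p$counterfactual), 1)
  expect_equal(gemm_rr(p, 0), 1)
  # theta = 0: no risk anywhere
  p0 <- gemm_params("IHD", "ALL", 0, 0, 1.6, 15.5, 36.8)
  expect_equal(gemm_rr(p0, 100), 1)
  # direct evaluation of the closed form at counterfactual + 10
  z <- 10
  expected <- exp(0.1430 * log(1 + z / 1.6) / (1 + exp(-(z - 15.5) / 36.8)))
  expect_equal(gemm_rr(p, p$counterfactual + 10), expected, tolerance = 1e-12)

  # 1000 random (param, conc) draws against an independent reimplementation
  set.seed(42)
  for (i in 1:1000) {
    pr <- gemm_params("STROKE", "ALL",
                      theta = runif(1, 0, 0.5), theta_se = runif(1, 0, 0.05),
                      alpha = runif(1, 0.5, 15), mu = runif(1, 1, 30),
                      nu = runif(1, 1, 50), counterfactual = runif(1, 0, 5))
    cc <- runif(1, 0, 120)
    br <- sample(c("central", "low", "high"), 1)
    expect_equal(gemm_rr(pr, cc, br), oracle_gemm_rr(pr, cc, br),
                 tolerance = 1e-12)
  }
})

test_that("attributable fraction is (RR-1)/RR, bounded and monotone", {
  expect_equal(attributable_fraction(1), 0)
  expect_equal(attributable_fraction(2), 0.5)
  expect_equal(attributable_fraction(1.25), 0.2)
  expect_error(attributable_fraction(0.99), "RR >= 1")
  rr <- seq(1, 50, length.out = 200)
  af <- attributable_fraction(rr)
  expect_true(all(diff(af) > 0))
  expect_true(all(af >= 0 & af < 1))
})

test_that("generated curves satisfy RR contracts on every branch", {
  st <- tiny_study()
  concs <- c(seq(0, TMREL_DEFAULT, length.out = 10), seq(4.2, 120, length.out = 40))
  for (erf in st$erfs$curves) {
    lo <- evaluate_rr(erf, concs, "low")
    ce <- evaluate_rr(erf, concs, "central")
    hi <- evaluate_rr(erf, concs, "high")
    # RR exactly 1 on [0, TMREL]
    expect_true(all(ce[concs <= TMREL_DEFAULT] == 1))
    # non-decreasing in concentration, branch ordering everywhere
    expect_true(all(diff(ce) >= -1e-12))
    expect_true(all(lo <= ce + 1e-12 & ce <= hi + 1e-12))
    # supralinear (concave) between the TMREL and 30 ug/m3: secant slopes fall
    cs <- seq(5, 30, by = 2.5)
    slopes <- diff(evaluate_rr(erf, cs)) / diff(cs)
    expect_true(all(diff(slopes) <= 1e-12))
  }
})

test_that("curve lookup prefers exact age and falls back to ALL", {
  ihd <- toy_erf("IHD", "45-49")
  copd <- toy_erf("COPD", "ALL")
  set <- erf_set(list(ihd, copd))
  expect_identical(get_erf(set, "IHD", "45-49"), ihd)
  expect_identical(get_erf(set, "COPD", "30-34"), copd)
  expect_error(get_erf(set, "IHD", "25-29"), "no exposure-response curve")
  expect_error(erf_set(list(copd, copd)), "duplicate")
})
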