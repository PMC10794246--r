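#' Causes of death considered
#'
#' The six adult causes with PM2.5 exposure-response functions: ischemic
#' heart disease (IHD), stroke, chronic obstructive pulmonary disease (COPD),
#' lung cancer (LC), lower respiratory infections (LRI) and type II diabetes
#' (T2D). Risk is age-dependent for IHD and stroke only; the remaining causes
#' use one curve applied to every adult age class.
#'
#' @return `data.frame` with columns `code` and `age_dependent`.
#' @export
cause_registry <- function() {
  data.frame(code = c("IHD", "STROKE", "COPD", "LC", "LRI", "T2D"),
             age_dependent = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
             stringsAsFactors = FALSE)
}

#' Default theoretical minimum risk exposure level (ug/m3)
#'
#' Concentration below which no excess risk is assumed; the mean of the
#' 2.4-5.9 ug/m3 uniform distribution used in recent burden assessments.
#' @export
TMREL_DEFAULT <- 4.15

#' Tabulated exposure-response curve
#'
#' A relative-risk curve for one cause (and age group where risk is
#' age-dependent), given as RR values at ascending concentration knots with
#' central / low / high (95% interval) branches. Curves of this form are how
#' MR-BRT spline output is consumed: as dense knot tables, not refit.
#'
#' @param cause Cause code from [cause_registry()].
#' @param age_group An [adult_age_classes()] label, or `"ALL"` for causes
#'   whose risk does not depend on age.
#' @param knots Strictly ascending concentrations (ug/m3); the first knot
#'   must not exceed `tmrel`.
#' @param rr_central,rr_low,rr_high Positive RR values at the knots, with
#'   `rr_low <= rr_central <= rr_high` everywhere and each branch
#'   non-decreasing in concentration.
#' @param tmrel Theoretical minimum risk exposure level (ug/m3).
#' @param scaled Whether the curve has already been anchored at `tmrel`
#'   (see [scale_to_tmrel()]). Evaluation requires a scaled curve.
#' @return Object of class `tabulated_erf`.
#' @export
tabulated_erf <- function(cause, age_group = "ALL", knots,
                          rr_central, rr_low, rr_high,
                          tmrel = TMREL_DEFAULT, scaled = FALSE) {
  reg <- cause_registry()
  if (!cause %in% reg$code) stop("unknown cause: ", cause)
  if (!(age_group == "ALL" || age_group %in% adult_age_classes()))
    stop("unknown age group: ", age_group)
  n <- length(knots)
  stopifnot(n >= 2, length(rr_central) == n, length(rr_low) == n, length(rr_high) == n)
  if (any(diff(knots) <= 0)) stop("knots must be strictly ascending")
  if (knots[1] > tmrel) stop("first knot must be <= tmrel")
  if (any(rr_low <= 0)) stop("RR branches must be positive")
  if (any(rr_low > rr_central + 1e-12) || any(rr_central > rr_high + 1e-12))
    stop("branch ordering violated: need rr_low <= rr_central <= rr_high at every knot")
  for (b in list(rr_central, rr_low, rr_high))
    if (any(diff(b) < -1e-12)) stop("RR branches must be non-decreasing in concentration")
  if (scaled && any(c(rr_central, rr_low, rr_high) < 1 - 1e-12))
    stop("scaled curves must have RR >= 1 everywhere")
  structure(list(cause = cause, age_group = age_group, knots = as.numeric(knots),
                 rr_central = as.numeric(rr_central), rr_low = as.numeric(rr_low),
                 rr_high = as.numeric(rr_high), tmrel = as.numeric(tmrel),
                 scaled = isTRUE(scaled)),
            class = "tabulated_erf")
}

#' @export
print.tabulated_erf <- function(x, ...) {
  cat(sprintf("<tabulated_erf> %s/%s, %d knots on [%g, %g] ug/m3, tmrel %g%s\n",
              x$cause, x$age_group, length(x$knots), min(x$knots), max(x$knots),
              x$tmrel, if (x$scaled) " (TMREL-scaled)" else " (raw)"))
  invisible(x)
}

branch_values <- function(erf, branch = c("central", "low", "high")) {
  branch <- match.arg(branch)
  switch(branch, central = erf$rr_central, low = erf$rr_low, high = erf$rr_high)
}

#' Anchor an exposure-response curve at the TMREL
#'
#' Divides each RR branch by its own (linearly interpolated) value at the
#' theoretical minimum risk exposure level, so that RR(tmrel) = 1, and sets
#' RR to exactly 1 for all concentrations at or below the TMREL — below
#' which no excess risk is assumed.
#'
#' @param raw A [tabulated_erf()] with positive branches.
#' @return A TMREL-scaled [tabulated_erf()].
#' @export
scale_to_tmrel <- function(raw) {
  stopifnot(inherits(raw, "tabulated_erf"))
  scale1 <- function(rr) {
    at <- stats::approx(raw$knots, rr, xout = raw$tmrel, rule = 2)$y
    if (!is.finite(at) || at <= 0)
      stop(sprintf("curve %s/%s has non-positive RR at tmrel", raw$cause, raw$age_group))
    s <- rr / at
    s[raw$knots <= raw$tmrel] <- 1
    pmax(s, 1)
  }
  tabulated_erf(raw$cause, raw$age_group, raw$knots,
                scale1(raw$rr_central), scale1(raw$rr_low), scale1(raw$rr_high),
                tmrel = raw$tmrel, scaled = TRUE)
}

#' Evaluate the relative risk of a tabulated curve
#'
#' Piecewise-linear interpolation between knots, constant extrapolation
#' beyond the last knot, and RR = 1 at or below the TMREL. Linear
#' interpolation preserves the monotonicity of the knot values and the knot
#' density can be made arbitrarily fine.
#'
#' @param erf A TMREL-scaled [tabulated_erf()].
#' @param conc Concentration(s), ug/m3, >= 0 (vectorized).
#' @param branch `"central"`, `"low"` or `"high"`.
#' @return RR value(s) >= 1.
#' @export
evaluate_rr <- function(erf, conc, branch = c("central", "low", "high")) {
  stopifnot(inherits(erf, "tabulated_erf"))
  if (!erf$scaled) stop("curve must be TMREL-scaled before evaluation; see scale_to_tmrel()")
  if (any(conc < 0)) stop("concentrations must be >= 0")
  rr <- stats::approx(erf$knots, branch_values(erf, branch), xout = conc, rule = 2)$y
  rr[conc <= erf$tmrel] <- 1
  rr
}

#' GEMM exposure-response parameters
#'
#' The four-parameter family of the Global Exposure Mortality Model:
#' RR(z) = exp(theta * log(1 + z/alpha) / (1 + exp(-(z - mu)/nu))) with
#' z = max(0, conc - counterfactual). Used as a sensitivity risk model
#' alongside the tabulated curves.
#'
#' @param cause Cause code (or `"NCD_LRI"`-style aggregate label is not
#'   supported; one of [cause_registry()] codes).
#' @param age_group Age class label or `"ALL"`.
#' @param theta,theta_se Log-risk scale parameter and its standard error
#'   (unitless); `theta >= 0`.
#' @param alpha,mu,nu Shape parameters (ug/m3); `alpha, nu > 0`.
#' @param counterfactual Counterfactual (no-risk) concentration, ug/m3.
#'   Defaults to the TMREL used for the tabulated curves; the original GEMM
#'   value of 2.4 ug/m3 can be set explicitly.
#' @return Object of class `gemm_params`.
#' @export
gemm_params <- function(cause, age_group = "ALL", theta, theta_se,
                        alpha, mu, nu, counterfactual = TMREL_DEFAULT) {
  if (!cause %in% cause_registry()$code) stop("unknown cause: ", cause)
  if (!(age_group == "ALL" || age_group %in% adult_age_classes()))
    stop("unknown age group: ", age_group)
  if (alpha <= 0 || nu <= 0) stop("alpha and nu must be positive")
  if (theta < 0) stop("theta must be >= 0")
  structure(list(cause = cause, age_group = age_group, theta = theta,
                 theta_se = theta_se, alpha = alpha, mu = mu, nu = nu,
                 counterfactual = counterfactual),
            class = "gemm_params")
}

#' Evaluate a GEMM relative risk
#'
#' @param p A [gemm_params()].
#' @param conc Concentration(s), ug/m3, >= 0 (vectorized).
#' @param branch `"central"` uses theta; `"low"` / `"high"` use
#'   theta -/+ 1.96 * theta_se (95% interval on the log-risk scale).
#' @return RR value(s); exactly 1 at or below the counterfactual.
#' @export
gemm_rr <- function(p, conc, branch = c("central", "low", "high")) {
  stopifnot(inherits(p, "gemm_params"))
  branch <- match.arg(branch)
  if (any(conc < 0)) stop("concentrations must be >= 0")
  th <- p$theta + switch(branch, central = 0, low = -1.96, high = 1.96) * p$theta_se
  th <- max(th, 0)
  z <- pmax(0, conc - p$counterfactual)
  exp(th * log1p(z / p$alpha) / (1 + exp(-(z - p$mu) / p$nu)))
}

#' Attributable fraction
#'
#' The fraction of mortality attributable to the exposure,
#' AF = (RR - 1) / RR, in \[0, 1).
#'
#' @param rr Relative risk(s) >= 1 (vectorized).
#' @return Fraction(s) in \[0, 1).
#' @export
attributable_fraction <- function(rr) {
  if (any(rr < 1)) stop("attributable fraction requires RR >= 1")
  (rr - 1) / rr
}

#' A set of exposure-response curves with (cause, age) lookup
#'
#' Bundles TMREL-scaled tabulated curves (or GEMM parameter sets) and
#' resolves the curve for a given cause and age group: an exact
#' (cause, age_group) entry is preferred, otherwise the cause's `ALL`-age
#' curve applies to every age class.
#'
#' @param curves List of [tabulated_erf()] or [gemm_params()] objects.
#' @return Object of class `erf_set`.
#' @export
erf_set <- function(curves) {
  stopifnot(length(curves) >= 1)
  ok <- vapply(curves, function(x) inherits(x, "tabulated_erf") || inherits(x, "gemm_params"),
               logical(1))
  if (!all(ok)) stop("curves must be tabulated_erf or gemm_params objects")
  keys <- vapply(curves, function(x) paste(x$cause, x$age_group, sep = "|"), character(1))
  if (anyDuplicated(keys)) stop("duplicate (cause, age_group) curves")
  names(curves) <- keys
  structure(list(curves = curves), class = "erf_set")
}

#' @rdname erf_set
#' @param set An `erf_set`.
#' @param cause,age_group Stratum to resolve.
#' @export
get_erf <- function(set, cause, age_group) {
  stopifnot(inherits(set, "erf_set"))
  k <- paste(cause, age_group, sep = "|")
  if (!is.null(set$curves[[k]])) return(set$curves[[k]])
  k <- paste(cause, "ALL", sep = "|")
  if (!is.null(set$curves[[k]])) return(set$curves[[k]])
  stop(sprintf("no exposure-response curve for (%s, %s)", cause, age_group))
}

#' Evaluate RR from any supported curve object
#'
#' Dispatches to [evaluate_rr()] or [gemm_rr()].
#' @param erf A [tabulated_erf()] or [gemm_params()].
#' @param conc Concentration(s), ug/m3.
#' @param branch Uncertainty branch.
#' @export
risk_rr <- function(erf, conc, branch = "central") {
  if (inherits(erf, "tabulated_erf")) evaluate_rr(erf, conc, branch)
  else if (inherits(erf, "gemm_params")) gemm_rr(erf, conc, branch)
  else stop("unsupported curve object")
}
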