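#' Attribute excess mortality to carbonaceous aerosols
#'
#' Multiplies the PM2.5 excess mortality in each cell and stratum by the
#' local aCA/PM2.5 mass fraction, optionally reweighted by a differential
#' toxicity factor. With `factor = 1` this is the plain mass-proportional
#' attribution; with `factor = 2` the fractional contribution of
#' carbonaceous particles is doubled while total PM2.5 mortality is held
#' constant, so the effective weight is `min(1, factor * fraction)` — RR is
#' never re-evaluated at inflated concentrations. The attributed mortality
#' therefore never exceeds the total PM2.5 mortality in any cell.
#'
#' @param m A [mortality_result()] from total PM2.5.
#' @param aca,pm [conc_field()]s of species `ACA` and `PM25` on the same
#'   grid and scenario as `m`.
#' @param factor Positive toxicity weight applied to the mass fraction
#'   (1 = equal toxicity, 2 = two-fold).
#' @return A [mortality_result()] of aCA-attributable deaths.
#' @export
aca_attribution <- function(m, aca, pm, factor = 1) {
  stopifnot(inherits(m, "mortality_result"))
  if (!is.numeric(factor) || length(factor) != 1 || factor <= 0)
    stop("toxicity factor must be a positive scalar")
  if (!identical(m$scenario, aca$scenario) || !identical(m$scenario, pm$scenario))
    stop("scenario mismatch between mortality result and concentration fields")
  if (!same_grid(m$grid, aca$grid) || !same_grid(m$grid, pm$grid))
    stop("grid mismatch between mortality result and concentration fields")
  w <- pmin(1, factor * aca_fraction(aca, pm))
  vals <- m$values * as.vector(w) # w recycles over strata (cells vary fastest)
  mortality_result(m$grid, m$scenario, vals)
}

#' Sectoral contribution by scenario differencing
#'
#' The zero-out estimate of a source's contribution: element-wise
#' BASE - SCENARIO, for gridded results, aggregate tables or plain numbers.
#' Negative values (possible where atmospheric chemistry responds
#' non-linearly to emission removal) are retained, not clipped, and counted
#' in the `n_negative` attribute of the returned object.
#'
#' @param m_base Mortality under the full-emission baseline: a
#'   [mortality_result()], a `data.frame` with a `deaths` column (as from
#'   [aggregate_mortality()]), or a numeric vector.
#' @param m_scen Mortality under the reduced-emission scenario, same shape.
#' @return Same shape as the inputs, holding BASE - SCEN, with attribute
#'   `n_negative`.
#' @export
sector_contribution <- function(m_base, m_scen) {
  if (inherits(m_base, "mortality_result") && inherits(m_scen, "mortality_result")) {
    if (!same_grid(m_base$grid, m_scen$grid) ||
        !identical(dim(m_base$values), dim(m_scen$values)))
      stop("mortality results are not aligned")
    d <- m_base$values - m_scen$values
    out <- list(grid = m_base$grid,
                scenario = paste(m_base$scenario, m_scen$scenario, sep = "-"),
                values = d)
    class(out) <- "mortality_contribution"
  } else if (is.data.frame(m_base) && is.data.frame(m_scen)) {
    keys <- setdiff(names(m_base), "deaths")
    if (!identical(names(m_base), names(m_scen)) ||
        nrow(m_base) != nrow(m_scen) ||
        (length(keys) && !identical(m_base[keys], m_scen[keys])))
      stop("aggregate tables are not aligned")
    out <- m_base
    d <- out$deaths <- m_base$deaths - m_scen$deaths
  } else if (is.numeric(m_base) && is.numeric(m_scen)) {
    if (length(m_base) != length(m_scen)) stop("shapes differ")
    d <- out <- m_base - m_scen
  } else stop("inputs must both be mortality results, aggregate tables or numerics")
  attr(out, "n_negative") <- sum(d < 0)
  out
}

round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percentage share
#'
#' 100 * part/whole, rounded half-away-from-zero to the requested number of
#' decimals (the convention used in the rendered report tables).
#'
#' @param part,whole Quantities in the same units; `whole > 0`, `part >= 0`.
#' @param decimals Number of decimals to keep.
#' @return Percentage(s).
#' @export
share_percent <- function(part, whole, decimals = 0) {
  part <- as.vector(part); whole <- as.vector(whole)
  if (any(whole <= 0)) stop("whole must be positive")
  if (any(part < 0)) stop("part must be >= 0")
  round_half_away(100 * part / whole, decimals)
}

#' Scenario-linearity diagnostic
#'
#' Checks whether the concentration response to emission reductions is
#' linear: for a sector with a 100%-removal scenario and a 20%-reduction
#' scenario, the per-cell ratio
#' r = 5 * (BASE - SCEN20) / (BASE - SCEN100)
#' equals 1 exactly when the response is linear in the removed emissions.
#' Cells where |BASE - SCEN100| <= eps carry no sectoral signal; they are
#' excluded from the ratio and counted.
#'
#' @param base,scen100,scen20 [conc_field()]s on one grid: the baseline, the
#'   full-removal scenario and the 20%-reduction scenario of one sector.
#' @param eps Minimum |BASE - SCEN100| (ug/m3) for a cell to enter the
#'   diagnostic; default 0.01.
#' @return List with `ratio` (matrix, `NA` on excluded cells),
#'   `mean_ratio` (population-unweighted mean over valid cells),
#'   `n_valid` and `n_excluded`.
#' @export
linearity_diagnostic <- function(base, scen100, scen20, eps = 0.01) {
  stopifnot(inherits(base, "conc_field"), inherits(scen100, "conc_field"),
            inherits(scen20, "conc_field"))
  if (!same_grid(base$grid, scen100$grid) || !same_grid(base$grid, scen20$grid))
    stop("fields must share one grid")
  d100 <- base$values - scen100$values
  d20 <- base$values - scen20$values
  valid <- abs(d100) > eps
  ratio <- matrix(NA_real_, nrow(d100), ncol(d100))
  ratio[valid] <- 5 * d20[valid] / d100[valid]
  list(ratio = ratio,
       mean_ratio = if (any(valid)) mean(ratio[valid]) else NA_real_,
       n_valid = sum(valid), n_excluded = sum(!valid))
}
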