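#' Run the full health-impact pipeline on a study
#'
#' Executes every stage on an in-memory study (from [generate_study()] or
#' [read_study()]): per-country population-weighted exposure for PM2.5 and
#' aCA, gridded excess mortality per scenario, carbonaceous-aerosol
#' attribution under each toxicity factor, sectoral contributions by
#' scenario differencing, sectoral shares, and the scenario-linearity
#' diagnostic. Re-running with identical inputs reproduces identical
#' outputs.
#'
#' @param study List with elements `scenarios` ([scenario_set()]),
#'   `population`, `mask`, `bmr`, `erfs`.
#' @param toxicity_factors Toxicity factors at which to attribute mortality
#'   to carbonaceous aerosols; default equal (1) and two-fold (2).
#' @param sector_scenarios Named list mapping a sector label to its
#'   `c(full_removal, partial_removal)` scenario labels, used for
#'   differencing and the linearity diagnostic. Entries whose scenarios are
#'   absent from the study are dropped.
#' @param output_dir Optional directory; when given, the report tables are
#'   written there as CSV (see [render_report()]).
#' @return A report bundle (list, class `pmburden_report`) with elements
#'   `exposure`, `mortality_by_cause`, `mortality_totals`, `attribution`,
#'   `sector_domain`, `sector_country`, `shares`, `linearity`, `log`.
#' @export
run_pipeline <- function(study,
                         toxicity_factors = c(1, 2),
                         sector_scenarios = list(RES = c("RES100", "RES20"),
                                                 TRA = c("TRA100", "TRA20")),
                         output_dir = NULL) {
  sc <- study$scenarios
  stopifnot(inherits(sc, "scenario_set"))
  pop <- study$population; mask <- study$mask
  labels <- names(sc$fields)

  # --- exposure summaries (BASE) -------------------------------------------
  base <- sc$fields$BASE
  exposure <- country_aggregate(base$pm, mask, "pop_weighted_mean", pop)
  names(exposure)[2] <- "pw_pm25"
  exposure$pw_aca <- country_aggregate(base$aca, mask, "pop_weighted_mean", pop)$value
  exposure$aca_percent <- share_percent(exposure$pw_aca, exposure$pw_pm25, decimals = 1)

  # --- excess mortality per scenario ---------------------------------------
  mort <- lapply(labels, function(nm)
    gridded_excess_mortality(sc$fields[[nm]]$pm, pop, study$bmr, study$erfs, mask))
  names(mort) <- labels

  mortality_by_cause <- do.call(rbind, lapply(labels, function(nm) {
    t <- aggregate_mortality(mort[[nm]], by = c("cause", "branch"))
    cbind(scenario = nm, t)
  }))
  mortality_totals <- do.call(rbind, lapply(labels, function(nm) {
    t <- aggregate_mortality(mort[[nm]], by = "branch")
    cbind(scenario = nm, t)
  }))

  # --- aCA attribution per scenario and toxicity factor --------------------
  attribution <- do.call(rbind, lapply(labels, function(nm) {
    do.call(rbind, lapply(toxicity_factors, function(f) {
      ma <- aca_attribution(mort[[nm]], sc$fields[[nm]]$aca, sc$fields[[nm]]$pm, f)
      t <- aggregate_mortality(ma, by = "branch")
      cbind(scenario = nm, toxicity_factor = f, t)
    }))
  }))

  # --- sectoral contributions ----------------------------------------------
  sector_scenarios <- Filter(function(v) all(v %in% labels), sector_scenarios)
  sector_domain <- sector_country <- NULL
  shares <- NULL
  central_total <- function(nm)
    aggregate_mortality(mort[[nm]], by = "branch")$deaths[
      aggregate_mortality(mort[[nm]], by = "branch")$branch == "central"]
  for (sec in names(sector_scenarios)) {
    for (nm in sector_scenarios[[sec]]) {
      dom <- sector_contribution(aggregate_mortality(mort$BASE, by = "branch"),
                                 aggregate_mortality(mort[[nm]], by = "branch"))
      sector_domain <- rbind(sector_domain,
                             cbind(sector = sec, scenario = nm, dom,
                                   n_negative = attr(dom, "n_negative")))
      ctry <- sector_contribution(
        aggregate_mortality(mort$BASE, mask, by = c("country", "branch")),
        aggregate_mortality(mort[[nm]], mask, by = c("country", "branch")))
      sector_country <- rbind(sector_country, cbind(sector = sec, scenario = nm, ctry))
    }
  }

  # --- shares of total (from the 100%-removal scenarios) -------------------
  base_total <- central_total("BASE")
  if (length(sector_scenarios) && base_total > 0) {
    part <- vapply(names(sector_scenarios), function(sec) {
      nm <- sector_scenarios[[sec]][1]
      base_total - central_total(nm)
    }, numeric(1))
    shares <- data.frame(sector = c(names(part), "OTHER"),
                         deaths = c(part, base_total - sum(part)),
                         stringsAsFactors = FALSE)
    shares$percent <- share_percent(pmax(shares$deaths, 0), base_total, decimals = 0)
  }

  # --- linearity diagnostic ------------------------------------------------
  linearity <- do.call(rbind, lapply(names(sector_scenarios), function(sec) {
    v <- sector_scenarios[[sec]]
    if (length(v) < 2) return(NULL)
    ld <- linearity_diagnostic(base$pm, sc$fields[[v[1]]]$pm, sc$fields[[v[2]]]$pm)
    data.frame(sector = sec, mean_ratio = ld$mean_ratio,
               n_valid = ld$n_valid, n_excluded = ld$n_excluded,
               stringsAsFactors = FALSE)
  }))

  log <- list(scenarios = labels, n_cells = sc$grid$n_rows * sc$grid$n_cols,
              n_countries = length(mask$countries), n_bmr_rows = nrow(study$bmr),
              n_curves = length(study$erfs$curves),
              toxicity_factors = toxicity_factors, timestamp = format(Sys.time()))

  bundle <- structure(
    list(exposure = exposure, mortality_by_cause = mortality_by_cause,
         mortality_totals = mortality_totals, attribution = attribution,
         sector_domain = sector_domain, sector_country = sector_country,
         shares = shares, linearity = linearity, log = log,
         gridded = mort),
    class = "pmburden_report")
  if (!is.null(output_dir)) render_report(bundle, output_dir)
  bundle
}

#' @export
print.pmburden_report <- function(x, ...) {
  ct <- x$mortality_totals[x$mortality_totals$branch == "central", ]
  cat("<pmburden_report>\n  central excess deaths/yr by scenario:\n")
  for (i in seq_len(nrow(ct)))
    cat(sprintf("    %-7s %10.0f\n", ct$scenario[i], ct$deaths[i]))
  if (!is.null(x$linearity)) {
    cat("  linearity ratio (5 x 20%-response / 100%-response):\n")
    for (i in seq_len(nrow(x$linearity)))
      cat(sprintf("    %-4s %.4f\n", x$linearity$sector[i], x$linearity$mean_ratio[i]))
  }
  invisible(x)
}

format_ci <- function(mean, low, high, digits = 0) {
  f <- function(v) formatC(round_half_away(v, digits), format = "f", digits = digits)
  sprintf("%s (%s-%s)", f(mean), f(low), f(high))
}

ci_wide <- function(df, keys) {
  # long (branch column) -> wide mean/low/high columns
  w <- stats::reshape(df[c(keys, "branch", "deaths")], direction = "wide",
                      idvar = keys, timevar = "branch")
  names(w) <- sub("^deaths\\.", "", names(w))
  rownames(w) <- NULL
  w
}

#' Render a report bundle to CSV tables
#'
#' Applies the reporting rounding profile — domain death totals to the
#' nearest thousand, per-country deaths to the nearest integer, percentages
#' half-away-from-zero — and writes country-sorted CSV tables with
#' confidence intervals formatted `mean (low-high)`. Stored pipeline data
#' are never rounded; rounding happens only here.
#'
#' @param bundle A `pmburden_report` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
render_report <- function(bundle, dir) {
  stopifnot(inherits(bundle, "pmburden_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- c()
  wr <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = FALSE, quote = FALSE)
    files[[name]] <<- p
  }

  # exposure table: country, pw PM2.5, pw aCA (one decimal, as reported)
  ex <- bundle$exposure[order(bundle$exposure$country), ]
  ex$pw_pm25 <- round_half_away(ex$pw_pm25, 1)
  ex$pw_aca <- round_half_away(ex$pw_aca, 1)
  wr(ex, "exposure_by_country.csv")

  # scenario x cause mortality in thousand deaths, CI formatted
  mc <- ci_wide(bundle$mortality_by_cause, c("scenario", "cause"))
  mc$deaths_thousands <- format_ci(mc$central / 1000, mc$low / 1000, mc$high / 1000)
  wr(mc[c("scenario", "cause", "deaths_thousands")], "mortality_by_cause.csv")

  att <- ci_wide(bundle$attribution, c("scenario", "toxicity_factor"))
  att$deaths_thousands <- format_ci(att$central / 1000, att$low / 1000, att$high / 1000)
  wr(att[c("scenario", "toxicity_factor", "deaths_thousands")], "aca_attribution.csv")

  if (!is.null(bundle$sector_country)) {
    scw <- ci_wide(bundle$sector_country, c("sector", "scenario", "country"))
    scw <- scw[order(scw$country), ]
    scw$avoidable_deaths <- format_ci(scw$central, scw$low, scw$high)
    wr(scw[c("country", "sector", "scenario", "avoidable_deaths")],
       "avoidable_by_country.csv")
  }
  if (!is.null(bundle$shares)) wr(bundle$shares, "sector_shares.csv")
  if (!is.null(bundle$linearity)) wr(bundle$linearity, "linearity.csv")
  invisible(unlist(files))
}
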