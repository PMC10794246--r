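#' Read and write gridded fields as plain text
#'
#' Rasters are stored in a self-describing text format: `#`-prefixed header
#' lines carrying the grid geometry and field metadata (species, scenario,
#' units), followed by the value matrix, one southern-to-northern row per
#' line, written at full double precision. Rounding applies only to rendered
#' report tables, never to stored data, so a write-read round trip is exact.
#'
#' @param field A [conc_field()].
#' @param path File path.
#' @return `read_field` returns a [conc_field()].
#' @export
write_field <- function(field, path) {
  stopifnot(inherits(field, "conc_field"))
  g <- field$grid
  hdr <- c("# pmburden raster v1",
           paste("# species", field$species),
           paste("# scenario", field$scenario),
           "# units ug m-3",
           paste("# n_rows", g$n_rows), paste("# n_cols", g$n_cols),
           paste("# cell_size", format(g$cell_size, digits = 17)),
           paste("# origin", format(g$origin[1], digits = 17),
                 format(g$origin[2], digits = 17)))
  body <- apply(field$values, 1, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

parse_raster_header <- function(lines) {
  hdr <- lines[startsWith(lines, "#")]
  kv <- strsplit(sub("^#\\s*", "", hdr), "\\s+")
  vals <- stats::setNames(lapply(kv, `[`, -1), vapply(kv, `[`, character(1), 1))
  grid <- grid_spec(as.integer(vals$n_rows[1]), as.integer(vals$n_cols[1]),
                    as.numeric(vals$cell_size[1]), as.numeric(vals$origin))
  list(grid = grid, species = vals$species[1], scenario = vals$scenario[1],
       body = lines[!startsWith(lines, "#")])
}

read_matrix_body <- function(body, grid) {
  if (length(body) != grid$n_rows) stop("raster body does not match header n_rows")
  m <- t(vapply(strsplit(trimws(body), "\\s+"),
                function(r) as.numeric(r), numeric(grid$n_cols)))
  matrix(m, grid$n_rows, grid$n_cols)
}

#' @rdname write_field
#' @export
read_field <- function(path) {
  p <- parse_raster_header(readLines(path))
  conc_field(p$grid, p$species, p$scenario, read_matrix_body(p$body, p$grid))
}

#' Read and write a country mask as plain text
#'
#' Same layout as [write_field()] with country codes in the body and the
#' word `NONE` as the sea / out-of-domain sentinel.
#'
#' @param mask A [country_mask()].
#' @param path File path.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "country_mask"))
  g <- mask$grid
  codes <- mask$codes
  codes[is.na(codes)] <- "NONE"
  hdr <- c("# pmburden mask v1",
           paste("# n_rows", g$n_rows), paste("# n_cols", g$n_cols),
           paste("# cell_size", format(g$cell_size, digits = 17)),
           paste("# origin", format(g$origin[1], digits = 17),
                 format(g$origin[2], digits = 17)))
  writeLines(c(hdr, apply(codes, 1, paste, collapse = " ")), path)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  p <- parse_raster_header(readLines(path))
  g <- p$grid
  body <- strsplit(trimws(p$body), "\\s+")
  if (length(body) != g$n_rows) stop("mask body does not match header n_rows")
  codes <- t(vapply(body, function(r) r, character(g$n_cols)))
  codes <- matrix(codes, g$n_rows, g$n_cols)
  codes[codes == "NONE"] <- NA_character_
  country_mask(g, codes)
}

#' Read and write a population grid as CSV
#'
#' Long format with columns `row`, `col`, `age_group`, `persons`; zero cells
#' are omitted on write. Grid geometry travels in `#` header lines.
#'
#' @param pop A [population_grid()].
#' @param path File path.
#' @export
write_population <- function(pop, path) {
  stopifnot(inherits(pop, "population_grid"))
  g <- pop$grid
  hdr <- c("# pmburden population v1",
           paste("# n_rows", g$n_rows), paste("# n_cols", g$n_cols),
           paste("# cell_size", format(g$cell_size, digits = 17)),
           paste("# origin", format(g$origin[1], digits = 17),
                 format(g$origin[2], digits = 17)))
  idx <- which(pop$values > 0, arr.ind = TRUE)
  df <- data.frame(row = idx[, 1], col = idx[, 2],
                   age_group = adult_age_classes()[idx[, 3]],
                   persons = sprintf("%.17g", pop$values[idx]))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_population
#' @export
read_population <- function(path) {
  lines <- readLines(path)
  p <- parse_raster_header(lines[startsWith(lines, "#")])
  g <- p$grid
  df <- utils::read.csv(text = lines[!startsWith(lines, "#")],
                        stringsAsFactors = FALSE)
  ages <- adult_age_classes()
  vals <- array(0, dim = c(g$n_rows, g$n_cols, length(ages)),
                dimnames = list(NULL, NULL, ages))
  vals[cbind(df$row, df$col, match(df$age_group, ages))] <- as.numeric(df$persons)
  population_grid(g, vals)
}

#' Read and write baseline-mortality and curve tables as CSV
#'
#' `write_bmr`/`read_bmr` use columns `country, cause, age_group, rate`;
#' `write_erfs`/`read_erfs` use the curve-table format
#' `cause, age_group, conc, rr_central, rr_low, rr_high, tmrel` (one row per
#' knot; curves are stored TMREL-scaled).
#'
#' @param bmr A [bmr_table()]; `set` an [erf_set()] of tabulated curves.
#' @param path File path.
#' @export
write_bmr <- function(bmr, path) {
  utils::write.csv(as.data.frame(bmr), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_bmr
#' @export
read_bmr <- function(path) bmr_table(utils::read.csv(path, stringsAsFactors = FALSE))

#' @rdname write_bmr
#' @param set An [erf_set()] of [tabulated_erf()] curves.
#' @export
write_erfs <- function(set, path) {
  stopifnot(inherits(set, "erf_set"))
  rows <- lapply(set$curves, function(e) {
    stopifnot(inherits(e, "tabulated_erf"))
    data.frame(cause = e$cause, age_group = e$age_group, conc = e$knots,
               rr_central = e$rr_central, rr_low = e$rr_low, rr_high = e$rr_high,
               tmrel = e$tmrel, scaled = e$scaled, stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_bmr
#' @export
read_erfs <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  parts <- split(df, paste(df$cause, df$age_group, sep = "|"))
  erf_set(lapply(parts, function(d) {
    d <- d[order(d$conc), ]
    tabulated_erf(d$cause[1], d$age_group[1], d$conc, d$rr_central, d$rr_low,
                  d$rr_high, tmrel = d$tmrel[1], scaled = isTRUE(all(d$scaled)))
  }))
}

#' GEMM parameter table I/O
#'
#' CSV with columns `cause, age_group, theta, theta_se, alpha, mu, nu,
#' counterfactual`.
#' @param path File path.
#' @export
read_gemm_params <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  erf_set(lapply(seq_len(nrow(df)), function(i)
    gemm_params(df$cause[i], df$age_group[i], df$theta[i], df$theta_se[i],
                df$alpha[i], df$mu[i], df$nu[i], df$counterfactual[i])))
}

#' Write a complete synthetic study to a directory
#'
#' Emits every input the pipeline reads — one raster pair per scenario, the
#' population, mask, baseline-mortality and curve tables — in the package's
#' text formats.
#'
#' @param study A `synthetic_study` from [generate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(study$scenarios$fields)) {
    write_field(study$scenarios$fields[[nm]]$pm, file.path(dir, paste0("pm25_", nm, ".txt")))
    write_field(study$scenarios$fields[[nm]]$aca, file.path(dir, paste0("aca_", nm, ".txt")))
  }
  write_population(study$population, file.path(dir, "population.csv"))
  write_mask(study$mask, file.path(dir, "mask.txt"))
  write_bmr(study$bmr, file.path(dir, "bmr.csv"))
  write_erfs(study$erfs, file.path(dir, "erfs.csv"))
  invisible(dir)
}

#' Read a study back from a directory written by [write_study()]
#'
#' @param dir Directory containing the study files.
#' @param scenarios Scenario labels to load.
#' @return A list with the same elements as a `synthetic_study` (minus
#'   `spec` and `sectors`).
#' @export
read_study <- function(dir, scenarios = c("BASE", "RES100", "RES20", "TRA100", "TRA20")) {
  fields <- lapply(scenarios, function(nm) list(
    pm = read_field(file.path(dir, paste0("pm25_", nm, ".txt"))),
    aca = read_field(file.path(dir, paste0("aca_", nm, ".txt")))))
  names(fields) <- scenarios
  list(scenarios = scenario_set(fields),
       population = read_population(file.path(dir, "population.csv")),
       mask = read_mask(file.path(dir, "mask.txt")),
       bmr = read_bmr(file.path(dir, "bmr.csv")),
       erfs = read_erfs(file.path(dir, "erfs.csv")))
}
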