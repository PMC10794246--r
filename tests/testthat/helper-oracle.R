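# Independent oracles, deliberately kept free of the package's evaluation
# path: manual linear interpolation and a plain triple loop over cells,
# causes and ages.

# linear interpolation with constant extrapolation, written out by hand
lin_interp <- function(xs, ys, x) {
  if (x <= xs[1]) return(ys[1])
  if (x >= xs[length(xs)]) return(ys[length(ys)])
  i <- max(which(xs <= x))
  ys[i] + (ys[i + 1] - ys[i]) * (x - xs[i]) / (xs[i + 1] - xs[i])
}

# RR of a tabulated curve, oracle version
oracle_rr <- function(erf, conc, branch) {
  if (conc <= erf$tmrel) return(1)
  ys <- switch(branch, central = erf$rr_central, low = erf$rr_low, high = erf$rr_high)
  lin_interp(erf$knots, ys, conc)
}

# GEMM closed form re-written independently
oracle_gemm_rr <- function(p, conc, branch) {
  th <- p$theta + c(central = 0, low = -1.96, high = 1.96)[[branch]] * p$theta_se
  th <- max(th, 0)
  z <- max(0, conc - p$counterfactual)
  exp(th * log(1 + z / p$alpha) / (1 + exp(-(z - p$mu) / p$nu)))
}

# Brute-force excess mortality: explicit loop over cells x causes x ages x
# branches, per-cell country lookup from the mask, AF written inline.
oracle_excess_mortality <- function(conc, pop, bmr, erfs, mask) {
  causes <- cause_registry()
  ages <- adult_age_classes()
  branches <- c("central", "low", "high")
  nr <- conc$grid$n_rows; nc <- conc$grid$n_cols
  out <- array(0, dim = c(nr, nc, nrow(causes), length(ages), length(branches)),
               dimnames = list(NULL, NULL, causes$code, ages, branches))
  bdf <- as.data.frame(bmr)
  for (r in seq_len(nr)) for (cl in seq_len(nc)) {
    co <- mask$codes[r, cl]
    if (is.na(co)) next
    cc <- conc$values[r, cl]
    for (j in seq_len(nrow(causes))) for (k in seq_along(ages)) {
      rate <- bdf$rate[bdf$country == co & bdf$cause == causes$code[j] &
                         bdf$age_group == ages[k]]
      erf <- get_erf(erfs, causes$code[j], ages[k])
      for (b in seq_along(branches)) {
        rr <- if (inherits(erf, "tabulated_erf")) oracle_rr(erf, cc, branches[b])
              else oracle_gemm_rr(erf, cc, branches[b])
        out[r, cl, j, k, b] <- rate * pop$values[r, cl, k] * (rr - 1) / rr
      }
    }
  }
  out
}
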