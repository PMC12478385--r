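#' NCI-60 percent growth
#'
#' The developmental-therapeutics two-branch convention with time-zero
#' correction: `PG = 100 * (Ti - Tz) / (C - Tz)` when the treated signal
#' `Ti` is at least the time-zero signal `Tz` (net growth), and
#' `PG = 100 * (Ti - Tz) / Tz` otherwise (net kill, bounded below by
#' -100). Both branches give 0 at `Ti = Tz`, so PG is continuous there.
#'
#' @param ti treated signal(s) after the incubation.
#' @param tz time-zero signal.
#' @param c0 untreated-control signal after the incubation.
#' @return percent growth, same length as `ti`.
#' @export
percent_growth <- function(ti, tz, c0) {
  if (c0 == tz) stop("control equals time-zero; PG undefined", call. = FALSE)
  if (tz == 0 && any(ti < tz))
    stop("time-zero of 0 with net-kill signals; PG undefined", call. = FALSE)
  ifelse(ti >= tz, 100 * (ti - tz) / (c0 - tz), 100 * (ti - tz) / tz)
}

#' GI50 by log-dose interpolation
#'
#' The concentration at which percent growth crosses `level` (default 50),
#' found by linear interpolation in log10(dose) between the bracketing
#' dose pair. When PG equals `level` exactly at a tested dose, that dose
#' is returned. If PG never falls below `level` the value is censored at
#' the highest tested dose (`> max`); if PG is below `level` everywhere it
#' is censored at the lowest (`< min`). With multiple crossings the first
#' is used and flagged.
#'
#' @param doses dose ladder (uM, > 0), ascending.
#' @param pg percent growth at each dose.
#' @param level crossing level (default 50).
#' @return list: `gi50` (uM), `censored` (`"none"`, `"above_max"`,
#'   `"below_min"`), `multiple_crossings` flag.
#' @export
compute_gi50 <- function(doses, pg, level = 50) {
  if (length(doses) < 2L) stop("need at least 2 doses", call. = FALSE)
  if (is.unsorted(doses)) {
    ord <- order(doses)
    doses <- doses[ord]; pg <- pg[ord]
  }
  below <- pg < level
  crossings <- which(diff(!below) != 0)
  multiple <- length(crossings) > 1L
  if (multiple) warning("PG crosses the level more than once; using the first")
  exact <- which(pg == level)
  if (length(exact))
    return(list(gi50 = doses[exact[1]], censored = "none",
                multiple_crossings = multiple))
  if (all(!below))
    return(list(gi50 = max(doses), censored = "above_max",
                multiple_crossings = FALSE))
  if (all(below))
    return(list(gi50 = min(doses), censored = "below_min",
                multiple_crossings = FALSE))
  i <- crossings[1]
  lx <- log10(doses)
  frac <- (level - pg[i]) / (pg[i + 1] - pg[i])
  list(gi50 = 10^(lx[i] + frac * (lx[i + 1] - lx[i])), censored = "none",
       multiple_crossings = multiple)
}

#' Growth curves and GI50s from a viability table
#'
#' Averages replicate signals per dose, converts them to percent growth
#' against the cell line's time-zero and untreated-control wells, and
#' computes the interpolated GI50 per (cell line, compound).
#'
#' @param table a viability data.frame with columns `cell_line`,
#'   `compound`, `role` (`TREATED` / `TZERO` / `CONTROL`), `dose`,
#'   `replicate`, `signal` (as from [generate_viability_dataset()]).
#' @param level GI level (default 50).
#' @return data.frame: one row per (cell_line, compound) with `gi50`,
#'   `censored`, plus an attribute `"curves"` holding the per-dose PG
#'   table.
#' @export
growth_curves <- function(table, level = 50) {
  split_keys <- interaction(table$cell_line, table$compound, drop = TRUE)
  res <- lapply(split(table, split_keys), function(d) {
    tz <- mean(d$signal[d$role == "TZERO"])
    c0 <- mean(d$signal[d$role == "CONTROL"])
    if (!is.finite(tz) || !is.finite(c0))
      stop("missing TZERO or CONTROL rows", call. = FALSE)
    tr <- d[d$role == "TREATED", ]
    means <- aggregate(signal ~ dose, data = tr, FUN = mean)
    means <- means[order(means$dose), ]
    pg <- percent_growth(means$signal, tz, c0)
    g <- compute_gi50(means$dose, pg, level)
    list(row = data.frame(cell_line = d$cell_line[1], compound = d$compound[1],
                          gi50 = g$gi50, censored = g$censored),
         curve = data.frame(cell_line = d$cell_line[1],
                            compound = d$compound[1], dose = means$dose,
                            percent_growth = pg))
  })
  out <- do.call(rbind, lapply(res, `[[`, "row"))
  rownames(out) <- NULL
  attr(out, "curves") <- do.call(rbind, lapply(res, `[[`, "curve"))
  out
}

#' GI50 by four-parameter logistic fit
#'
#' Fits a 4PL to viability (or percent growth) versus log10 dose and
#' reports the midpoint concentration, with the same convergence contract
#' as [fit_inhibition_curve()].
#'
#' @param doses dose ladder (>= 4 levels).
#' @param viability_fraction viability (or PG) at each dose; any
#'   monotone-decreasing response works, the midpoint is taken relative to
#'   its own plateaus.
#' @return A `dose_response_fit` (see [fit_inhibition_curve()]); `ic50` is
#'   the fitted GI50.
#' @export
fit_logistic_gi50 <- function(doses, viability_fraction) {
  fit_inhibition_curve(doses, viability_fraction)
}
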