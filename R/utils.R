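## internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Clamp values to an interval
#' @noRd
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Multiplicative log-normal noise factors with a given coefficient of
#' variation. CV is on the natural scale; sdlog = sqrt(log(1 + cv^2)) gives
#' E[factor] close to 1 for the moderate CVs used here.
#' @noRd
lognormal_noise <- function(n, cv) {
  if (cv < 0) stop("noise_cv must be non-negative", call. = FALSE)
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(rnorm(n, mean = -sdlog^2 / 2, sd = sdlog))
}

#' Fractional inhibition of a one-site competition curve
#'
#' Fraction of baseline signal competed away at dose `d` for a site with
#' half-maximal competition at `ic50` and Hill slope `hill`:
#' d^h / (d^h + ic50^h). Returns 0 at d = 0.
#' @noRd
hill_inhibition <- function(d, ic50, hill = 1) {
  ifelse(d <= 0, 0, d^hill / (d^hill + ic50^hill))
}

#' Four-parameter logistic in dose
#'
#' `bottom + (top - bottom) / (1 + (d/ic50)^hill)` — decreasing in dose for
#' hill > 0, equal to `top` at dose 0 and to the midpoint at `d = ic50`.
#' @param dose numeric vector of doses (same units as `ic50`).
#' @param top,bottom upper and lower plateaus.
#' @param ic50 midpoint concentration (> 0).
#' @param hill Hill slope (> 0 for a decreasing curve).
#' @return numeric vector of responses.
#' @export
four_pl <- function(dose, top, bottom, ic50, hill = 1) {
  stopifnot(ic50 > 0)
  bottom + (top - bottom) * (1 - hill_inhibition(dose, ic50, hill))
}

#' @noRd
stop_if_not_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0)
    stop(sprintf("`%s` must be a positive scalar", name), call. = FALSE)
}
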