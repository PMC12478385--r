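#' Fit a constrained four-parameter logistic inhibition curve
#'
#' Fits `y = bottom + (top - bottom) / (1 + 10^(hill * (log10(d) - log10(ic50))))`
#' to response-versus-dose data by bounded Levenberg-Marquardt least squares.
#' The vehicle (dose 0) point enters at the model's zero-dose limit (the
#' logistic term vanishes exactly, so the vehicle pins the upper plateau
#' without biasing the midpoint, unlike a finite pseudo-dose would).
#' The top plateau is constrained to within 20% of the vehicle mean and the
#' bottom to `[0, top]`, so a fitted IC50 is always the concentration of
#' half-maximal loss relative to vehicle.
#'
#' @param doses numeric vector of doses (uM), may include 0 (vehicle).
#' @param response numeric vector of responses at those doses (e.g. mean
#'   stoichiometry in percent, or viability fraction).
#' @param hill_bounds length-2 numeric, allowed Hill slope range.
#' @param top_window fractional window around the vehicle mean within which
#'   the top plateau may move.
#' @return A `dose_response_fit` list with elements `ic50`, `hill`, `top`,
#'   `bottom`, `rss`, `converged`, and `insensitive` (TRUE when the fitted
#'   midpoint lies above the tested range or the fitted dynamic range is
#'   negligible). `ic50` is `NA` when the optimizer fails.
#' @examples
#' d <- c(0, 0.1, 1, 10, 30)
#' y <- four_pl(d, top = 40, bottom = 0, ic50 = 1)
#' fit_inhibition_curve(d, y)$ic50
#' @export
fit_inhibition_curve <- function(doses, response,
                                 hill_bounds = c(0.2, 5),
                                 top_window = 0.2) {
  stopifnot(length(doses) == length(response))
  keep <- is.finite(doses) & is.finite(response)
  doses <- doses[keep]; response <- response[keep]
  if (length(unique(doses)) < 4L)
    stop("need at least 4 dose levels to fit a 4PL", call. = FALSE)
  nz <- doses[doses > 0]
  # dose 0 -> -Inf on the log axis; 10^(hill * (-Inf - l50)) is exactly 0,
  # so the vehicle point contributes `top` with no midpoint bias
  lx <- ifelse(doses <= 0, -Inf, log10(doses))

  top0 <- if (any(doses <= 0)) mean(response[doses <= 0]) else max(response)
  top0 <- max(top0, .Machine$double.eps)
  fail <- structure(
    list(ic50 = NA_real_, hill = NA_real_, top = top0, bottom = NA_real_,
         rss = NA_real_, converged = FALSE, insensitive = NA),
    class = "dose_response_fit")

  lower <- c(top = top0 * (1 - top_window), bottom = 0,
             l50 = log10(min(nz)) - 2, hill = hill_bounds[1])
  upper <- c(top = top0 * (1 + top_window), bottom = top0,
             l50 = max(lx) + 2, hill = hill_bounds[2])
  # start l50 where the response crosses the plateau midpoint; the
  # optimizer can report a singular initial Jacobian for some start/bound
  # combinations, so a short cascade of perturbed starts is tried
  mid <- (top0 + min(response)) / 2
  l50_mid <- clamp(lx[which.min(abs(response - mid))],
                   lower[["l50"]], upper[["l50"]])
  l50_med <- stats::median(lx[is.finite(lx)])
  top_start <- clamp(top0 * 1.001, lower[["top"]], upper[["top"]])
  starts <- list(
    list(top = top_start, bottom = clamp(0.5 * min(response), 0,
                                         upper[["bottom"]]),
         l50 = l50_mid, hill = 1),
    list(top = top_start, bottom = 0, l50 = l50_mid, hill = 1),
    list(top = top_start, bottom = 0, l50 = l50_med, hill = 1.2),
    list(top = clamp(top0 * 1.05, lower[["top"]], upper[["top"]]),
         bottom = 0, l50 = clamp(l50_med + 0.5, lower[["l50"]],
                                 upper[["l50"]]), hill = 0.8))
  fit <- NULL
  for (start in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        response ~ bottom + (top - bottom) / (1 + 10^(hill * (lx - l50))),
        start = start, lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) return(fail)

  p <- coef(fit)
  ic50 <- 10^p[["l50"]]
  span <- p[["top"]] - p[["bottom"]]
  insensitive <- ic50 > max(nz) || span < 0.05 * p[["top"]]
  structure(
    list(ic50 = ic50, hill = p[["hill"]], top = p[["top"]],
         bottom = p[["bottom"]], rss = sum(resid(fit)^2),
         converged = !insensitive || span >= 0.05 * p[["top"]],
         insensitive = insensitive),
    class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  if (!x$converged || is.na(x$ic50)) {
    cat("4PL fit: not converged\n")
  } else {
    cat(sprintf("4PL fit: IC50 = %.4g uM, hill = %.2f, top = %.3g, bottom = %.3g%s\n",
                x$ic50, x$hill, x$top, x$bottom,
                if (isTRUE(x$insensitive)) " [insensitive]" else ""))
  }
  invisible(x)
}
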