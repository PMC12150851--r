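#' Willingness-to-pay thresholds from per-capita GDP
#'
#' Stores GDP once and derives each threshold as the cent-rounded product
#' with its multiplier, avoiding rounding drift between thresholds.
#'
#' @param gdp_per_capita 2024 per-capita GDP, $ (default 12,240.62, i.e.
#'   36,721.86 / 3).
#' @param multipliers GDP multiples (default 1.5, 1.94 and 3: the monetary
#'   value of a QALY for general health gains, the end-stage-disease value,
#'   and the guideline ceiling for severe disease).
#' @return Data frame with columns \code{multiplier} and \code{threshold}.
#' @export
wtp_thresholds <- function(gdp_per_capita = 12240.62,
                           multipliers = c(1.5, 1.94, 3.0)) {
  stopifnot(gdp_per_capita > 0, all(multipliers > 0))
  data.frame(multiplier = multipliers,
             threshold = round(multipliers * gdp_per_capita, 2))
}

#' Affine coefficients of the ICER-price relationship
#'
#' Incremental cost is affine in the ACI per-cycle price,
#' \eqn{\Delta C(p) = \Delta C_0 + \beta p}, with slope \eqn{\beta} equal to
#' the discounted PFS occupancy summed over the ACI-dosed induction cycles;
#' incremental QALY does not depend on price. The coefficients are recovered
#' from two full model evaluations (at price 0 and at \code{probe_price})
#' and verified against a third; detected nonlinearity is an error (callers
#' may then fall back to \code{\link{solve_price}}'s bisection).
#'
#' @param cs_control,cs_aci Curve sets.
#' @param econ Economic parameters.
#' @param settings Model settings.
#' @param probe_price Positive probe price (default 1000).
#' @return List with \code{delta_cost0}, \code{slope} and \code{delta_qaly}.
#' @export
icer_price_coefficients <- function(
    cs_control = calibrated_curve_set(arm = "control"),
    cs_aci = calibrated_curve_set(arm = "aci"),
    econ = default_econ_params(), settings = model_settings(),
    probe_price = 1000) {
  stopifnot(probe_price > 0)
  at_price <- function(p) {
    econ$aci_price_per_cycle <- p
    fit <- cea(cs_control, cs_aci, econ, settings)
    c(dc = fit$incremental_cost, de = fit$incremental_qaly)
  }
  r0 <- at_price(0)
  r1 <- at_price(probe_price)
  slope <- (r1[["dc"]] - r0[["dc"]]) / probe_price
  r2 <- at_price(2 * probe_price)
  pred <- r0[["dc"]] + slope * 2 * probe_price
  if (abs(pred - r2[["dc"]]) > 1e-6 * max(1, abs(r2[["dc"]])))
    stop("incremental cost is not affine in the ACI price")
  list(delta_cost0 = r0[["dc"]], slope = slope, delta_qaly = r0[["de"]])
}

#' Maximum ACI price satisfying a willingness-to-pay threshold
#'
#' Closed-form inversion of the affine ICER-price relationship,
#' \eqn{p^\star = (\lambda \Delta E - \Delta C_0)/\beta}, floored at zero,
#' cross-checked by bisection of the full model over [0, 1e6] to $0.01.
#'
#' @param wtp Willingness-to-pay threshold, $/QALY.
#' @param coefficients As from \code{\link{icer_price_coefficients}}.
#' @param cs_control,cs_aci,econ,settings Model inputs for the bisection
#'   cross-check; set \code{bisection = FALSE} to skip it.
#' @param bisection Run the bisection cross-check (default \code{TRUE}).
#' @return List of class \code{"price_solve"}: \code{wtp},
#'   \code{price_star}, \code{icer_at_price_star}, \code{achievable},
#'   \code{method}, and \code{price_bisect} when cross-checked.
#' @export
solve_price <- function(wtp, coefficients,
                        cs_control = calibrated_curve_set(arm = "control"),
                        cs_aci = calibrated_curve_set(arm = "aci"),
                        econ = default_econ_params(),
                        settings = model_settings(),
                        bisection = TRUE) {
  stopifnot(coefficients$slope > 0, coefficients$delta_qaly > 0)
  raw <- (wtp * coefficients$delta_qaly - coefficients$delta_cost0) /
    coefficients$slope
  achievable <- raw >= 0
  price_star <- max(0, raw)
  icer_at <- (coefficients$delta_cost0 + coefficients$slope * price_star) /
    coefficients$delta_qaly
  out <- list(wtp = wtp, price_star = price_star,
              icer_at_price_star = icer_at, achievable = achievable,
              method = "closed_form")
  if (bisection && achievable) {
    f <- function(p) {
      econ$aci_price_per_cycle <- p
      fit <- cea(cs_control, cs_aci, econ, settings)
      fit$icer - wtp
    }
    if (f(0) > 0) {
      out$price_bisect <- 0
    } else {
      out$price_bisect <- stats::uniroot(f, c(0, 1e6), tol = 0.001)$root
    }
  }
  structure(out, class = "price_solve")
}

#' Price ceilings across the GDP-multiple thresholds
#'
#' @param thresholds As from \code{\link{wtp_thresholds}}.
#' @param cs_control,cs_aci,econ,settings Model inputs.
#' @param bisection Cross-check each solution by bisection.
#' @return Data frame with \code{multiplier}, \code{threshold},
#'   \code{price_star} and \code{achievable}.
#' @export
price_ceilings <- function(thresholds = wtp_thresholds(),
                           cs_control = calibrated_curve_set(arm = "control"),
                           cs_aci = calibrated_curve_set(arm = "aci"),
                           econ = default_econ_params(),
                           settings = model_settings(),
                           bisection = FALSE) {
  coefs <- icer_price_coefficients(cs_control, cs_aci, econ, settings)
  sol <- lapply(thresholds$threshold, solve_price, coefficients = coefs,
                cs_control = cs_control, cs_aci = cs_aci, econ = econ,
                settings = settings, bisection = bisection)
  data.frame(multiplier = thresholds$multiplier,
             threshold = thresholds$threshold,
             price_star = vapply(sol, `[[`, numeric(1), "price_star"),
             achievable = vapply(sol, `[[`, logical(1), "achievable"))
}

#' @export
print.price_solve <- function(x, ...) {
  fm <- function(v) formatC(v, format = "f", digits = 2, big.mark = ",")
  cat("Value-based price at WTP $", fm(x$wtp), "/QALY: $",
      fm(x$price_star), " per cycle", sep = "")
  if (!x$achievable) cat(" (not achievable at any non-negative price)")
  cat("\n")
  if (!is.null(x$price_bisect))
    cat("  bisection cross-check: $", fm(x$price_bisect), "\n", sep = "")
  invisible(x)
}
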