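#' Time-horizon scenario analysis
#'
#' Re-runs the full base-case evaluation at each requested horizon with all
#' other settings fixed.
#'
#' @param cs_control,cs_aci Curve sets.
#' @param econ Economic parameters.
#' @param years_list Horizons in years (default 10, 15, 20).
#' @param settings Template settings (discount, cycle length, half-cycle
#'   flag); the horizon and cycle count are overridden per scenario.
#' @return Data frame with one row per horizon: per-arm totals, increments
#'   and ICER; the full \code{"cea"} fits are attached as attribute
#'   \code{fits}.
#' @export
horizon_scenarios <- function(cs_control = calibrated_curve_set(arm = "control"),
                              cs_aci = calibrated_curve_set(arm = "aci"),
                              econ = default_econ_params(),
                              years_list = c(10, 15, 20),
                              settings = model_settings()) {
  if (length(years_list) == 0L) stop("empty horizon list")
  fits <- lapply(years_list, function(y) {
    s <- model_settings(horizon_years = y, cycle_days = settings$cycle_days,
                        discount_annual = settings$discount_annual,
                        half_cycle = settings$half_cycle)
    cea(cs_control, cs_aci, econ, s)
  })
  out <- data.frame(
    horizon_years = years_list,
    cost_aci = vapply(fits, function(f) f$arms$aci$total_cost, numeric(1)),
    cost_control = vapply(fits, function(f) f$arms$control$total_cost,
                          numeric(1)),
    qaly_aci = vapply(fits, function(f) f$arms$aci$total_qaly, numeric(1)),
    qaly_control = vapply(fits, function(f) f$arms$control$total_qaly,
                          numeric(1)),
    icer = vapply(fits, function(f) f$icer, numeric(1)),
    label = vapply(fits, function(f) f$label, character(1)))
  attr(out, "fits") <- fits
  out
}

#' Distribution cross-validation grid
#'
#' Pairs every screened control-arm curve set with every screened ACI-arm
#' curve set (the full Cartesian product), evaluates each arm's cohort run
#' through the transition-matrix path, and summarizes the ICER distribution
#' of all pairings. Supplied sets are expected to have passed
#' \code{\link{screen_pair}}. Since each arm's costs and QALYs depend only on
#' its own curve set, per-arm totals are computed once per set and then
#' crossed.
#'
#' @param control_sets,treat_sets Lists of \code{"curve_set"} objects.
#' @param econ Economic parameters.
#' @param wtp Willingness-to-pay threshold for the cost-effective fraction.
#' @param settings Model settings.
#' @return An object of class \code{"crossval_report"}: list with counts,
#'   the per-pair ICER vector, \code{fraction_cost_effective},
#'   \code{icer_min}, \code{icer_max} and the per-pair increments.
#' @export
crossval_grid <- function(control_sets, treat_sets,
                          econ = default_econ_params(),
                          wtp = 36721.86,
                          settings = model_settings()) {
  if (length(control_sets) == 0L || length(treat_sets) == 0L)
    stop("empty curve-set list")
  eval_arm <- function(cs, arm) {
    tr <- run_markov(transition_matrices(cs, settings)$matrices,
                     settings = settings)
    accumulate(tr, arm, econ, settings)
  }
  ctrl <- lapply(control_sets, eval_arm, arm = "control")
  trt <- lapply(treat_sets, eval_arm, arm = "aci")
  cc <- vapply(ctrl, `[[`, numeric(1), "total_cost")
  ce <- vapply(ctrl, `[[`, numeric(1), "total_qaly")
  tc <- vapply(trt, `[[`, numeric(1), "total_cost")
  te <- vapply(trt, `[[`, numeric(1), "total_qaly")
  dcost <- outer(tc, cc, `-`)          # treat x control
  dqaly <- outer(te, ce, `-`)
  icers <- ifelse(abs(dqaly) > 1e-12, dcost / dqaly, NA)
  accept <- dcost <= wtp * dqaly
  valid <- is.finite(icers) & dqaly > 0
  structure(list(
    n_control_combos = length(control_sets),
    n_treat_combos = length(treat_sets),
    n_pairs = length(control_sets) * length(treat_sets),
    icer = as.vector(icers),
    dcost = as.vector(dcost), dqaly = as.vector(dqaly),
    fraction_cost_effective = mean(accept),
    icer_min = if (any(valid)) min(icers[valid]) else NA_real_,
    icer_max = if (any(valid)) max(icers[valid]) else NA_real_,
    wtp = wtp), class = "crossval_report")
}

#' @export
print.crossval_report <- function(x, ...) {
  fm <- function(v) formatC(v, format = "f", digits = 2, big.mark = ",")
  cat("Distribution cross-validation: ", x$n_control_combos, " control x ",
      x$n_treat_combos, " treatment = ", x$n_pairs, " pairs\n", sep = "")
  cat("  ICER range: $", fm(x$icer_min), " - $", fm(x$icer_max),
      "/QALY\n", sep = "")
  cat("  cost-effective at WTP $", fm(x$wtp), ": ",
      formatC(100 * x$fraction_cost_effective, format = "f", digits = 2),
      "%\n", sep = "")
  invisible(x)
}

#' Build screened curve sets from fitted families
#'
#' Crosses the converged PFS and OS fits of one arm and keeps the pairs
#' passing the OS >= PFS screen on the cycle grid.
#'
#' @param arm_label Arm name.
#' @param pfs_fits,os_fits Lists of \code{"parsurv"} fits.
#' @param settings Model settings (supplies the screening grid).
#' @return List of screened \code{"curve_set"} objects.
#' @export
screened_curve_sets <- function(arm_label, pfs_fits, os_fits,
                                settings = model_settings()) {
  grid <- cycle_times(settings)
  out <- list()
  for (sp in pfs_fits) for (so in os_fits) {
    if (!isTRUE(sp$converged) || !isTRUE(so$converged)) next
    cs <- curve_set(arm_label, sp, so)
    if (screen_pair(cs, grid)) out[[length(out) + 1L]] <- cs
  }
  out
}

#' Assemble a plain-markdown analysis report
#'
#' Collects the stage outputs into a single six-section document
#' (base case, horizons, one-way sensitivity, probabilistic sensitivity,
#' price simulation, cross-validation); missing stages are flagged in place.
#'
#' @param base_case A \code{"cea"} fit, required.
#' @param horizons Optional data frame from \code{\link{horizon_scenarios}}.
#' @param owsa_res Optional \code{"owsa"} object.
#' @param psa_res Optional \code{"psa"} object.
#' @param price_table Optional data frame from \code{\link{price_ceilings}}.
#' @param crossval Optional \code{"crossval_report"}.
#' @param file Optional path; when given the document is also written there.
#' @return The report as a character vector of markdown lines, invisibly
#'   when written to file.
#' @export
assemble_report <- function(base_case, horizons = NULL, owsa_res = NULL,
                            psa_res = NULL, price_table = NULL,
                            crossval = NULL, file = NULL) {
  stopifnot(inherits(base_case, "cea"))
  fm <- function(v) formatC(v, format = "f", digits = 2, big.mark = ",")
  sec <- function(title, body) c(paste("##", title), "", body, "")
  lines <- c("# Cost-effectiveness analysis report", "")
  lines <- c(lines, sec("Base case", c(
    "| Group | Total cost ($) | Total QALY |",
    "|---|---|---|",
    paste0("| ACI | ", fm(base_case$arms$aci$total_cost), " | ",
           formatC(base_case$arms$aci$total_qaly, format = "f", digits = 2),
           " |"),
    paste0("| Control | ", fm(base_case$arms$control$total_cost), " | ",
           formatC(base_case$arms$control$total_qaly, format = "f",
                   digits = 2), " |"),
    "",
    paste0("Incremental cost $", fm(base_case$incremental_cost),
           ", incremental QALY ",
           formatC(base_case$incremental_qaly, format = "f", digits = 2),
           ", ICER ",
           if (base_case$label == "icer")
             paste0("$", fm(base_case$icer), "/QALY")
           else base_case$label, "."))))
  lines <- c(lines, sec("Time-horizon scenarios",
    if (is.null(horizons)) "*Stage not run.*"
    else c("| Horizon (y) | ICER ($/QALY) |", "|---|---|",
           paste0("| ", horizons$horizon_years, " | ", fm(horizons$icer),
                  " |"))))
  lines <- c(lines, sec("One-way sensitivity analysis",
    if (is.null(owsa_res)) "*Stage not run.*"
    else paste0("Top driver: ", owsa_res$parameter[1], " (ICER range $",
                fm(owsa_res$range[1]), ").")))
  lines <- c(lines, sec("Probabilistic sensitivity analysis",
    if (is.null(psa_res)) "*Stage not run.*"
    else paste0(nrow(psa_res), " Monte Carlo iterations; mean incremental ",
                "QALY ", formatC(mean(psa_res$dqaly), format = "f",
                                 digits = 2), ".")))
  lines <- c(lines, sec("Price simulation",
    if (is.null(price_table)) "*Stage not run.*"
    else c("| GDP multiple | WTP ($/QALY) | Max price ($/cycle) |",
           "|---|---|---|",
           paste0("| ", price_table$multiplier, " | ",
                  fm(price_table$threshold), " | ",
                  fm(price_table$price_star), " |"))))
  lines <- c(lines, sec("Distribution cross-validation",
    if (is.null(crossval)) "*Stage not run.*"
    else paste0(crossval$n_pairs, " pairings; ",
                formatC(100 * crossval$fraction_cost_effective,
                        format = "f", digits = 2),
                "% cost-effective; ICER range $", fm(crossval$icer_min),
                " - $", fm(crossval$icer_max), "/QALY.")))
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}
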