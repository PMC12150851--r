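#' Set one analysis parameter by name
#'
#' Shared parameter-addressing used by the one-way and probabilistic
#' sensitivity analyses. \code{"discount_rate"} lives in the model settings;
#' everything else lives in the economic parameter list.
#' \code{"ae_cost_scale"} scales the whole adverse-event cost column
#' (baseline 1).
#'
#' @param econ Economic parameters.
#' @param settings Model settings.
#' @param name Parameter name (see \code{\link{default_owsa_ranges}}).
#' @param value New value.
#' @return List with updated \code{econ} and \code{settings}.
#' @export
set_econ_param <- function(econ, settings, name, value) {
  switch(name,
    discount_rate = { settings$discount_annual <- value },
    u_pd = { econ$utilities$u_pd <- value },
    u_pfs_aci = { econ$utilities$u_pfs_aci <- value },
    u_pfs_control = { econ$utilities$u_pfs_control <- value },
    aci_price_per_cycle = { econ$aci_price_per_cycle <- value },
    price_bevacizumab = { econ$drug_prices$bevacizumab <- value },
    price_oxaliplatin = { econ$drug_prices$oxaliplatin <- value },
    price_capecitabine = { econ$drug_prices$capecitabine <- value },
    subsequent_tx_cost = { econ$subsequent_tx$cost <- value },
    subsequent_tx_prob_aci = { econ$subsequent_tx$prob_aci <- value },
    subsequent_tx_prob_control = { econ$subsequent_tx$prob_control <- value },
    bsc_cost_per_cycle = { econ$bsc_cost_per_cycle <- value },
    followup_cost_per_cycle = { econ$followup_cost_per_cycle <- value },
    terminal_cost = { econ$terminal_cost <- value },
    ae_cost_scale = { econ$ae$cost <- econ$ae$cost_base * value },
    stop("unknown parameter: ", name))
  econ$ae$cost_base <- NULL
  list(econ = econ, settings = settings)
}

.get_econ_param <- function(econ, settings, name) {
  switch(name,
    discount_rate = settings$discount_annual,
    u_pd = econ$utilities$u_pd,
    u_pfs_aci = econ$utilities$u_pfs_aci,
    u_pfs_control = econ$utilities$u_pfs_control,
    aci_price_per_cycle = econ$aci_price_per_cycle,
    price_bevacizumab = econ$drug_prices$bevacizumab,
    price_oxaliplatin = econ$drug_prices$oxaliplatin,
    price_capecitabine = econ$drug_prices$capecitabine,
    subsequent_tx_cost = econ$subsequent_tx$cost,
    subsequent_tx_prob_aci = econ$subsequent_tx$prob_aci,
    subsequent_tx_prob_control = econ$subsequent_tx$prob_control,
    bsc_cost_per_cycle = econ$bsc_cost_per_cycle,
    followup_cost_per_cycle = econ$followup_cost_per_cycle,
    terminal_cost = econ$terminal_cost,
    ae_cost_scale = 1,
    stop("unknown parameter: ", name))
}

#' Default one-way sensitivity ranges
#'
#' Cost and utility parameters vary by +/- 25% around baseline except the
#' higher-uncertainty adverse-event, best-supportive-care and terminal-care
#' costs, which vary by +/- 30%; the discount rate spans its accepted 0-8%
#' range; utility highs are capped at 1.
#'
#' @param econ Economic parameters.
#' @param settings Model settings.
#' @return Data frame with columns \code{parameter}, \code{low},
#'   \code{high}, \code{kind} (\code{"cost"}, \code{"utility"},
#'   \code{"probability"} or \code{"rate"}).
#' @export
default_owsa_ranges <- function(econ = default_econ_params(),
                                settings = model_settings()) {
  pm <- function(name, frac, kind) {
    base <- .get_econ_param(econ, settings, name)
    lo <- base * (1 - frac); hi <- base * (1 + frac)
    if (kind %in% c("utility", "probability")) hi <- min(hi, 1)
    data.frame(parameter = name, low = lo, high = hi, kind = kind)
  }
  rbind(
    pm("u_pd", 0.25, "utility"),
    pm("u_pfs_aci", 0.25, "utility"),
    pm("u_pfs_control", 0.25, "utility"),
    data.frame(parameter = "discount_rate", low = 0, high = 0.08,
               kind = "rate"),
    pm("aci_price_per_cycle", 0.25, "cost"),
    pm("price_bevacizumab", 0.25, "cost"),
    pm("price_oxaliplatin", 0.25, "cost"),
    pm("price_capecitabine", 0.25, "cost"),
    pm("subsequent_tx_cost", 0.25, "cost"),
    pm("subsequent_tx_prob_aci", 0.25, "probability"),
    pm("subsequent_tx_prob_control", 0.25, "probability"),
    pm("ae_cost_scale", 0.30, "cost"),
    pm("bsc_cost_per_cycle", 0.30, "cost"),
    pm("followup_cost_per_cycle", 0.25, "cost"),
    pm("terminal_cost", 0.30, "cost")
  )
}

.eval_icer <- function(cs_control, cs_aci, econ, settings, name, value) {
  upd <- set_econ_param(econ, settings, name, value)
  fit <- cea(cs_control, cs_aci, upd$econ, upd$settings)
  fit$icer
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' Each parameter is set in turn to its lower and upper bound with all others
#' at baseline; the model is fully re-evaluated at each bound. Rows are
#' sorted by the absolute ICER range, descending, ready for a tornado
#' diagram.
#'
#' @param cs_control,cs_aci Curve sets for the two arms.
#' @param econ Economic parameters.
#' @param settings Model settings.
#' @param ranges Data frame as from \code{\link{default_owsa_ranges}}.
#' @return An object of class \code{"owsa"}: the ranges with columns
#'   \code{icer_low}, \code{icer_high}, \code{range}, plus attribute
#'   \code{base_icer}.
#' @export
owsa <- function(cs_control = calibrated_curve_set(arm = "control"),
                 cs_aci = calibrated_curve_set(arm = "aci"),
                 econ = default_econ_params(),
                 settings = model_settings(),
                 ranges = default_owsa_ranges(econ, settings)) {
  econ$ae$cost_base <- econ$ae$cost     # baseline for ae_cost_scale
  base <- cea(cs_control, cs_aci, econ, settings)
  res <- ranges
  res$icer_low <- vapply(seq_len(nrow(ranges)), function(i)
    .eval_icer(cs_control, cs_aci, econ, settings,
               ranges$parameter[i], ranges$low[i]), numeric(1))
  res$icer_high <- vapply(seq_len(nrow(ranges)), function(i)
    .eval_icer(cs_control, cs_aci, econ, settings,
               ranges$parameter[i], ranges$high[i]), numeric(1))
  res$range <- abs(res$icer_high - res$icer_low)
  res <- res[order(-res$range), ]
  rownames(res) <- NULL
  structure(res, class = c("owsa", "data.frame"), base_icer = base$icer)
}

#' @export
plot.owsa <- function(x, n_top = nrow(x), ...) {
  d <- x[seq_len(min(n_top, nrow(x))), ]
  d <- d[order(d$range), ]
  base <- attr(x, "base_icer")
  lo <- pmin(d$icer_low, d$icer_high); hi <- pmax(d$icer_low, d$icer_high)
  graphics::par(mar = c(5, 12, 3, 2))
  graphics::plot(NA, xlim = range(c(lo, hi, base)),
                 ylim = c(0.5, nrow(d) + 0.5), yaxt = "n",
                 xlab = "ICER ($/QALY)", ylab = "",
                 main = "One-way sensitivity analysis")
  graphics::segments(lo, seq_len(nrow(d)), hi, seq_len(nrow(d)),
                     lwd = 10, col = "#7fb3d5")
  graphics::abline(v = base, lty = 2)
  graphics::axis(2, at = seq_len(nrow(d)), labels = d$parameter, las = 1,
                 cex.axis = 0.8)
  invisible(x)
}

#' Default probabilistic dispersion specification
#'
#' Costs get gamma distributions and utilities/probabilities beta
#' distributions, moment-matched to the baseline mean and a standard
#' deviation tied to the one-way bounds, \code{sd = (high - low)/(2 * 1.96)},
#' so the deterministic and probabilistic analyses describe one coherent
#' uncertainty level. The discount rate is not sampled.
#'
#' @param econ Economic parameters.
#' @param settings Model settings.
#' @return Data frame with columns \code{parameter}, \code{dist},
#'   \code{mean}, \code{sd}.
#' @export
default_psa_spec <- function(econ = default_econ_params(),
                             settings = model_settings()) {
  rg <- default_owsa_ranges(econ, settings)
  rg <- rg[rg$parameter != "discount_rate", ]
  data.frame(
    parameter = rg$parameter,
    dist = ifelse(rg$kind == "cost", "gamma", "beta"),
    mean = vapply(rg$parameter, function(p)
      .get_econ_param(econ, settings, p), numeric(1)),
    sd = (rg$high - rg$low) / (2 * 1.96),
    row.names = NULL)
}

#' Draw one probabilistic parameter vector
#'
#' Gamma draws use shape \eqn{m^2/s^2} and scale \eqn{s^2/m}; beta draws use
#' standard moment matching with the feasibility requirement
#' \eqn{s^2 < m(1-m)}. A zero standard deviation collapses the draw to the
#' mean. Uses (and advances) the current RNG state.
#'
#' @param spec Data frame as from \code{\link{default_psa_spec}}.
#' @return Named numeric vector of drawn parameter values.
#' @export
draw_psa <- function(spec) {
  vals <- numeric(nrow(spec))
  for (i in seq_len(nrow(spec))) {
    m <- spec$mean[i]; s <- spec$sd[i]
    if (s <= 0 || m == 0) { vals[i] <- m; next }
    if (spec$dist[i] == "gamma") {
      vals[i] <- stats::rgamma(1, shape = m^2 / s^2, scale = s^2 / m)
    } else {
      if (s^2 >= m * (1 - m))
        stop("infeasible beta moments for parameter ", spec$parameter[i])
      nu <- m * (1 - m) / s^2 - 1
      vals[i] <- stats::rbeta(1, shape1 = m * nu, shape2 = (1 - m) * nu)
    }
  }
  stats::setNames(vals, spec$parameter)
}

#' Probabilistic sensitivity analysis
#'
#' Monte Carlo re-evaluation of the cost-effectiveness model under sampled
#' cost/utility/probability parameters (survival-curve parameters are not
#' sampled; curve uncertainty is addressed by the distribution
#' cross-validation grid instead). State traces are computed once since the
#' curves and discounting do not vary across iterations.
#'
#' @param cs_control,cs_aci Curve sets.
#' @param econ Economic parameters.
#' @param settings Model settings.
#' @param spec Dispersion specification (\code{\link{default_psa_spec}}).
#' @param n_iter Number of Monte Carlo iterations (default 1000).
#' @param seed Integer seed.
#' @return An object of class \code{"psa"}: data frame with one row per
#'   iteration (sampled parameters, per-arm cost and QALY, increments,
#'   ICER).
#' @export
run_psa <- function(cs_control = calibrated_curve_set(arm = "control"),
                    cs_aci = calibrated_curve_set(arm = "aci"),
                    econ = default_econ_params(),
                    settings = model_settings(),
                    spec = default_psa_spec(econ, settings),
                    n_iter = 1000, seed = 1L) {
  set.seed(seed)
  tr_c <- occupancy_trace(cs_control, settings)
  tr_a <- occupancy_trace(cs_aci, settings)
  econ$ae$cost_base <- econ$ae$cost
  rows <- vector("list", n_iter)
  for (it in seq_len(n_iter)) {
    draw <- draw_psa(spec)
    e <- econ; s <- settings
    for (p in names(draw)) {
      upd <- set_econ_param(e, s, p, draw[[p]])
      e <- upd$econ; s <- upd$settings
      e$ae$cost_base <- econ$ae$cost_base
    }
    res_c <- accumulate(tr_c, "control", e, s)
    res_a <- accumulate(tr_a, "aci", e, s)
    rows[[it]] <- c(iter = it, draw,
                    cost_aci = res_a$total_cost, qaly_aci = res_a$total_qaly,
                    cost_control = res_c$total_cost,
                    qaly_control = res_c$total_qaly)
  }
  out <- as.data.frame(do.call(rbind, rows))
  out$dcost <- out$cost_aci - out$cost_control
  out$dqaly <- out$qaly_aci - out$qaly_control
  out$icer <- ifelse(abs(out$dqaly) > 1e-12, out$dcost / out$dqaly, NA)
  structure(out, class = c("psa", "data.frame"))
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the fraction of probabilistic samples
#' with \eqn{\Delta C \le \lambda \, \Delta E} — computed by counting, not
#' smoothing.
#'
#' @param samples A \code{"psa"} object (or data frame with \code{dcost},
#'   \code{dqaly}).
#' @param wtp_grid Willingness-to-pay values, $/QALY.
#' @return Data frame with columns \code{wtp} and \code{probability}.
#' @export
ceac <- function(samples, wtp_grid = seq(0, 80000, by = 2000)) {
  if (nrow(samples) == 0L) stop("empty samples")
  data.frame(wtp = wtp_grid,
             probability = vapply(wtp_grid, function(l)
               mean(samples$dcost <= l * samples$dqaly), numeric(1)))
}

#' @export
plot.psa <- function(x, wtp = 36721.86, ...) {
  graphics::plot(x$dqaly, x$dcost, pch = 16, cex = 0.5,
                 col = grDevices::adjustcolor("#2c7fb8", 0.5),
                 xlab = "Incremental QALY", ylab = "Incremental cost ($)",
                 main = "Probabilistic sensitivity analysis")
  graphics::abline(a = 0, b = wtp, lty = 2)
  graphics::abline(h = 0, v = 0, col = "grey70")
  invisible(x)
}

#' Plot a cost-effectiveness acceptability curve
#' @param ceac_df Data frame from \code{\link{ceac}}.
#' @param ... Passed to \code{plot}.
#' @return The input, invisibly.
#' @export
plot_ceac <- function(ceac_df, ...) {
  graphics::plot(ceac_df$wtp, ceac_df$probability, type = "l", lwd = 2,
                 ylim = c(0, 1), xlab = "Willingness to pay ($/QALY)",
                 ylab = "Probability cost-effective",
                 main = "Cost-effectiveness acceptability curve", ...)
  invisible(ceac_df)
}
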