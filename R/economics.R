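#' Patient characteristics used for dosing
#'
#' Body surface area is a direct config input (default 1.79 m^2) rather than
#' recomputed from height and weight.
#'
#' @param height_cm,weight_kg,bsa_m2 Positive anthropometrics.
#' @return A list of class \code{"patient_spec"}.
#' @export
patient_spec <- function(height_cm = 165, weight_kg = 65, bsa_m2 = 1.79) {
  stopifnot(height_cm > 0, weight_kg > 0, bsa_m2 > 0)
  structure(list(height_cm = height_cm, weight_kg = weight_kg,
                 bsa_m2 = bsa_m2), class = "patient_spec")
}

#' Default treatment schedule
#'
#' XELOX plus bevacizumab on 21-day cycles: bevacizumab 7.5 mg/kg day 1,
#' oxaliplatin 130 mg/m^2 day 1 (induction only), capecitabine 1,000 mg/m^2
#' twice daily days 1-14; six induction cycles, then maintenance
#' (bevacizumab + capecitabine) while progression-free. The ACI arm
#' additionally receives the cell infusion on day 17 of each induction cycle.
#'
#' @return A list of class \code{"schedule_spec"}.
#' @export
default_schedule <- function() {
  structure(list(
    cycle_days = 21,
    induction_cycles = 6,
    bevacizumab_mg_per_kg = 7.5,
    oxaliplatin_mg_per_m2 = 130,
    capecitabine_mg_per_m2 = 1000,
    capecitabine_doses_per_day = 2,
    capecitabine_days = 14
  ), class = "schedule_spec")
}

#' Default economic parameter set (synthetic)
#'
#' A documented set of plausible unit costs (2024 USD, Chinese healthcare
#' system perspective) and utilities for the worked examples and default
#' analyses. These are synthetic placeholder values chosen for plausibility;
#' they are not trial-derived micro-costing data. Trial-anchored entries are
#' the ACI base-case price ($6,819.45 per cycle) and the subsequent-therapy
#' uptake probabilities (56.0% ACI, 64.7% control). The adverse-event table
#' lists grade >= 3 events with incidence above 2%.
#'
#' @return A nested list of class \code{"econ_params"}.
#' @export
default_econ_params <- function() {
  structure(list(
    patient = patient_spec(),
    schedule = default_schedule(),
    drug_prices = list(          # $ per mg
      bevacizumab = 1.10,
      oxaliplatin = 0.60,
      capecitabine = 0.0015
    ),
    aci_price_per_cycle = 6819.45,
    utilities = list(u_pfs_aci = 0.80, u_pfs_control = 0.78, u_pd = 0.60),
    ae = data.frame(
      name = c("anemia", "neutropenia", "leukopenia",
               "thrombocytopenia", "diarrhea"),
      inc_aci = c(0.04, 0.07, 0.05, 0.05, 0.03),
      inc_control = c(0.06, 0.09, 0.06, 0.06, 0.04),
      cost = c(560, 640, 480, 910, 330),
      disutility = c(0.07, 0.09, 0.07, 0.05, 0.10),
      duration_days = c(14, 10, 10, 12, 6)
    ),
    subsequent_tx = list(prob_aci = 0.560, prob_control = 0.647,
                         cost = 12000),
    bsc_cost_per_cycle = 380,
    followup_cost_per_cycle = 120,
    terminal_cost = 1800
  ), class = "econ_params")
}

.ae_incidence <- function(econ, arm) {
  if (arm == "aci") econ$ae$inc_aci else econ$ae$inc_control
}

.u_pfs <- function(econ, arm) {
  if (arm == "aci") econ$utilities$u_pfs_aci else econ$utilities$u_pfs_control
}

#' Per-administration drug cost
#'
#' Weight-based (mg/kg) or BSA-based (mg/m^2) dose multiplied by the unit
#' price per mg. For capecitabine the administration is the full
#' days-1-to-14 oral course of one cycle.
#'
#' @param drug \code{"bevacizumab"}, \code{"oxaliplatin"},
#'   \code{"capecitabine"}.
#' @param patient A \code{\link{patient_spec}}.
#' @param econ An \code{\link{default_econ_params}}-style list (prices and
#'   schedule are read from it).
#' @return Cost in dollars.
#' @export
dose_cost <- function(drug, patient = patient_spec(),
                      econ = default_econ_params()) {
  sch <- econ$schedule
  mg <- switch(drug,
    bevacizumab = sch$bevacizumab_mg_per_kg * patient$weight_kg,
    oxaliplatin = sch$oxaliplatin_mg_per_m2 * patient$bsa_m2,
    capecitabine = sch$capecitabine_mg_per_m2 * patient$bsa_m2 *
      sch$capecitabine_doses_per_day * sch$capecitabine_days,
    stop("unknown drug: ", drug))
  mg * econ$drug_prices[[drug]]
}

#' Cost and QALY accrual of one cycle in one state
#'
#' Per patient occupying \code{state} during cycle \code{cycle_index}
#' (1-based). Progression-free cycles up to the induction count accrue the
#' induction drug costs (plus the ACI price in the ACI arm); later
#' progression-free cycles accrue maintenance drugs (no oxaliplatin, no ACI).
#' The first cycle additionally accrues the expected adverse-event management
#' cost and subtracts the duration-adjusted expected adverse-event
#' disutility. Progressed-disease cycles accrue best-supportive-care plus
#' follow-up costs. Utility is the state utility scaled to the cycle length
#' in years. The one-off subsequent-therapy and terminal-care costs are
#' charged by \code{\link{accumulate}} on PD entry and death, not here.
#'
#' @param arm \code{"control"} or \code{"aci"}.
#' @param cycle_index 1-based cycle number.
#' @param state \code{"PFS"} or \code{"PD"}.
#' @param econ Economic parameters.
#' @return Named numeric vector \code{c(cost, qaly)}.
#' @export
cycle_values <- function(arm, cycle_index, state, econ = default_econ_params()) {
  if (cycle_index < 1) stop("cycle_index must be >= 1")
  state <- match.arg(state, c("PFS", "PD"))
  sch <- econ$schedule
  cyc_years <- sch$cycle_days / 365.25
  if (state == "PFS") {
    drugs <- dose_cost("bevacizumab", econ$patient, econ) +
      dose_cost("capecitabine", econ$patient, econ)
    if (cycle_index <= sch$induction_cycles) {
      drugs <- drugs + dose_cost("oxaliplatin", econ$patient, econ)
      if (arm == "aci") drugs <- drugs + econ$aci_price_per_cycle
    }
    cost <- drugs + econ$followup_cost_per_cycle
    qaly <- .u_pfs(econ, arm) * cyc_years
    if (cycle_index == 1) {
      inc <- .ae_incidence(econ, arm)
      cost <- cost + sum(inc * econ$ae$cost)
      qaly <- qaly - sum(inc * econ$ae$disutility *
                           pmin(econ$ae$duration_days, sch$cycle_days) / 365.25)
    }
  } else {
    cost <- econ$bsc_cost_per_cycle + econ$followup_cost_per_cycle
    qaly <- econ$utilities$u_pd * cyc_years
  }
  c(cost = cost, qaly = qaly)
}

#' Accumulate discounted cost and QALY over a state trace
#'
#' Sums per-cycle discounted occupancy-weighted costs and utilities over the
#' trace, adds the expected one-off subsequent-therapy cost on each cycle's
#' flow into the progressed state, and charges the terminal-care cost once
#' per incremental death. With \code{settings$half_cycle} the state-occupancy
#' terms use mid-cycle (averaged) occupancy.
#'
#' @param trace A \code{"state_trace"} (with \code{pd_entry} column).
#' @param arm \code{"control"} or \code{"aci"}.
#' @param econ Economic parameters.
#' @param settings The \code{\link{model_settings}} the trace was built with.
#' @return List with \code{total_cost} and \code{total_qaly} (discounted).
#' @export
accumulate <- function(trace, arm, econ = default_econ_params(),
                       settings = model_settings()) {
  n <- nrow(trace) - 1
  pfs <- trace$pfs; pd <- trace$pd; death <- trace$death
  w_pfs <- pfs[1:n]; w_pd <- pd[1:n]
  if (isTRUE(settings$half_cycle)) {
    w_pfs <- (pfs[1:n] + pfs[2:(n + 1)]) / 2
    w_pd <- (pd[1:n] + pd[2:(n + 1)]) / 2
  }
  disc <- trace$discount[1:n]
  vals_pfs <- vapply(seq_len(n), function(k)
    cycle_values(arm, k, "PFS", econ), numeric(2))
  val_pd <- cycle_values(arm, 1, "PD", econ)
  subseq_prob <- if (arm == "aci") econ$subsequent_tx$prob_aci
                 else econ$subsequent_tx$prob_control
  cost_k <- w_pfs * vals_pfs["cost", ] + w_pd * val_pd[["cost"]] +
    trace$pd_entry[1:n] * subseq_prob * econ$subsequent_tx$cost +
    (death[2:(n + 1)] - death[1:n]) * econ$terminal_cost
  qaly_k <- w_pfs * vals_pfs["qaly", ] + w_pd * val_pd[["qaly"]]
  list(total_cost = sum(disc * cost_k), total_qaly = sum(disc * qaly_k))
}

#' Incremental cost-effectiveness ratio
#'
#' @param result_aci,result_control Lists with \code{total_cost} and
#'   \code{total_qaly} computed under identical settings.
#' @return List with \code{incremental_cost}, \code{incremental_qaly},
#'   \code{icer} (numeric, or \code{NA} when labelled) and \code{label}
#'   (\code{"icer"}, \code{"dominant"}, \code{"dominated"} or
#'   \code{"undefined"}).
#' @export
icer <- function(result_aci, result_control) {
  dc <- result_aci$total_cost - result_control$total_cost
  de <- result_aci$total_qaly - result_control$total_qaly
  if (abs(de) < 1e-9) {
    label <- "undefined"; val <- NA_real_
  } else if (dc < 0 && de > 0) {
    label <- "dominant"; val <- dc / de
  } else if (dc > 0 && de < 0) {
    label <- "dominated"; val <- dc / de
  } else {
    label <- "icer"; val <- dc / de
  }
  list(incremental_cost = dc, incremental_qaly = de, icer = val,
       label = label)
}
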