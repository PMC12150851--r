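toy_trace <- function(pfs, pd, death, discount, pd_entry = 0 * pfs) {
  structure(data.frame(cycle = seq_along(pfs) - 1, time_months = 0,
                       pfs = pfs, pd = pd, death = death,
                       discount = discount, pd_entry = pd_entry),
            class = c("state_trace", "data.frame"))
}

no_ae_econ <- function() {
  e <- default_econ_params()
  e$ae$inc_aci <- 0; e$ae$inc_control <- 0
  e
}

test_that("dose costs follow weight- and BSA-based arithmetic", {
  e <- default_econ_params()
  expect_equal(dose_cost("bevacizumab", patient_spec(), e),
               7.5 * 65 * e$drug_prices$bevacizumab)
  expect_equal(dose_cost("oxaliplatin", patient_spec(), e),
               130 * 1.79 * e$drug_prices$oxaliplatin)
  expect_equal(dose_cost("capecitabine", patient_spec(), e),
               1000 * 1.79 * 2 * 14 * e$drug_prices$capecitabine)
  e$drug_prices$bevacizumab <- 0
  expect_equal(dose_cost("bevacizumab", patient_spec(), e), 0)
  expect_error(dose_cost("aspirin", patient_spec(), e), "unknown drug")
})

test_that("cycle values encode the schedule and first-cycle AE burden", {
  e <- default_econ_params()
  v_aci3 <- cycle_values("aci", 3, "PFS", e)
  v_ctrl3 <- cycle_values("control", 3, "PFS", e)
  expect_equal(v_aci3[["cost"]] - v_ctrl3[["cost"]], e$aci_price_per_cycle)
  # maintenance cycles drop oxaliplatin and ACI
  v_aci10 <- cycle_values("aci", 10, "PFS", e)
  expect_equal(v_aci10[["cost"]],
               dose_cost("bevacizumab", e$patient, e) +
                 dose_cost("capecitabine", e$patient, e) +
                 e$followup_cost_per_cycle)
  expect_identical(cycle_values("control", 10, "PFS", e),
                   cycle_values("control", 12, "PFS", e))
  # first cycle adds AE cost and subtracts duration-adjusted disutility
  v1 <- cycle_values("control", 1, "PFS", e)
  v2 <- cycle_values("control", 2, "PFS", e)
  inc <- e$ae$inc_control
  expect_equal(v1[["cost"]] - v2[["cost"]] + e$aci_price_per_cycle * 0,
               sum(inc * e$ae$cost))
  expect_equal(v2[["qaly"]] - v1[["qaly"]],
               sum(inc * e$ae$disutility *
                     pmin(e$ae$duration_days, 21) / 365.25))
  # with zero incidence the first two PFS cycles are identical
  e0 <- no_ae_econ()
  expect_identical(cycle_values("control", 1, "PFS", e0),
                   cycle_values("control", 2, "PFS", e0))
  expect_error(cycle_values("control", 0, "PFS", e), "cycle_index")
})

test_that("a one-cycle cohort accrues exactly u * cycle-length QALYs", {
  e <- no_ae_econ()
  tr <- toy_trace(pfs = c(1, 0), pd = c(0, 0), death = c(0, 1),
                  discount = c(1, 1))
  res <- accumulate(tr, "aci", e, model_settings(discount_annual = 0))
  expect_equal(res$total_qaly, 0.80 * 21 / 365.25)
  # instant death accrues only the terminal cost
  tr0 <- toy_trace(pfs = c(0, 0), pd = c(0, 0), death = c(1, 1),
                   discount = c(1, 1))
  tr0$death <- c(0, 1); tr0$pfs <- c(0, 0)  # all die during cycle 1
  res0 <- accumulate(tr0, "control", e, model_settings(discount_annual = 0))
  expect_equal(res0$total_cost, e$terminal_cost)
  expect_equal(res0$total_qaly, 0)
})

test_that("discounting monotonically lowers both totals", {
  cs_c <- calibrated_curve_set(arm = "control")
  totals <- lapply(c(0, 0.05, 0.08), function(r) {
    s <- model_settings(discount_annual = r)
    accumulate(occupancy_trace(cs_c, s), "control",
               default_econ_params(), s)
  })
  expect_gt(totals[[1]]$total_qaly, totals[[2]]$total_qaly)
  expect_gt(totals[[2]]$total_qaly, totals[[3]]$total_qaly)
  expect_gt(totals[[1]]$total_cost, totals[[2]]$total_cost)
})

test_that("arm cost is affine in the ACI price with the discounted-dose slope", {
  e <- default_econ_params()
  s <- model_settings()
  tr <- occupancy_trace(calibrated_curve_set(arm = "aci"), s)
  at_price <- function(p) {
    e$aci_price_per_cycle <- p
    accumulate(tr, "aci", e, s)
  }
  c0 <- at_price(0); c1 <- at_price(1000); c2 <- at_price(2000)
  slope <- (c1$total_cost - c0$total_cost) / 1000
  expect_equal(c2$total_cost, c0$total_cost + slope * 2000,
               tolerance = 1e-12)
  # slope equals discounted PFS occupancy over the six induction cycles
  expect_equal(slope, sum(tr$discount[1:6] * tr$pfs[1:6]), tolerance = 1e-12)
  expect_lte(slope, 6 * tr$discount[2])
  # QALYs are price-invariant
  expect_identical(c0$total_qaly, c2$total_qaly)
})

test_that("ICER handles quadrants and the printed worked example", {
  # incremental arithmetic recomputed from the published per-arm totals
  r_aci <- list(total_cost = 108136.35, total_qaly = 3.91)
  r_ctl <- list(total_cost = 46106.57, total_qaly = 2.18)
  inc <- icer(r_aci, r_ctl)
  expect_equal(inc$incremental_cost, 62029.78)
  expect_equal(inc$incremental_qaly, 1.73)
  expect_equal(inc$icer, 62029.78 / 1.73, tolerance = 1e-12)
  expect_equal(inc$label, "icer")
  expect_equal(icer(list(total_cost = 5, total_qaly = 2),
                    list(total_cost = 5, total_qaly = 1))$icer, 0)
  expect_equal(icer(list(total_cost = 1, total_qaly = 2),
                    list(total_cost = 5, total_qaly = 1))$label, "dominant")
  expect_equal(icer(list(total_cost = 9, total_qaly = 1),
                    list(total_cost = 5, total_qaly = 2))$label, "dominated")
  expect_equal(icer(list(total_cost = 9, total_qaly = 1),
                    list(total_cost = 5, total_qaly = 1))$label, "undefined")
})

test_that("raising the PD utility raises both arms' QALYs", {
  s <- model_settings()
  e_lo <- default_econ_params()
  e_hi <- default_econ_params(); e_hi$utilities$u_pd <- 0.75
  for (arm in c("control", "aci")) {
    tr <- occupancy_trace(calibrated_curve_set(arm = arm), s)
    expect_gt(accumulate(tr, arm, e_hi, s)$total_qaly,
              accumulate(tr, arm, e_lo, s)$total_qaly)
  }
})

test_that("the cea object carries consistent totals and increments", {
  fit <- cea()
  expect_s3_class(fit, "cea")
  expect_equal(fit$incremental_cost,
               fit$arms$aci$total_cost - fit$arms$control$total_cost)
  expect_equal(fit$incremental_qaly,
               fit$arms$aci$total_qaly - fit$arms$control$total_qaly)
  expect_equal(fit$icer, fit$incremental_cost / fit$incremental_qaly)
  # both engines agree
  fit_m <- cea(engine = "markov")
  expect_equal(fit_m$icer, fit$icer, tolerance = 1e-6)
  expect_output(print(fit), "ICER")
  expect_output(print(summary(fit)), "WTP")
})

test_that("economic config survives a YAML round trip", {
  e <- default_econ_params()
  f <- tempfile(fileext = ".yaml")
  write_econ_config(e, f)
  e2 <- read_econ_config(f)
  expect_equal(e2$utilities, e$utilities)
  expect_equal(e2$ae, e$ae)
  expect_equal(e2$aci_price_per_cycle, e$aci_price_per_cycle)
  # the shipped default config matches the in-code defaults
  shipped <- read_econ_config(system.file("extdata", "default_econ.yaml",
                                          package = "acicea"))
  expect_equal(shipped$drug_prices, e$drug_prices)
  expect_equal(shipped$utilities, e$utilities)
})
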