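test_that("ICER falls as the horizon extends from 10 to 20 years", {
  hs <- horizon_scenarios(years_list = c(10, 15, 20))
  expect_equal(hs$horizon_years, c(10, 15, 20))
  expect_true(all(diff(hs$icer) < 0))
  # QALY totals strictly increase with horizon in both arms
  expect_true(all(diff(hs$qaly_aci) > 0))
  expect_true(all(diff(hs$qaly_control) > 0))
})

test_that("degenerate horizons are rejected or labelled", {
  expect_error(horizon_scenarios(years_list = numeric(0)), "empty")
  expect_error(horizon_scenarios(years_list = 0.01))
  # identical curves and symmetric utilities: incremental QALY is exactly
  # zero and the ICER is undefined-labelled
  cs <- calibrated_curve_set(arm = "control")
  e <- default_econ_params()
  e$utilities$u_pfs_aci <- e$utilities$u_pfs_control
  e$ae$inc_aci <- e$ae$inc_control
  hs <- horizon_scenarios(cs, cs, econ = e, years_list = 20)
  expect_equal(hs$label, "undefined")
  expect_true(is.na(hs$icer))
})

test_that("the cross-validation grid is the exact Cartesian product", {
  # 72 x 34 sets mirroring the published grid shape
  mk_set <- function(arm, i, base_scale_pfs, base_scale_os) {
    curve_set(arm,
              parsurv("weibull", c(shape = 1.2, scale = base_scale_pfs + i / 10)),
              parsurv("weibull", c(shape = 1.2, scale = base_scale_os + i / 10)))
  }
  ctrl <- lapply(1:72, mk_set, arm = "control", base_scale_pfs = 12,
                 base_scale_os = 30)
  trt <- lapply(1:34, mk_set, arm = "aci", base_scale_pfs = 18,
                base_scale_os = 45)
  s <- model_settings(horizon_years = 2)   # short horizon keeps this cheap
  grid <- cycle_times(s)
  expect_true(all(vapply(c(ctrl, trt), screen_pair, logical(1), grid = grid)))
  rep72 <- crossval_grid(ctrl, trt, settings = s)
  expect_equal(rep72$n_pairs, 2448)
  expect_equal(rep72$n_control_combos, 72)
  expect_equal(rep72$n_treat_combos, 34)
  expect_length(rep72$icer, 2448)
  expect_gte(rep72$fraction_cost_effective, 0)
  expect_lte(rep72$fraction_cost_effective, 1)
  expect_lte(rep72$icer_min, rep72$icer_max)
})

test_that("degenerate grids behave: 1x1 fraction, dominance, empty sets", {
  s <- model_settings(horizon_years = 2)
  cs_c <- calibrated_curve_set(arm = "control")
  cs_a <- calibrated_curve_set(arm = "aci")
  r11 <- crossval_grid(list(cs_c), list(cs_a), settings = s)
  expect_equal(r11$n_pairs, 1)
  expect_true(r11$fraction_cost_effective %in% c(0, 1))
  expect_error(crossval_grid(list(), list(cs_a), settings = s), "empty")
  # construction where every treatment set dominates: the treatment cohort
  # never progresses (no BSC cost, higher utility), the control cohort
  # progresses immediately; strip out every other cost
  e <- default_econ_params()
  e$drug_prices <- list(bevacizumab = 0, oxaliplatin = 0, capecitabine = 0)
  e$aci_price_per_cycle <- 0
  e$ae$cost <- 0 * e$ae$cost
  e$subsequent_tx$cost <- 0
  e$followup_cost_per_cycle <- 0
  e$terminal_cost <- 0
  ctrl <- list(curve_set("control", exp_law(1.0), exp_law(0.05)))
  trt <- list(curve_set("aci", exp_law(0.05), exp_law(0.05)))
  rdom <- crossval_grid(ctrl, trt, econ = e, settings = s)
  expect_lt(rdom$dcost, 0)
  expect_gt(rdom$dqaly, 0)
  expect_equal(rdom$fraction_cost_effective, 1)
})

test_that("fit-set screening keeps only OS-above-PFS pairs", {
  s <- model_settings(horizon_years = 2)
  pfs_fits <- list(exp_law(0.10), exp_law(0.06))
  os_fits <- list(exp_law(0.05), exp_law(0.08))
  sets <- screened_curve_sets("control", pfs_fits, os_fits, s)
  # rate(os) <= rate(pfs) required: (.1,.05) (.1,.08) (.06,.05) pass
  expect_length(sets, 3)
  bad <- parsurv("exponential", c(rate = 0.5)); bad$converged <- FALSE
  expect_length(screened_curve_sets("control", c(pfs_fits, list(bad)),
                                    os_fits, s), 3)
})

test_that("the report always carries six sections with gaps flagged", {
  base <- cea(settings = model_settings(horizon_years = 2))
  rep1 <- assemble_report(base)
  expect_equal(sum(grepl("^## ", rep1)), 6)
  expect_equal(sum(grepl("Stage not run", rep1)), 5)
  hs <- horizon_scenarios(years_list = c(10, 20))
  tab <- wtp_thresholds()
  price <- data.frame(multiplier = tab$multiplier,
                      threshold = tab$threshold,
                      price_star = c(1, 2, 3), achievable = TRUE)
  rep2 <- assemble_report(base, horizons = hs, price_table = price)
  expect_equal(sum(grepl("Stage not run", rep2)), 3)
  # deterministic: identical inputs give identical documents
  expect_identical(rep2, assemble_report(base, horizons = hs,
                                         price_table = price))
  f <- tempfile(fileext = ".md")
  assemble_report(base, file = f)
  expect_identical(readLines(f), rep1)
})
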