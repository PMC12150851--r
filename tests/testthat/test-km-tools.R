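test_that("product-limit estimate matches hand computation", {
  km <- kaplan_meier(ipd_five_events())
  expect_equal(km$survival, c(0.8, 0.6, 0.4, 0.2, 0.0))
  expect_equal(km$time, 1:5)
  # all censored: survival stays at 1
  km2 <- kaplan_meier(ipd_df(c(2, 4, 6), c(0, 0, 0)))
  expect_true(all(km2$survival == 1))
  # ties: events precede censors at equal times
  km3 <- kaplan_meier(ipd_df(c(2, 2, 3), c(1, 0, 1)))
  expect_equal(km_survival_at(km3, 2), 2 / 3)
  expect_equal(km_survival_at(km3, 3), 0)
  expect_error(kaplan_meier(ipd_df(-1, 1)), "negative")
})

test_that("median uses the first-time-at-or-below-half rule", {
  km <- kaplan_meier(ipd_five_events())
  expect_equal(km_median(km), 3)          # S(3) = 0.4 <= 0.5
  # exact touch of 0.5 counts
  km2 <- kaplan_meier(ipd_df(c(10, 10, 20, 20), c(1, 1, 1, 1)))
  expect_equal(km_median(km2), 10)
  # never reaches half -> not reached
  km3 <- kaplan_meier(ipd_df(c(1, 2, 3, 4), c(1, 0, 0, 0)))
  expect_true(is.na(km_median(km3)))
})

test_that("restricted mean is the area under the step function", {
  km <- kaplan_meier(ipd_five_events())
  # hand area: 1*1 + .8 + .6 + .4 + .2 over unit widths
  expect_equal(km_rmst(km, 5), 1 + 0.8 + 0.6 + 0.4 + 0.2)
  expect_equal(km_rmst(km, 2.5), 1 + 0.8 + 0.5 * 0.6)
})

test_that("single-interval reconstruction recovers the forced split", {
  cur <- data.frame(time_months = c(0, 1), survival = c(1, 0.5))
  rk <- data.frame(time_months = c(0, 2), n_at_risk = c(10, 4))
  rec <- guyot_reconstruct(cur, rk)
  expect_equal(sum(rec$ipd$event), 5)
  expect_equal(rec$counts$events[1], 5)
  expect_equal(rec$counts$censored[1], 1)
  expect_equal(sum(rec$ipd$time_months >= 2), 4)
})

test_that("no-censoring digitization reconstructs exact event times", {
  times <- c(1, 2, 2, 3.5, 4, 5, 6, 6, 7, 8, 9, 9.5, 10, 11, 12, 13, 14,
             15, 16, 17)
  ipd <- ipd_df(times, rep(1, 20))
  dig <- emit_digitized_km(ipd, digitization_grid(ipd, 25),
                           c(0, 6, 12, 17))
  rec <- guyot_reconstruct(dig$curve, dig$risk)
  expect_equal(sum(rec$ipd$event), 20)
  expect_equal(sort(rec$ipd$time_months[rec$ipd$event == 1]), sort(times))
  expect_equal(rec$max_dev, 0)
})

test_that("reconstruction conserves subjects and reproduces at-risk counts", {
  spec <- default_trial_spec()
  for (sd in c(1, 42, 99)) {
    ipd <- simulate_arm_ipd(spec$control_pfs, 102, spec$censoring, seed = sd)
    rtimes <- seq(0, max(ipd$time_months), by = 3)
    dig <- emit_digitized_km(ipd, digitization_grid(ipd, 25, rtimes), rtimes)
    rec <- guyot_reconstruct(dig$curve, dig$risk)
    expect_equal(nrow(rec$ipd), 102)
    expect_equal(sum(rec$counts$events) + sum(rec$counts$censored), 102)
    at_risk <- vapply(rtimes, function(r) sum(rec$ipd$time_months >= r),
                      numeric(1))
    expect_equal(at_risk, as.numeric(dig$risk$n_at_risk))
  }
})

test_that("round trip recovers median and 30-month restricted mean to 5%", {
  spec <- default_trial_spec()
  for (sd in c(1, 42, 2024)) {
    ipd <- simulate_arm_ipd(spec$control_pfs, 102, spec$censoring, seed = sd)
    km <- kaplan_meier(ipd)
    rtimes <- seq(0, max(ipd$time_months), by = 3)
    dig <- emit_digitized_km(ipd, digitization_grid(ipd, 25, rtimes), rtimes)
    rec <- guyot_reconstruct(dig$curve, dig$risk)
    km2 <- kaplan_meier(rec$ipd)
    expect_lt(rec$max_dev, 0.02)
    expect_lt(abs(km_median(km2) - km_median(km)) / km_median(km), 0.05)
    expect_lt(abs(km_rmst(km2, 30) - km_rmst(km, 30)) / km_rmst(km, 30),
              0.05)
  }
})

test_that("iterative reconstruction matches the exhaustive-search optimum", {
  # small instances digitized from true IPD; when every subject has an
  # event the counts are forced and the optimum deviation is zero, with a
  # mid-interval censor the optimum is positive but still attained
  cases <- list(
    list(times = c(1, 2, 4, 5, 7, 9), ev = c(1, 1, 0, 1, 1, 1),
         rt = c(0, 3, 6)),
    list(times = c(0.5, 1.5, 2.5, 3.5, 4.5, 5.5, 6.5, 8),
         ev = c(1, 1, 1, 0, 1, 1, 1, 1), rt = c(0, 3, 6)),
    list(times = c(1, 1, 2, 3, 4, 5, 5, 6, 7, 8), ev = rep(1, 10),
         rt = c(0, 4, 8)))
  for (cs in cases) {
    ipd <- ipd_df(cs$times, cs$ev)
    dig <- emit_digitized_km(ipd, digitization_grid(ipd, 25, cs$rt), cs$rt)
    rec <- guyot_reconstruct(dig$curve, dig$risk)
    best <- guyot_oracle_best_dev(dig$curve, dig$risk)
    expect_equal(rec$max_dev, best, tolerance = 1e-12)
    if (all(cs$ev == 1)) expect_equal(best, 0, tolerance = 1e-12)
  }
})

test_that("inconsistent digitization inputs are rejected", {
  cur_up <- data.frame(time_months = c(0, 1, 2), survival = c(1, 0.5, 0.8))
  rk <- data.frame(time_months = c(0, 3), n_at_risk = c(10, 5))
  expect_error(guyot_reconstruct(cur_up, rk), "increases")
  cur <- data.frame(time_months = c(0, 1, 2), survival = c(1, 0.8, 0.79))
  rk_up <- data.frame(time_months = c(0, 3), n_at_risk = c(10, 12))
  expect_error(guyot_reconstruct(cur, rk_up), "increases")
  # small inversions are clipped when monotone_fix is on, rejected when off
  cur_noise <- data.frame(time_months = c(0, 1, 1.5, 2),
                          survival = c(1, 0.80, 0.81, 0.6))
  expect_silent(guyot_reconstruct(cur_noise, rk))
  expect_error(guyot_reconstruct(cur_noise, rk, monotone_fix = FALSE),
               "increases")
})
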