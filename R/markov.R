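DAYS_PER_MONTH <- 365.25 / 12

#' Cohort model settings
#'
#' @param horizon_years Time horizon, years (default 20).
#' @param cycle_days Cycle length, days (default 21, the regimen cycle).
#' @param discount_annual Annual discount rate for costs and outcomes
#'   (default 0.05; accepted range 0 to 0.08).
#' @param n_cycles Number of cycles; defaults to
#'   \code{ceiling(horizon_years * 365.25 / cycle_days)} but may be
#'   overridden (e.g. 374).
#' @param half_cycle Apply a half-cycle correction when accumulating
#'   (default \code{FALSE}).
#' @return An object of class \code{"model_settings"}.
#' @export
model_settings <- function(horizon_years = 20, cycle_days = 21,
                           discount_annual = 0.05, n_cycles = NULL,
                           half_cycle = FALSE) {
  stopifnot(horizon_years > 0, cycle_days > 0,
            discount_annual >= 0, discount_annual <= 0.08)
  if (horizon_years * 365.25 < cycle_days)
    stop("horizon shorter than one cycle")
  if (is.null(n_cycles)) n_cycles <- ceiling(horizon_years * 365.25 / cycle_days)
  if (n_cycles < 1) stop("horizon shorter than one cycle")
  structure(list(horizon_years = horizon_years, cycle_days = cycle_days,
                 discount_annual = discount_annual, n_cycles = n_cycles,
                 half_cycle = half_cycle),
            class = "model_settings")
}

#' Per-cycle discount factor
#'
#' \eqn{(1+r)^{-c/365.25}} for annual rate r and cycle length c days, so that
#' compounding over one year of cycles reproduces the annual factor
#' \eqn{1/(1+r)} exactly.
#'
#' @param annual_rate Annual discount rate (>= 0).
#' @param cycle_days Cycle length in days.
#' @return Discount factor in (0, 1].
#' @export
per_cycle_discount <- function(annual_rate, cycle_days = 21) {
  if (annual_rate < 0) stop("negative discount rate")
  (1 + annual_rate)^(-cycle_days / 365.25)
}

#' Cycle start times of a settings object, in months
#' @noRd
cycle_times <- function(settings) {
  (0:settings$n_cycles) * settings$cycle_days / DAYS_PER_MONTH
}

#' Partitioned state-occupancy trace
#'
#' Derives per-cycle occupancy of the three states directly from the PFS and
#' OS survival curves: \code{pfs = S_pfs(t)}, \code{pd = S_os(t) - S_pfs(t)}
#' (clamped at 0 against residual numerical crossings),
#' \code{death = 1 - S_os(t)}, at cycle start times t.
#'
#' @param cs A \code{"curve_set"}.
#' @param settings A \code{\link{model_settings}}.
#' @return An object of class \code{"state_trace"}: data frame with columns
#'   \code{cycle}, \code{time_months}, \code{pfs}, \code{pd}, \code{death},
#'   \code{discount}; attribute \code{clamped} flags cycles where the pd
#'   clamp was active.
#' @export
occupancy_trace <- function(cs, settings = model_settings()) {
  tk <- cycle_times(settings)
  s_pfs <- survival_at(cs$s_pfs, tk)
  s_os <- survival_at(cs$s_os, tk)
  if (any(s_pfs < 0 | s_pfs > 1 | s_os < 0 | s_os > 1))
    stop("survival evaluator outside [0, 1]")
  pd <- s_os - s_pfs
  clamped <- pd < 0
  pd[clamped] <- 0
  pfs <- pmin(s_pfs, s_os)
  d <- per_cycle_discount(settings$discount_annual, settings$cycle_days)
  n <- settings$n_cycles
  # flow into PD during cycle k (recorded at row k): PFS exits not absorbed
  # by the overall conditional death probability
  ratio <- function(s) ifelse(s[1:n] > 1e-12, 1 - s[2:(n + 1)] / s[1:n], 0)
  p_exit <- pmin(pmax(ratio(pfs), 0), 1)
  p_d <- pmin(pmax(ratio(s_os), 0), 1)
  pd_entry <- c(pfs[1:n] * (p_exit - pmin(p_d, p_exit)), 0)
  tr <- data.frame(cycle = 0:settings$n_cycles, time_months = tk,
                   pfs = pfs, pd = pd, death = 1 - s_os,
                   discount = d^(0:settings$n_cycles),
                   pd_entry = pd_entry)
  structure(tr, class = c("state_trace", "data.frame"),
            clamped = clamped, arm_label = cs$arm_label)
}

#' Per-cycle transition probability matrices from a curve set
#'
#' For cycle k (between times \eqn{t_k} and \eqn{t_{k+1}}): the probability
#' of leaving PFS is \eqn{1 - S_{pfs}(t_{k+1})/S_{pfs}(t_k)} and the overall
#' conditional death probability is \eqn{1 - S_{os}(t_{k+1})/S_{os}(t_k)}.
#' PFS-to-death receives the overall death probability, PFS-to-PD the
#' remainder of the PFS exits, and PD-to-death is solved each cycle so that
#' cohort deaths reproduce \eqn{1 - S_{os}}. Probabilities falling outside
#' [0, 1] are clamped and flagged.
#'
#' @param cs A \code{"curve_set"}.
#' @param settings A \code{\link{model_settings}}.
#' @return List with \code{matrices} (list of 3x3 matrices, states
#'   \code{c("pfs","pd","death")}, rows = from) and \code{clamped} (logical
#'   per cycle).
#' @export
transition_matrices <- function(cs, settings = model_settings()) {
  tk <- cycle_times(settings)
  s_pfs <- pmin(survival_at(cs$s_pfs, tk), survival_at(cs$s_os, tk))
  s_os <- survival_at(cs$s_os, tk)
  n <- settings$n_cycles
  mats <- vector("list", n)
  clamped <- logical(n)
  # cohort state tracked alongside to solve the PD exit rate
  pfs <- s_pfs[1]; pd <- max(0, s_os[1] - s_pfs[1]); death <- 1 - s_os[1]
  states <- c("pfs", "pd", "death")
  for (k in seq_len(n)) {
    p_exit <- if (s_pfs[k] > 1e-12) 1 - s_pfs[k + 1] / s_pfs[k] else 0
    p_d <- if (s_os[k] > 1e-12) 1 - s_os[k + 1] / s_os[k] else 0
    p_exit <- min(max(p_exit, 0), 1)
    p_d <- min(max(p_d, 0), 1)
    p_pfs_death <- min(p_d, p_exit)
    p_pfs_pd <- p_exit - p_pfs_death
    target_death <- 1 - s_os[k + 1]
    q_raw <- if (pd > 1e-12)
      (target_death - death - pfs * p_pfs_death) / pd else 0
    q <- min(max(q_raw, 0), 1)
    if (abs(q - q_raw) > 1e-9) clamped[k] <- TRUE
    m <- matrix(0, 3, 3, dimnames = list(states, states))
    m["pfs", ] <- c(1 - p_exit, p_pfs_pd, p_pfs_death)
    m["pd", ] <- c(0, 1 - q, q)
    m["death", ] <- c(0, 0, 1)
    mats[[k]] <- m
    new <- c(pfs, pd, death) %*% m
    pfs <- new[1]; pd <- new[2]; death <- new[3]
  }
  list(matrices = mats, clamped = clamped)
}

#' Run the cohort Markov chain
#'
#' @param matrices List of per-cycle 3x3 transition matrices (as from
#'   \code{\link{transition_matrices}}\code{$matrices}).
#' @param initial Initial occupancy, default everyone progression-free.
#' @param settings A \code{\link{model_settings}} supplying the discount
#'   column and cycle times; \code{n_cycles} must equal
#'   \code{length(matrices)}.
#' @return A \code{"state_trace"} as in \code{\link{occupancy_trace}}.
#' @export
run_markov <- function(matrices, initial = c(1, 0, 0),
                       settings = model_settings(n_cycles = length(matrices),
                                                 horizon_years = 1)) {
  n <- length(matrices)
  stopifnot(settings$n_cycles == n, length(initial) == 3,
            abs(sum(initial) - 1) < 1e-9)
  occ <- matrix(0, n + 1, 3)
  occ[1, ] <- initial
  pd_entry <- numeric(n + 1)
  for (k in seq_len(n)) {
    occ[k + 1, ] <- occ[k, ] %*% matrices[[k]]
    pd_entry[k] <- occ[k, 1] * matrices[[k]]["pfs", "pd"]
  }
  d <- per_cycle_discount(settings$discount_annual, settings$cycle_days)
  tr <- data.frame(cycle = 0:n, time_months = cycle_times(settings),
                   pfs = occ[, 1], pd = occ[, 2], death = occ[, 3],
                   discount = d^(0:n), pd_entry = pd_entry)
  structure(tr, class = c("state_trace", "data.frame"),
            clamped = rep(FALSE, n + 1))
}

#' @export
print.state_trace <- function(x, ...) {
  n <- nrow(x) - 1
  cat("State trace:", n, "cycles (",
      format(x$time_months[n + 1] / 12, digits = 4), "years )\n")
  cat("  final occupancy: PFS", format(x$pfs[n + 1], digits = 4),
      "| PD", format(x$pd[n + 1], digits = 4),
      "| death", format(x$death[n + 1], digits = 4), "\n")
  invisible(x)
}
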