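#' Calibrate a proportional-hazards Weibull from two medians and a hazard ratio
#'
#' Solves for the unique Weibull survival law \eqn{S_c(t) = \exp\{-(t/\lambda)^k\}}
#' such that the control arm has median \code{median_control} and the
#' treatment arm, defined by proportional hazards as \eqn{S_c(t)^{HR}}, has
#' median \code{median_treatment}. The closed form is
#' \deqn{k = \log(1/HR) / \log(m_t / m_c), \qquad
#'       \lambda = m_c / (\log 2)^{1/k}.}
#' An exponential law (k = 1) arises exactly when the median ratio equals
#' 1/HR.
#'
#' @param median_control Control-arm median survival, months.
#' @param median_treatment Treatment-arm median survival, months.
#' @param hazard_ratio Treatment-vs-control hazard ratio (> 0, != 1).
#' @return A list with components \code{shape} and \code{scale} (months).
#' @examples
#' calibrate_ph_weibull(9.9, 14.8, 0.60)
#' @export
calibrate_ph_weibull <- function(median_control, median_treatment, hazard_ratio) {
  stopifnot(median_control > 0, median_treatment > 0, hazard_ratio > 0)
  if (hazard_ratio == 1 && median_treatment != median_control)
    stop("infeasible: hazard ratio 1 with unequal medians")
  if (median_treatment == median_control && hazard_ratio != 1)
    stop("infeasible: equal medians with hazard ratio != 1")
  if ((hazard_ratio < 1) != (median_treatment > median_control))
    stop("infeasible: hazard ratio and median ordering disagree")
  shape <- log(1 / hazard_ratio) / log(median_treatment / median_control)
  scale <- median_control / (log(2))^(1 / shape)
  list(shape = shape, scale = scale)
}

#' Specification of one synthetic trial arm
#'
#' Bundles the survival law and event-rate summaries for one arm/endpoint.
#' The survival law is Weibull: the control arm uses (\code{weibull_shape},
#' \code{weibull_scale}) directly; a treatment arm is obtained by raising the
#' control survival to the power \code{hazard_ratio}, which for a Weibull is
#' again Weibull with the same shape and scale
#' \eqn{\lambda \cdot HR^{-1/k}}.
#'
#' @param arm_label \code{"control"} or \code{"aci"}.
#' @param endpoint \code{"PFS"} or \code{"OS"}.
#' @param weibull_shape,weibull_scale Control-law Weibull parameters (months).
#' @param hazard_ratio Treatment-vs-control hazard ratio; 1 for the control
#'   arm itself.
#' @param ae_grade3_prob Probability of a grade >= 3 adverse event.
#' @param subsequent_tx_prob Probability of receiving subsequent therapy
#'   after progression.
#' @return An object of class \code{"arm_spec"}.
#' @export
arm_spec <- function(arm_label = c("control", "aci"),
                     endpoint = c("PFS", "OS"),
                     weibull_shape, weibull_scale,
                     hazard_ratio = 1,
                     ae_grade3_prob = 0,
                     subsequent_tx_prob = 0) {
  arm_label <- match.arg(arm_label)
  endpoint <- match.arg(endpoint)
  stopifnot(weibull_shape > 0, weibull_scale > 0, hazard_ratio > 0,
            ae_grade3_prob >= 0, ae_grade3_prob <= 1,
            subsequent_tx_prob >= 0, subsequent_tx_prob <= 1)
  structure(list(arm_label = arm_label, endpoint = endpoint,
                 weibull_shape = weibull_shape, weibull_scale = weibull_scale,
                 hazard_ratio = hazard_ratio,
                 ae_grade3_prob = ae_grade3_prob,
                 subsequent_tx_prob = subsequent_tx_prob),
            class = "arm_spec")
}

#' Effective Weibull scale of an arm after the proportional-hazards tilt
#' @noRd
arm_scale <- function(spec) {
  spec$weibull_scale * spec$hazard_ratio^(-1 / spec$weibull_shape)
}

#' Administrative censoring specification
#'
#' Uniform-accrual administrative censoring: a subject accrued at a uniform
#' time within \code{accrual_window} is followed until database lock at
#' \code{max_followup}, so the censoring time is
#' \code{max_followup - runif(0, accrual_window)}, truncated below at a small
#' positive value.
#'
#' @param accrual_window Accrual duration, months (> 0).
#' @param max_followup Time from first accrual to database lock, months (> 0).
#' @return An object of class \code{"censor_spec"}.
#' @export
censor_spec <- function(accrual_window = 18, max_followup = 36) {
  stopifnot(accrual_window > 0, max_followup > 0)
  structure(list(accrual_window = accrual_window, max_followup = max_followup),
            class = "censor_spec")
}

#' Default synthetic-trial specification
#'
#' Arm specifications calibrated to the published summary statistics of the
#' NCT03950154 trial: median PFS 9.9 (control) vs 14.8 months (ACI) with
#' HR 0.60; control median OS 25.6 months with HR 0.57 (the ACI OS median was
#' not reached, so the ACI OS law is defined only through the hazard ratio on
#' the control law, whose shape is taken from the PFS calibration). Grade >= 3
#' adverse-event incidences 20.0% (ACI) vs 23.5% (control); subsequent-therapy
#' uptake 56.0% vs 64.7%.
#'
#' @return A list with elements \code{control_pfs}, \code{aci_pfs},
#'   \code{control_os}, \code{aci_os} (each an \code{\link{arm_spec}}) and
#'   \code{censoring} (a \code{\link{censor_spec}}).
#' @export
default_trial_spec <- function() {
  cal <- calibrate_ph_weibull(9.9, 14.8, 0.60)
  os_scale <- 25.6 / (log(2))^(1 / cal$shape)
  list(
    control_pfs = arm_spec("control", "PFS", cal$shape, cal$scale, 1,
                           ae_grade3_prob = 0.235, subsequent_tx_prob = 0.647),
    aci_pfs = arm_spec("aci", "PFS", cal$shape, cal$scale, 0.60,
                       ae_grade3_prob = 0.200, subsequent_tx_prob = 0.560),
    control_os = arm_spec("control", "OS", cal$shape, os_scale, 1,
                          ae_grade3_prob = 0.235, subsequent_tx_prob = 0.647),
    aci_os = arm_spec("aci", "OS", cal$shape, os_scale, 0.57,
                      ae_grade3_prob = 0.200, subsequent_tx_prob = 0.560),
    censoring = censor_spec()
  )
}

#' Simulate individual patient data for one arm
#'
#' Draws event times by inverse-CDF sampling from the arm's Weibull law and
#' applies independent administrative censoring; the observed time is the
#' minimum of the event and censoring times with the event flag set
#' accordingly.
#'
#' @param spec An \code{\link{arm_spec}}.
#' @param n Number of subjects (>= 1).
#' @param censor A \code{\link{censor_spec}}, or \code{NULL} for no censoring.
#' @param seed Integer seed; fixed seed gives identical output.
#' @return A data frame with columns \code{subject_id}, \code{arm},
#'   \code{endpoint}, \code{time_months}, \code{event}.
#' @export
simulate_arm_ipd <- function(spec, n, censor = censor_spec(), seed = 1L) {
  stopifnot(inherits(spec, "arm_spec"), n >= 1)
  set.seed(seed)
  tev <- stats::rweibull(n, shape = spec$weibull_shape, scale = arm_scale(spec))
  if (is.null(censor)) {
    tcens <- rep(Inf, n)
  } else {
    tcens <- pmax(censor$max_followup - stats::runif(n, 0, censor$accrual_window),
                  1e-6)
  }
  time <- pmin(tev, tcens)
  data.frame(subject_id = seq_len(n),
             arm = spec$arm_label,
             endpoint = spec$endpoint,
             time_months = time,
             event = as.integer(tev <= tcens))
}

#' Sample digitized survival coordinates and a number-at-risk table from IPD
#'
#' Emulates the product of figure digitization: the Kaplan-Meier
#' step-function value at each grid time, plus the exact at-risk count at
#' each risk-table time.
#'
#' @param ipd IPD data frame (columns \code{time_months}, \code{event}).
#' @param coordinate_grid Times (months) at which to sample the KM curve.
#' @param risk_times Times (months) at which to report numbers at risk.
#' @return A list with \code{curve} (data frame \code{time_months},
#'   \code{survival}) and \code{risk} (data frame \code{time_months},
#'   \code{n_at_risk}).
#' @export
emit_digitized_km <- function(ipd, coordinate_grid, risk_times) {
  if (nrow(ipd) == 0L) stop("empty IPD")
  tmax <- max(ipd$time_months)
  stopifnot(all(coordinate_grid >= 0), all(coordinate_grid <= tmax),
            all(risk_times >= 0), all(risk_times <= tmax))
  km <- kaplan_meier(ipd)
  list(curve = data.frame(time_months = coordinate_grid,
                          survival = km_survival_at(km, coordinate_grid)),
       risk = data.frame(time_months = risk_times,
                         n_at_risk = vapply(risk_times, function(t)
                           sum(ipd$time_months >= t), integer(1))))
}

#' Choose digitization coordinate times for a Kaplan-Meier curve
#'
#' Emulates how a figure is digitized in practice: clicks land on the
#' visible step corners of the plotted curve. Selects approximately
#' \code{n_points} of the curve's event-step times, evenly spaced by step
#' index, always including time zero and the last observed time.
#'
#' @param ipd IPD data frame.
#' @param n_points Target number of coordinates (default 25).
#' @param risk_times Optional number-at-risk axis times: the last step at or
#'   before each is always included, as a digitizer anchors clicks at the
#'   axis ticks.
#' @return Sorted vector of times (months).
#' @export
digitization_grid <- function(ipd, n_points = 25, risk_times = NULL) {
  stopifnot(n_points >= 2)
  km <- kaplan_meier(ipd)
  steps <- km$time[km$n_event > 0]
  anchors <- numeric(0)
  if (!is.null(risk_times))
    anchors <- vapply(risk_times, function(r) {
      below <- steps[steps <= r]
      if (length(below)) max(below) else 0
    }, numeric(1))
  picked <- if (length(steps) > n_points - 1)
    steps[unique(round(seq(1, length(steps), length.out = n_points - 1)))]
  else steps
  sort(unique(c(0, picked, anchors, max(ipd$time_months))))
}

#' Simulate a grade >= 3 adverse-event count
#'
#' @param prob Per-subject probability of a grade >= 3 adverse event.
#' @param n Number of subjects.
#' @param seed Integer seed.
#' @return Binomial count of affected subjects.
#' @export
simulate_ae_count <- function(prob, n, seed = 1L) {
  stopifnot(prob >= 0, prob <= 1, n >= 0)
  set.seed(seed)
  stats::rbinom(1L, size = n, prob = prob)
}

#' Write IPD to CSV in the canonical schema
#' @param ipd IPD data frame.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_ipd_csv <- function(ipd, path) {
  utils::write.csv(ipd, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read IPD from CSV
#' @param path CSV with columns subject_id, arm, endpoint, time_months, event.
#' @return IPD data frame.
#' @export
read_ipd_csv <- function(path) {
  ipd <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "arm", "endpoint", "time_months", "event")
  if (!all(need %in% names(ipd))) stop("missing IPD columns")
  ipd
}
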