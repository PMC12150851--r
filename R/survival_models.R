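#' @importFrom flexsurv flexsurvreg pgompertz pllogis pgengamma
NULL

.parsurv_families <- c("exponential", "weibull", "gompertz", "gamma",
                       "loglogistic", "lognormal", "generalized_gamma")

.flexsurv_dist <- c(exponential = "exp", weibull = "weibull",
                    gompertz = "gompertz", gamma = "gamma",
                    loglogistic = "llogis", lognormal = "lnorm",
                    generalized_gamma = "gengamma")

#' Supported parametric survival families
#' @return Character vector of the seven family names.
#' @export
parsurv_families <- function() .parsurv_families

#' Construct a parametric survival law from known parameters
#'
#' Builds a \code{"parsurv"} object directly from parameter values, without
#' fitting, for use as an input curve to the cohort model (e.g. a calibrated
#' generator law). Parameters use the \pkg{flexsurv} natural-scale
#' parameterizations: exponential \code{rate}; weibull \code{shape},
#' \code{scale}; gompertz \code{shape}, \code{rate}; gamma \code{shape},
#' \code{rate}; loglogistic \code{shape}, \code{scale}; lognormal
#' \code{meanlog}, \code{sdlog}; generalized_gamma \code{mu}, \code{sigma},
#' \code{Q} (the Q = 0 lognormal boundary is handled by the distribution
#' function itself).
#'
#' @param family One of \code{parsurv_families()}.
#' @param params Named numeric vector of natural-scale parameters.
#' @param hr Optional proportional-hazards multiplier: the survival function
#'   is raised to the power \code{hr}.
#' @return A \code{"parsurv"} object.
#' @export
parsurv <- function(family, params, hr = 1) {
  family <- match.arg(family, .parsurv_families)
  stopifnot(hr > 0)
  structure(list(family = family, params = params, hr = hr,
                 loglik = NA_real_, aic = NA_real_, bic = NA_real_,
                 n = NA_integer_, converged = TRUE),
            class = "parsurv")
}

.base_surv <- function(family, params, t) {
  p <- as.list(params)
  switch(family,
    exponential = stats::pexp(t, rate = p$rate, lower.tail = FALSE),
    weibull = stats::pweibull(t, shape = p$shape, scale = p$scale,
                              lower.tail = FALSE),
    gompertz = flexsurv::pgompertz(t, shape = p$shape, rate = p$rate,
                                   lower.tail = FALSE),
    gamma = stats::pgamma(t, shape = p$shape, rate = p$rate,
                          lower.tail = FALSE),
    loglogistic = flexsurv::pllogis(t, shape = p$shape, scale = p$scale,
                                    lower.tail = FALSE),
    lognormal = stats::plnorm(t, meanlog = p$meanlog, sdlog = p$sdlog,
                              lower.tail = FALSE),
    generalized_gamma = flexsurv::pgengamma(t, mu = p$mu, sigma = p$sigma,
                                            Q = p$Q, lower.tail = FALSE))
}

#' Evaluate a fitted or constructed survival law
#'
#' @param fit A \code{"parsurv"} object.
#' @param t Times, months (>= 0).
#' @return Survival probabilities in [0, 1], with S(0) = 1.
#' @export
survival_at <- function(fit, t) {
  stopifnot(inherits(fit, "parsurv"))
  if (any(t < 0)) stop("negative time")
  s <- .base_surv(fit$family, fit$params, t)
  pmin(pmax(s^fit$hr, 0), 1)
}

#' Fit one parametric survival family by maximum likelihood
#'
#' Right-censored maximum likelihood via \code{flexsurv::flexsurvreg}. AIC
#' and BIC follow the usual definitions \eqn{-2\ell + 2p} and
#' \eqn{-2\ell + p\log n} with p the number of parameters and n the number of
#' subjects.
#'
#' @param ipd IPD data frame with columns \code{time_months}, \code{event}.
#' @param family One of \code{parsurv_families()}.
#' @return A \code{"parsurv"} object carrying \code{params}, \code{loglik},
#'   \code{aic}, \code{bic}, \code{n} and a \code{converged} flag
#'   (\code{FALSE} when the optimizer failed; such fits are excluded by
#'   \code{\link{rank_fits}}).
#' @export
fit_parametric <- function(ipd, family) {
  family <- match.arg(family, .parsurv_families)
  if (sum(ipd$event) < 2) stop("need at least 2 events")
  if (any(ipd$time_months < 0)) stop("negative times")
  dat <- data.frame(time = pmax(ipd$time_months, 1e-8), event = ipd$event)
  fit <- tryCatch(
    flexsurv::flexsurvreg(survival::Surv(time, event) ~ 1, data = dat,
                          dist = .flexsurv_dist[[family]]),
    error = function(e) NULL)
  n <- nrow(dat)
  if (is.null(fit)) {
    out <- parsurv(family, stats::setNames(numeric(0), character(0)))
    out$converged <- FALSE
    out$n <- n
    return(out)
  }
  params <- fit$res[, "est"]
  names(params) <- rownames(fit$res)
  p <- fit$npars
  out <- parsurv(family, params)
  out$loglik <- fit$loglik
  out$aic <- -2 * fit$loglik + 2 * p
  out$bic <- -2 * fit$loglik + p * log(n)
  out$n <- n
  out
}

#' Fit all (or selected) parametric families to one data set
#'
#' @param ipd IPD data frame.
#' @param families Families to fit; default all seven.
#' @return A list of \code{"parsurv"} objects, one per family.
#' @export
fit_all_families <- function(ipd, families = parsurv_families()) {
  stats::setNames(lapply(families, function(f) fit_parametric(ipd, f)),
                  families)
}

#' Rank parametric fits by information criteria
#'
#' Primary key AIC ascending; fits whose AIC lies within 2 of the best AIC of
#' their run are treated as statistically tied and ordered by BIC ascending.
#' Non-converged fits are dropped.
#'
#' @param fits List of \code{"parsurv"} objects.
#' @return The converged fits in ranked order.
#' @export
rank_fits <- function(fits) {
  fits <- Filter(function(f) isTRUE(f$converged) && is.finite(f$aic), fits)
  if (length(fits) == 0L) stop("no converged fits to rank")
  aic <- vapply(fits, function(f) f$aic, numeric(1))
  bic <- vapply(fits, function(f) f$bic, numeric(1))
  ord <- order(aic)
  fits <- fits[ord]; aic <- aic[ord]; bic <- bic[ord]
  # greedy AIC-tie clusters (within 2 of the cluster minimum), BIC inside
  out <- integer(0); i <- 1
  while (i <= length(fits)) {
    j <- i
    while (j < length(fits) && aic[j + 1] - aic[i] < 2) j <- j + 1
    cluster <- i:j
    out <- c(out, cluster[order(bic[cluster])])
    i <- j + 1
  }
  fits[out]
}

#' Summarize a list of fits as a report table
#' @param fits List of \code{"parsurv"} objects.
#' @return Data frame with family, loglik, AIC, BIC, convergence flag.
#' @export
fit_report <- function(fits) {
  data.frame(
    family = vapply(fits, function(f) f$family, character(1)),
    loglik = vapply(fits, function(f) f$loglik, numeric(1)),
    aic = vapply(fits, function(f) f$aic, numeric(1)),
    bic = vapply(fits, function(f) f$bic, numeric(1)),
    converged = vapply(fits, function(f) f$converged, logical(1)),
    row.names = NULL)
}

#' Pair of PFS and OS survival laws for one arm
#'
#' @param arm_label Arm name.
#' @param s_pfs,s_os \code{"parsurv"} objects for PFS and OS.
#' @return A \code{"curve_set"} object.
#' @export
curve_set <- function(arm_label, s_pfs, s_os) {
  stopifnot(inherits(s_pfs, "parsurv"), inherits(s_os, "parsurv"))
  structure(list(arm_label = arm_label, s_pfs = s_pfs, s_os = s_os),
            class = "curve_set")
}

#' Screen a curve set for clinical plausibility
#'
#' Passes when the OS survival curve is greater than or equal to the PFS
#' curve (within 1e-9) at every grid point — progression cannot be slower
#' than death.
#'
#' @param cs A \code{"curve_set"}.
#' @param grid Evaluation times, months.
#' @return \code{TRUE} or \code{FALSE}.
#' @export
screen_pair <- function(cs, grid) {
  stopifnot(inherits(cs, "curve_set"))
  all(survival_at(cs$s_os, grid) >= survival_at(cs$s_pfs, grid) - 1e-9)
}

#' Curve sets implied by the calibrated trial generator
#'
#' Converts the Weibull generator laws of a trial specification into
#' \code{"curve_set"} inputs for the cohort model.
#'
#' @param trial A trial specification as from \code{\link{default_trial_spec}}.
#' @param arm \code{"control"} or \code{"aci"}.
#' @return A \code{"curve_set"}.
#' @export
calibrated_curve_set <- function(trial = default_trial_spec(),
                                 arm = c("control", "aci")) {
  arm <- match.arg(arm)
  pick <- function(ep) trial[[paste0(arm, "_", tolower(ep))]]
  mk <- function(spec) parsurv("weibull",
                               c(shape = spec$weibull_shape,
                                 scale = spec$weibull_scale),
                               hr = spec$hazard_ratio)
  curve_set(arm, mk(pick("PFS")), mk(pick("OS")))
}

#' @export
print.parsurv <- function(x, ...) {
  cat("Parametric survival law:", x$family)
  if (x$hr != 1) cat(" (PH multiplier", x$hr, ")")
  cat("\n  parameters:",
      paste(names(x$params), format(x$params, digits = 5),
            sep = " = ", collapse = ", "), "\n")
  if (is.finite(x$aic))
    cat("  loglik =", format(x$loglik, digits = 6),
        "AIC =", format(x$aic, digits = 6),
        "BIC =", format(x$bic, digits = 6), "n =", x$n, "\n")
  invisible(x)
}
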