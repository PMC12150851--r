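#' Kaplan-Meier product-limit estimate
#'
#' Wraps \code{survival::survfit} and returns a compact step-curve object.
#' Ties at equal times follow the standard convention that events precede
#' censorings.
#'
#' @param ipd IPD data frame with columns \code{time_months} and \code{event}.
#' @return An object of class \code{"km_curve"}: a list with \code{time}
#'   (all distinct observed times), \code{survival}, \code{n_event},
#'   \code{n_censor}, \code{n_risk} and \code{n} (initial sample size).
#' @export
kaplan_meier <- function(ipd) {
  if (nrow(ipd) < 1L) stop("need at least one record")
  if (any(ipd$time_months < 0)) stop("negative times")
  fit <- survival::survfit(survival::Surv(time_months, event) ~ 1,
                           data = ipd, conf.type = "none")
  structure(list(time = fit$time, survival = fit$surv,
                 n_event = fit$n.event, n_censor = fit$n.censor,
                 n_risk = fit$n.risk, n = nrow(ipd)),
            class = "km_curve")
}

#' Evaluate a Kaplan-Meier step function at arbitrary times
#'
#' @param km A \code{"km_curve"}.
#' @param t Times (months), any order.
#' @return Survival probabilities; 1 before the first observed time.
#' @export
km_survival_at <- function(km, t) {
  stopifnot(all(t >= 0))
  sf <- stats::stepfun(km$time, c(1, km$survival), right = FALSE)
  sf(t)
}

#' Median survival time of a Kaplan-Meier curve
#'
#' The smallest step time at which survival drops to 0.5 or below;
#' \code{NA} ("not reached") if the curve never reaches 0.5.
#'
#' @param km A \code{"km_curve"}.
#' @return Months, or \code{NA_real_} when the median is not reached.
#' @export
km_median <- function(km) {
  idx <- which(km$survival <= 0.5)
  if (length(idx) == 0L) return(NA_real_)
  km$time[idx[1L]]
}

#' Restricted mean survival time of a Kaplan-Meier curve
#'
#' Area under the step function from 0 to \code{tmax}.
#'
#' @param km A \code{"km_curve"}.
#' @param tmax Upper integration limit, months.
#' @return Months.
#' @export
km_rmst <- function(km, tmax) {
  stopifnot(tmax > 0)
  knots <- c(0, km$time[km$time < tmax], tmax)
  s <- c(1, km$survival[km$time < tmax])
  sum(s * diff(knots))
}

#' @export
print.km_curve <- function(x, ...) {
  med <- km_median(x)
  cat("Kaplan-Meier curve: n =", x$n,
      "| events =", sum(x$n_event),
      "| median =", if (is.na(med)) "not reached" else
        paste0(format(med, digits = 4), " months"), "\n")
  invisible(x)
}
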