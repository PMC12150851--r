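#' Write economic parameters to a YAML config file
#'
#' @param econ An \code{"econ_params"} list.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_econ_config <- function(econ, path) {
  x <- unclass(econ)
  x$patient <- unclass(x$patient)
  x$schedule <- unclass(x$schedule)
  x$ae <- lapply(as.list(x$ae), function(col)
    if (is.factor(col)) as.character(col) else col)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read economic parameters from a YAML config file
#'
#' @param path Config file as written by \code{\link{write_econ_config}}.
#' @return An \code{"econ_params"} list.
#' @export
read_econ_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$patient <- do.call(patient_spec, x$patient)
  x$schedule <- structure(x$schedule, class = "schedule_spec")
  x$ae <- as.data.frame(x$ae)
  structure(x, class = "econ_params")
}

#' Default full analysis configuration
#'
#' Bundles the trial emulation spec, model settings, economic parameters and
#' willingness-to-pay thresholds into one list, the shape consumed by the
#' pipeline examples. The censoring pattern of the emulator (uniform accrual
#' over 18 months, 36-month follow-up) is an assumption, not a trial-reported
#' quantity.
#'
#' @return Nested list with elements \code{trial}, \code{settings},
#'   \code{econ}, \code{wtp}.
#' @export
default_config <- function() {
  list(trial = default_trial_spec(),
       settings = model_settings(),
       econ = default_econ_params(),
       wtp = wtp_thresholds())
}
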