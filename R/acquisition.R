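# Acquisition protocol specification.

# cohort means under rest and stress used as defaults when a heart rate is
# not supplied
.default_heart_rate <- c(rest = 84.86, stress = 93.04)
.default_peak_hu <- c(rest = 640.07, stress = 540.07)

#' Define a contrast injection / acquisition protocol
#'
#' Encodes the weight-based injection protocol: contrast dose in mL/kg
#' injected at a fixed rate, followed by a saline chaser, with ECG-gated
#' volumes reconstructed at a fixed fraction of the R-R interval. The
#' injection time is derived, `T_i = dose * weight / rate`.
#'
#' @param weight subject weight (kg), > 0.
#' @param condition `"rest"` or `"stress"`.
#' @param heart_rate heart rate (beats/min); defaults to the cohort mean for
#'   the condition (84.86 rest, 93.04 stress).
#' @param contrast_dose contrast dose (mL/kg), default 1.
#' @param injection_rate injection rate (mL/s), default 5.
#' @param saline_dose saline chaser dose (mL/kg), default 0.5.
#' @param gating_phase reconstruction phase as a fraction of R-R, default 0.75.
#' @param seed integer seed for any downstream stochastic generation.
#' @return an object of class `acquisition_spec` with derived `T_i` (s).
#' @export
acquisition_spec <- function(weight, condition = c("rest", "stress"),
                             heart_rate = NULL, contrast_dose = 1.0,
                             injection_rate = 5.0, saline_dose = 0.5,
                             gating_phase = 0.75, seed = NULL) {
  condition <- match.arg(condition)
  check_positive(weight, "weight")
  check_positive(contrast_dose, "contrast_dose")
  check_positive(injection_rate, "injection_rate")
  check_nonnegative(saline_dose, "saline_dose")
  if (gating_phase < 0 || gating_phase >= 1)
    fpact_abort("gating_phase must lie in [0, 1)", "fpact_invalid_parameter")
  if (is.null(heart_rate)) heart_rate <- .default_heart_rate[[condition]]
  check_positive(heart_rate, "heart_rate")
  structure(
    list(weight = weight, condition = condition, heart_rate = heart_rate,
         contrast_dose = contrast_dose, injection_rate = injection_rate,
         saline_dose = saline_dose,
         T_i = contrast_dose * weight / injection_rate,
         gating_phase = gating_phase, seed = seed),
    class = "acquisition_spec"
  )
}

#' @export
print.acquisition_spec <- function(x, ...) {
  cat(sprintf("Acquisition: %.1f kg %s, HR %.1f bpm, T_i = %.2f s (%.0f mL @ %.0f mL/s)\n",
              x$weight, x$condition, x$heart_rate, x$T_i,
              x$contrast_dose * x$weight, x$injection_rate))
  invisible(x)
}

#' ECG-gate time stamps for an acquisition
#'
#' One reconstruction per cardiac cycle at the gating phase: gate k sits at
#' `(k - 1 + gating_phase) * 60 / heart_rate` seconds.
#'
#' @param spec an [acquisition_spec()].
#' @param duration scan duration (s).
#' @return numeric vector of gate times (s), strictly increasing.
#' @export
gate_times <- function(spec, duration) {
  rr <- 60 / spec$heart_rate
  n <- floor(duration / rr)
  (seq_len(n) - 1 + spec$gating_phase) * rr
}
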