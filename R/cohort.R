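# Cohort simulation and end-to-end experiment orchestration.

#' Experiment configuration
#'
#' Describes a synthetic cohort emulating the validation study: subject
#' weights spanning the 28-96 mL injection-volume range (injection times
#' 5.6-19.2 s at 1 mL/kg and 5 mL/s), one to two rest plus one to three
#' stress acquisitions per subject, condition-specific heart rates, a fixed
#' generator dispersion delay, and the bolus-tracking protocol settings.
#'
#' @param n_subjects number of subjects, default 28.
#' @param weight_range subject weight range (kg), default `c(28, 96)`.
#' @param hr_model `"cohort"` draws heart rates from the condition-specific
#'   normals (rest 84.86 +/- 13.67, stress 93.04 +/- 12.09 beats/min,
#'   truncated to `hr_range`); `"uniform"` draws uniformly on `hr_range`.
#' @param hr_range heart-rate range (beats/min), default `c(59.74, 126.94)`.
#' @param acq_per_subject `c(rest_min, rest_max, stress_min, stress_max)`
#'   acquisitions per subject, default 1-2 rest and 1-3 stress.
#' @param dispersion_delay generator dispersion delay T_d (s), default 2.3.
#' @param noise_sd additive HU noise, default 10.
#' @param b gamma shape, default 3.
#' @param baseline_hu blood-pool baseline (HU), default 40.
#' @param t0 contrast arrival delay (s), default 6.
#' @param trigger_delta trigger threshold above baseline (HU), default 140.
#' @param protocol_d protocol dispersion delay d for perfusion runs (s),
#'   default 1.
#' @param d_grid sweep grid (s), default 0-4 by 0.5.
#' @param perfusion_range range of ground-truth perfusion values drawn per
#'   acquisition (mL/min/g), default `c(0.5, 3)`.
#' @param phantom_grid phantom grid for perfusion runs; small by default so
#'   cohort-scale runs stay within test budgets.
#' @param seed master seed (mandatory for reproducibility).
#' @return a list of class `experiment_config`.
#' @export
experiment_config <- function(n_subjects = 28, weight_range = c(28, 96),
                              hr_model = c("cohort", "uniform"),
                              hr_range = c(59.74, 126.94),
                              acq_per_subject = c(1, 2, 1, 3),
                              dispersion_delay = 2.3, noise_sd = 10,
                              b = 3, baseline_hu = 40, t0 = 6,
                              trigger_delta = 140, protocol_d = 1,
                              d_grid = seq(0, 4, by = 0.5),
                              perfusion_range = c(0.5, 3),
                              phantom_grid = c(16L, 16L, 8L),
                              seed = 1L) {
  hr_model <- match.arg(hr_model)
  if (is.null(seed))
    fpact_abort("a seed is mandatory for stochastic experiment runs",
                "fpact_invalid_parameter")
  structure(
    list(n_subjects = n_subjects, weight_range = weight_range,
         hr_model = hr_model, hr_range = hr_range,
         acq_per_subject = acq_per_subject,
         dispersion_delay = dispersion_delay, noise_sd = noise_sd,
         b = b, baseline_hu = baseline_hu, t0 = t0,
         trigger_delta = trigger_delta, protocol_d = protocol_d,
         d_grid = d_grid, perfusion_range = perfusion_range,
         phantom_grid = as.integer(phantom_grid), seed = as.integer(seed)),
    class = "experiment_config"
  )
}

.hr_sd <- c(rest = 13.67, stress = 12.09)

draw_heart_rate <- function(config, condition) {
  if (config$hr_model == "uniform")
    return(stats::runif(1, config$hr_range[1], config$hr_range[2]))
  repeat {
    hr <- stats::rnorm(1, .default_heart_rate[[condition]], .hr_sd[[condition]])
    if (hr >= config$hr_range[1] && hr <= config$hr_range[2]) return(hr)
  }
}

#' Simulate a cohort of acquisitions
#'
#' Each subject receives a weight, per-condition heart rates, and one to two
#' rest plus one to three stress acquisitions; each acquisition gets its own
#' seed derived hierarchically from the master seed, so cohort growth never
#' reshuffles earlier subjects. Each element carries the acquisition spec,
#' the sampled noisy aortic curve, and the true generating parameters.
#'
#' @param config an [experiment_config()].
#' @return list of class `fpa_cohort`; elements are lists with `subject`,
#'   `condition`, `spec`, `curve`, `true_params`, `true_P` (mL/min/g).
#' @export
simulate_cohort <- function(config = experiment_config()) {
  cohort <- list()
  for (s in seq_len(config$n_subjects)) {
    sseed <- derive_seed(config$seed, s)
    subject <- with_seed(sseed, {
      w <- stats::runif(1, config$weight_range[1], config$weight_range[2])
      nr <- sample(config$acq_per_subject[1]:config$acq_per_subject[2], 1)
      ns <- sample(config$acq_per_subject[3]:config$acq_per_subject[4], 1)
      conds <- c(rep("rest", nr), rep("stress", ns))
      hrs <- vapply(conds, function(cc) draw_heart_rate(config, cc), numeric(1))
      Ps <- stats::runif(length(conds), config$perfusion_range[1],
                         config$perfusion_range[2])
      list(w = w, conds = conds, hrs = hrs, Ps = Ps)
    })
    for (a in seq_along(subject$conds)) {
      cond <- subject$conds[a]
      spec <- acquisition_spec(subject$w, cond, heart_rate = subject$hrs[a],
                               seed = derive_seed(sseed, a))
      model <- curve_model_config(cond, b = config$b, C = config$baseline_hu,
                                  t0 = config$t0,
                                  dispersion_delay = config$dispersion_delay,
                                  noise_sd = config$noise_sd)
      gen <- generate_aortic_curve(spec, model)
      cohort[[length(cohort) + 1]] <- list(
        subject = s, condition = cond, spec = spec, model = model,
        curve = gen$curve, true_params = gen$params, true_P = subject$Ps[a])
    }
  }
  class(cohort) <- c("fpa_cohort", "list")
  cohort
}

#' Fit every acquisition's aortic curve
#'
#' @param cohort an `fpa_cohort`.
#' @return the cohort with a `fit` ([gamma_params()]) added per acquisition.
#' @export
fit_cohort <- function(cohort) {
  for (i in seq_along(cohort)) cohort[[i]]$fit <- fit_gamma(cohort[[i]]$curve)
  cohort
}

#' Timing regression over a fitted cohort
#'
#' Extracts `T_g` from each fitted curve via the second-derivative landmark,
#' averages per subject, and regresses on half the injection time.
#'
#' @param cohort a fitted `fpa_cohort` (see [fit_cohort()]).
#' @param literal passed to [timing_regression()].
#' @return a `timing_regression` with the per-measurement table attached as
#'   attribute `"measurements"`.
#' @export
cohort_timing_regression <- function(cohort, literal = FALSE) {
  tab <- data.frame(
    subject = vapply(cohort, `[[`, numeric(1), "subject"),
    half_ti = vapply(cohort, function(a) a$spec$T_i / 2, numeric(1)),
    t_g = vapply(cohort, function(a) timing_landmarks(a$fit)$T_g, numeric(1))
  )
  reg <- timing_regression(tab$half_ti, tab$t_g, grouping = tab$subject,
                           literal = literal)
  attr(reg, "measurements") <- tab
  reg
}

#' Run the full synthetic experiment
#'
#' Generate a cohort, fit every aortic curve, regress time-to-peak on half
#' injection time, sweep the protocol dispersion delay, run the low-dose
#' versus retrospective-reference perfusion comparison on a phantom
#' sub-study, and assemble the dose report. Fully reproducible from the
#' config seed. When `outdir` is given, each stage writes its table (CSV)
#' or summary (JSON) there.
#'
#' @param config an [experiment_config()].
#' @param n_perfusion number of acquisitions in the perfusion sub-study
#'   (default 20; 0 skips the stage).
#' @param outdir optional output directory for stage artifacts.
#' @param dose list of dose-chain inputs (`ctdi_vol_32`, `effective_diameter`,
#'   `scan_length`, `k_factor`).
#' @return a list of class `fpa_experiment` with elements `cohort`,
#'   `timing` (regression or a recorded stage error), `sweep`, `perfusion`
#'   (agreement of low-dose vs reference global means), `dose`.
#' @export
run_experiment <- function(config = experiment_config(), n_perfusion = 20,
                           outdir = NULL,
                           dose = list(ctdi_vol_32 = 9.2,
                                       effective_diameter = 23,
                                       scan_length = 16, k_factor = 0.014)) {
  cohort <- simulate_cohort(config)
  cohort <- fit_cohort(cohort)

  timing <- tryCatch(cohort_timing_regression(cohort),
                     fpact_error = function(e)
                       list(error = conditionMessage(e)))

  pconf <- protocol_config(trigger_delta = config$trigger_delta,
                           dispersion_delay_d = config$protocol_d,
                           d_grid = config$d_grid)
  sweep <- dispersion_sweep(cohort, pconf)

  perfusion <- NULL
  if (n_perfusion > 0) {
    idx <- seq_len(min(n_perfusion, length(cohort)))
    ref <- low <- numeric(0)
    for (i in idx) {
      acq <- cohort[[i]]
      ph <- phantom_spec(grid_shape = config$phantom_grid,
                         true_perfusion = acq$true_P,
                         baseline_hu_myo = 45)
      series <- generate_dynamic_phantom(acq$spec, ph, acq$model)
      m_ref <- tryCatch(reference_retrospective(series, fitted = acq$fit),
                        fpact_error = function(e) NULL)
      m_low <- tryCatch(lowdose_fpa(series, pconf, fitted = acq$fit),
                        fpact_error = function(e) NULL)
      if (!is.null(m_ref) && !is.null(m_low)) {
        ref <- c(ref, m_ref$global_mean)
        low <- c(low, m_low$global_mean)
      }
    }
    perfusion <- tryCatch(
      c(agreement(ref, low), list(reference = ref, lowdose = low)),
      fpact_error = function(e) list(error = conditionMessage(e)))
  }

  dose_rep <- do.call(dose_report, dose)

  out <- structure(
    list(config = config, cohort = cohort, timing = timing, sweep = sweep,
         perfusion = perfusion, dose = dose_rep),
    class = "fpa_experiment"
  )
  if (!is.null(outdir)) write_experiment(out, outdir)
  out
}

#' @export
print.fpa_experiment <- function(x, ...) {
  cat(sprintf("FPA experiment: %d acquisitions from %d subjects (seed %d)\n",
              length(x$cohort), x$config$n_subjects, x$config$seed))
  if (inherits(x$timing, "timing_regression")) print(x$timing)
  else cat("  timing stage:", x$timing$error, "\n")
  best <- x$sweep$d[which.min(abs(x$sweep$mean))]
  cat(sprintf("  sweep: best d = %.1f s (smallest |mean offset|)\n", best))
  if (!is.null(x$perfusion) && is.null(x$perfusion$error))
    cat(sprintf("  perfusion: low-dose = %.3f * reference + %.3f (r = %.3f, n = %d)\n",
                x$perfusion$slope, x$perfusion$intercept,
                x$perfusion$pearson_r, x$perfusion$n))
  print(x$dose)
  invisible(x)
}

# stage artifacts: CSV tables and JSON summaries under outdir
write_experiment <- function(exp, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (inherits(exp$timing, "timing_regression")) {
    utils::write.csv(attr(exp$timing, "measurements"),
                     file.path(outdir, "timing_measurements.csv"),
                     row.names = FALSE)
    jsonlite::write_json(unclass(exp$timing)[c("slope", "intercept",
                                               "pearson_r", "rmse", "rmsd", "n")],
                         file.path(outdir, "timing_regression.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  utils::write.csv(as.data.frame(exp$sweep),
                   file.path(outdir, "dispersion_sweep.csv"),
                   row.names = FALSE)
  if (!is.null(exp$perfusion) && is.null(exp$perfusion$error)) {
    utils::write.csv(data.frame(reference = exp$perfusion$reference,
                                lowdose = exp$perfusion$lowdose),
                     file.path(outdir, "perfusion_pairs.csv"),
                     row.names = FALSE)
    jsonlite::write_json(exp$perfusion[c("slope", "intercept", "pearson_r",
                                         "ccc", "rmse", "rmsd", "bias",
                                         "loa_low", "loa_high", "p_value", "n")],
                         file.path(outdir, "perfusion_agreement.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(unclass(exp$dose), file.path(outdir, "dose_report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}
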