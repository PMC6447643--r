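# Voxel-wise first-pass-analysis perfusion from two gated volumes.
#
# One-compartment indicator dilution with no venous outflow over the
# measurement window: mean perfusion is the rate of myocardial contrast mass
# entry normalized by the arterial input level and the tissue mass, and the
# voxel map redistributes the mean by each voxel's enhancement change:
#
#   P_AVE = 60 * dHU_AVE / (rho * C_in * (t2 - t1))   [mL/min/g]
#   P_v   = P_AVE * dHU_v / dHU_AVE

#' Pair of gated volume scans for perfusion measurement
#'
#' @param v1,v2 HU volumes (arrays of identical shape) at times `t1 < t2`.
#' @param t1,t2 scan times (s).
#' @param myocardium_mask,aorta_mask logical arrays matching the volumes.
#' @param voxel_volume voxel volume (mL).
#' @param baseline_aorta pre-contrast aortic attenuation (HU), used to
#'   baseline-subtract the aortic ROI.
#' @return an object of class `volume_pair`.
#' @export
volume_pair <- function(v1, v2, t1, t2, myocardium_mask, aorta_mask,
                        voxel_volume, baseline_aorta = 0) {
  if (!identical(dim(v1), dim(v2)))
    fpact_abort("v1 and v2 must have identical shape", "fpact_dimension")
  if (t2 <= t1)
    fpact_abort("t2 must be later than t1", "fpact_invalid_parameter")
  for (nm in c("myocardium_mask", "aorta_mask"))
    if (!identical(dim(get(nm)), dim(v1)))
      fpact_abort(sprintf("%s does not match the volumes", nm), "fpact_dimension")
  check_positive(voxel_volume, "voxel_volume")
  structure(list(v1 = v1, v2 = v2, t1 = t1, t2 = t2,
                 myocardium_mask = myocardium_mask, aorta_mask = aorta_mask,
                 voxel_volume = voxel_volume, baseline_aorta = baseline_aorta),
            class = "volume_pair")
}

#' Arterial input level between the two scans
#'
#' `two_point` mode (all that is available prospectively) averages the
#' baseline-subtracted aortic ROI means of the two scans; `integral` mode
#' (retrospective reference) averages the fitted baseline-subtracted curve
#' over `[t1, t2]` using the closed-form running integral.
#'
#' @param pair a [volume_pair()].
#' @param mode `"two_point"` or `"integral"`.
#' @param fitted a [gamma_params()]; required for `integral` mode.
#' @return C_in (HU), guaranteed positive.
#' @export
compute_cin <- function(pair, mode = c("two_point", "integral"), fitted = NULL) {
  mode <- match.arg(mode)
  idx <- which(pair$aorta_mask)
  if (!length(idx))
    fpact_abort("empty aorta mask", "fpact_invalid_parameter")
  cin <- if (mode == "two_point") {
    a1 <- mean(pair$v1[idx]) - pair$baseline_aorta
    a2 <- mean(pair$v2[idx]) - pair$baseline_aorta
    (a1 + a2) / 2
  } else {
    if (is.null(fitted))
      fpact_abort("integral mode requires fitted gamma parameters",
                  "fpact_invalid_parameter")
    diff(gamma_cumulative(fitted, c(pair$t1, pair$t2))) / (pair$t2 - pair$t1)
  }
  if (!is.finite(cin) || cin <= 0)
    fpact_abort("non-physiological arterial input: C_in <= 0",
                "fpact_non_physiological_input")
  cin
}

#' Voxel-wise first-pass perfusion map
#'
#' Computes the perfusion map and its intermediates from the enhancement
#' change between the two scans. The mean of the voxel map over the
#' myocardial mask equals the global mean by construction.
#'
#' @param pair a [volume_pair()].
#' @param C_in arterial input level (HU), > 0 (see [compute_cin()]).
#' @param density tissue density (g/mL), default 1.05.
#' @param guard error when the average enhancement change is non-positive
#'   (V2 not later on the upslope than V1); with `guard = FALSE` a zero map
#'   is returned instead.
#' @return an object of class `perfusion_map`: `voxel_perfusion` (vector
#'   over the mask, mL/min/g), `global_mean`, and intermediates `M_T` (g),
#'   `C_in` (HU), `delta_hu_ave` (HU), `dMc_dt` (HU*mL/s).
#' @export
fpa_map <- function(pair, C_in, density = 1.05, guard = TRUE) {
  check_positive(C_in, "C_in")
  check_positive(density, "density")
  idx <- which(pair$myocardium_mask)
  if (!length(idx))
    fpact_abort("empty myocardium mask", "fpact_invalid_parameter")
  dt <- pair$t2 - pair$t1
  d_hu <- pair$v2[idx] - pair$v1[idx]
  d_ave <- mean(d_hu)
  if (d_ave <= 0) {
    if (guard)
      fpact_abort("average myocardial enhancement did not increase between V1 and V2",
                  "fpact_invalid_enhancement")
    d_hu <- rep(0, length(idx))               # zero map
  }
  M_T <- density * pair$voxel_volume * length(idx)
  dMc_dt <- sum(d_hu) * pair$voxel_volume / dt
  p_ave <- 60 * mean(d_hu) / (density * C_in * dt)
  voxel <- if (mean(d_hu) > 0) p_ave * d_hu / mean(d_hu) else rep(0, length(idx))
  structure(
    list(voxel_perfusion = voxel, global_mean = p_ave,
         mask_index = idx,
         M_T = M_T, C_in = C_in, delta_hu_ave = mean(pair$v2[idx] - pair$v1[idx]),
         dMc_dt = dMc_dt, t1 = pair$t1, t2 = pair$t2),
    class = "perfusion_map"
  )
}

#' @export
print.perfusion_map <- function(x, ...) {
  cat(sprintf("FPA perfusion map: %d voxels, global mean %.3f mL/min/g\n",
              length(x$voxel_perfusion), x$global_mean))
  cat(sprintf("  M_T = %.2f g, C_in = %.1f HU, dHU_AVE = %.2f HU, dMc/dt = %.3f HU*mL/s\n",
              x$M_T, x$C_in, x$delta_hu_ave, x$dMc_dt))
  invisible(x)
}

# shared: build a volume_pair from two gates of a dynamic series
series_pair <- function(series, i1, i2) {
  ph <- series$phantom
  volume_pair(series$volumes[[i1]], series$volumes[[i2]],
              series$gate_times[i1], series$gate_times[i2],
              myocardium_mask = ph$myocardium_mask,
              aorta_mask = ph$aorta_mask,
              voxel_volume = (ph$voxel_size / 10)^3,  # mm^3 -> mL via cm^3
              baseline_aorta = series$aortic_curve$baseline)
}

#' Retrospective reference perfusion map
#'
#' The reference standard: fits the full retrospective aortic curve, places
#' V1 at the gate nearest the fitted base landmark and V2 at the gate
#' nearest the fitted peak, and uses the integral-mode arterial input.
#'
#' @param series a `dynamic_series` from [generate_dynamic_phantom()].
#' @param fitted optional pre-computed [gamma_params()] for the series'
#'   aortic curve; fitted on demand otherwise.
#' @return a `perfusion_map`.
#' @export
reference_retrospective <- function(series, fitted = NULL) {
  if (is.null(fitted)) fitted <- fit_gamma(series$aortic_curve)
  lm_ <- timing_landmarks(fitted)
  i1 <- which.min(abs(series$gate_times - lm_$t_base))
  i2 <- which.min(abs(series$gate_times - lm_$t_peak))
  if (i2 <= i1) i2 <- i1 + 1
  pair <- series_pair(series, i1, i2)
  fpa_map(pair, compute_cin(pair, "integral", fitted),
          density = series$phantom$tissue_density)
}

#' Low-dose protocol perfusion map
#'
#' Emulates the prospective two-scan protocol: bolus-tracking trigger, V1 as
#' the next gated scan, V2 at `T_i/2 + d` after V1, and the two-point
#' arterial input (the only one available from two scans).
#'
#' @param series a `dynamic_series`.
#' @param config a [protocol_config()] (provides trigger threshold and `d`).
#' @param cin_mode `"two_point"` (default, prospective) or `"integral"`.
#' @param fitted optional [gamma_params()] fit of the full curve, used for
#'   `integral` mode.
#' @return a `perfusion_map` with the `protocol_result` attached as
#'   attribute `"protocol"`.
#' @export
lowdose_fpa <- function(series, config = protocol_config(),
                        cin_mode = c("two_point", "integral"), fitted = NULL) {
  cin_mode <- match.arg(cin_mode)
  if (is.null(fitted) && cin_mode == "integral")
    fitted <- fit_gamma(series$aortic_curve)
  acq <- list(curve = series$aortic_curve, spec = series$spec,
              fit = if (is.null(fitted)) fit_gamma(series$aortic_curve) else fitted)
  prot <- run_protocol(acq, config)
  i1 <- which.min(abs(series$gate_times - prot$v1_time))
  i2 <- which.min(abs(series$gate_times - prot$v2_time))
  pair <- series_pair(series, i1, i2)
  map <- fpa_map(pair, compute_cin(pair, cin_mode, fitted = acq$fit),
                 density = series$phantom$tissue_density)
  attr(map, "protocol") <- prot
  map
}
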