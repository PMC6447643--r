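# Digital dynamic-CT phantom: aorta + myocardium with known perfusion.
#
# Forward model per myocardial voxel v (one-compartment, no venous outflow
# over the first pass):
#   HU_v(t) = baseline_hu_myo + (P_v * rho / 60) * integral_{t0}^{t} c_a(s) ds
# with c_a the baseline-subtracted aortic curve, rho the tissue density in
# g/mL, and P_v the ground-truth perfusion in mL/min/g. The first-pass map
# (fpa_map) is the exact algebraic inverse of this model.

#' Phantom geometry and ground truth
#'
#' @param grid_shape integer length-3 voxel grid dimensions.
#' @param voxel_size isotropic voxel edge (mm).
#' @param aorta_mask,myocardium_mask logical arrays of `grid_shape`; must be
#'   disjoint.
#' @param true_perfusion ground-truth perfusion (mL/min/g): a scalar applied
#'   to every myocardial voxel or an array matching `grid_shape`.
#' @param tissue_density myocardial density (g/mL), default 1.05.
#' @param baseline_hu_myo pre-contrast myocardial attenuation (HU).
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(32L, 32L, 16L), voxel_size = 1,
                         aorta_mask = NULL, myocardium_mask = NULL,
                         true_perfusion = 1.5, tissue_density = 1.05,
                         baseline_hu_myo = 45) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3 || any(grid_shape < 2))
    fpact_abort("grid_shape must be three dimensions of at least 2 voxels",
                "fpact_invalid_parameter")
  check_positive(voxel_size, "voxel_size")
  check_positive(tissue_density, "tissue_density")
  if (is.null(aorta_mask) || is.null(myocardium_mask)) {
    m <- default_masks(grid_shape)
    if (is.null(aorta_mask)) aorta_mask <- m$aorta
    if (is.null(myocardium_mask)) myocardium_mask <- m$myocardium
  }
  for (nm in c("aorta_mask", "myocardium_mask")) {
    msk <- get(nm)
    if (!identical(dim(msk), grid_shape))
      fpact_abort(sprintf("%s does not match grid_shape", nm), "fpact_dimension")
  }
  if (any(aorta_mask & myocardium_mask))
    fpact_abort("aorta and myocardium masks overlap", "fpact_invalid_parameter")
  if (!any(aorta_mask) || !any(myocardium_mask))
    fpact_abort("aorta and myocardium masks must be non-empty (grid too small?)",
                "fpact_invalid_parameter")
  if (length(true_perfusion) == 1)
    true_perfusion <- array(true_perfusion, grid_shape)
  if (!identical(dim(true_perfusion), grid_shape))
    fpact_abort("true_perfusion must be scalar or match grid_shape",
                "fpact_dimension")
  if (any(true_perfusion < 0))
    fpact_abort("true_perfusion must be non-negative", "fpact_invalid_parameter")
  structure(
    list(grid_shape = grid_shape, voxel_size = voxel_size,
         aorta_mask = aorta_mask, myocardium_mask = myocardium_mask,
         true_perfusion = true_perfusion, tissue_density = tissue_density,
         baseline_hu_myo = baseline_hu_myo),
    class = "phantom_spec"
  )
}

# central cylindrical aorta surrounded by an annular myocardial shell
default_masks <- function(grid_shape) {
  nx <- grid_shape[1]; ny <- grid_shape[2]; nz <- grid_shape[3]
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  r <- sqrt(outer((seq_len(nx) - cx)^2, (seq_len(ny) - cy)^2, "+"))
  r_ao <- max(2, nx / 10)
  plane_ao <- r <= r_ao
  plane_myo <- r > r_ao + 1.5 & r <= min(nx, ny) * 0.45
  list(aorta = array(plane_ao, grid_shape),
       myocardium = array(plane_myo, grid_shape))
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("Phantom %s @ %.1f mm: aorta %d vox, myocardium %d vox, mean P %.2f mL/min/g\n",
              paste(x$grid_shape, collapse = "x"), x$voxel_size,
              sum(x$aorta_mask), sum(x$myocardium_mask),
              mean(x$true_perfusion[x$myocardium_mask])))
  invisible(x)
}

#' Generate an ECG-gated dynamic phantom series
#'
#' Aortic voxels follow the gamma-variate enhancement curve; myocardial
#' voxels accumulate contrast proportionally to their ground-truth perfusion
#' (one-compartment model with no outflow); background stays flat. Per-voxel
#' Gaussian HU noise is seeded from the acquisition seed.
#'
#' @param spec an [acquisition_spec()].
#' @param phantom a [phantom_spec()].
#' @param model a [curve_model_config()].
#' @param duration scan duration (s); same default as
#'   [generate_aortic_curve()].
#' @return an object of class `dynamic_series`: list with `gate_times`,
#'   `volumes` (list of HU arrays), `spec`, `phantom`, `true_params` (the
#'   generating [gamma_params()]), and `aortic_curve` (the ROI-mean measured
#'   curve).
#' @export
generate_dynamic_phantom <- function(spec, phantom = phantom_spec(),
                                     model = curve_model_config(spec$condition),
                                     duration = NULL) {
  gen <- generate_aortic_curve(spec, model, duration)
  params <- gen$params
  tg <- gen$curve$times

  aorta_true <- gamma_value(params, tg)                      # includes baseline C
  cum <- gamma_cumulative(params, tg)                        # HU*s above baseline
  rho <- phantom$tissue_density
  myo_idx <- which(phantom$myocardium_mask)
  ao_idx <- which(phantom$aorta_mask)
  P <- phantom$true_perfusion[myo_idx]

  volumes <- vector("list", length(tg))
  noise_seed <- if (is.null(spec$seed)) NULL else derive_seed(spec$seed, 7919L)
  make_vols <- function() {
    for (k in seq_along(tg)) {
      vol <- array(0, phantom$grid_shape)
      vol[ao_idx] <- aorta_true[k]
      vol[myo_idx] <- phantom$baseline_hu_myo + (P * rho / 60) * cum[k]
      if (model$noise_sd > 0)
        vol <- vol + array(stats::rnorm(length(vol), 0, model$noise_sd),
                           phantom$grid_shape)
      volumes[[k]] <<- vol
    }
  }
  if (is.null(noise_seed)) make_vols() else with_seed(noise_seed, make_vols())

  measured <- vapply(volumes, function(v) mean(v[ao_idx]), numeric(1))
  structure(
    list(gate_times = tg, volumes = volumes, spec = spec, phantom = phantom,
         true_params = params,
         aortic_curve = aortic_curve(tg, measured, baseline = model$C)),
    class = "dynamic_series"
  )
}

#' @export
print.dynamic_series <- function(x, ...) {
  cat(sprintf("Dynamic series: %d gates over %.1f s, grid %s\n",
              length(x$gate_times), max(x$gate_times),
              paste(x$phantom$grid_shape, collapse = "x")))
  invisible(x)
}

#' Mean time-density curve over a mask
#'
#' @param series a `dynamic_series`.
#' @param mask logical array matching the series grid.
#' @param baseline optional known baseline (HU); defaults to the series'
#'   aortic baseline.
#' @return an [aortic_curve()] of per-gate ROI means.
#' @export
extract_roi_curve <- function(series, mask, baseline = NA_real_) {
  idx <- which(mask)
  if (!length(idx)) fpact_abort("empty mask", "fpact_invalid_parameter")
  y <- vapply(series$volumes, function(v) mean(v[idx]), numeric(1))
  aortic_curve(series$gate_times, y, baseline = baseline)
}
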