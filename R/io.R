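# Plain-text serialization of dynamic series and experiment configs.
#
# A dynamic series is written as a directory: a JSON manifest (grid shape,
# voxel size, gate times, file names, acquisition metadata), integer-label
# mask CSV, and one flattened-CSV volume per gate. Text-only by design so
# fixtures and outputs stay portable and diffable.

#' Write / read a dynamic series as plain text
#'
#' @param series a `dynamic_series`.
#' @param dir output directory (created if missing).
#' @return `read_dynamic_series` returns a `dynamic_series` (without the
#'   generating parameters, which are not part of the on-disk contract).
#' @export
write_dynamic_series <- function(series, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ph <- series$phantom
  gate_files <- sprintf("gate_%03d.csv", seq_along(series$gate_times))
  manifest <- list(
    grid_shape = ph$grid_shape, voxel_size = ph$voxel_size,
    tissue_density = ph$tissue_density,
    baseline_hu_myo = ph$baseline_hu_myo,
    baseline_hu_aorta = series$aortic_curve$baseline,
    gate_times = series$gate_times, gate_files = gate_files,
    weight = series$spec$weight, condition = series$spec$condition,
    heart_rate = series$spec$heart_rate, T_i = series$spec$T_i,
    gating_phase = series$spec$gating_phase
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  labels <- array(0L, ph$grid_shape)
  labels[ph$aorta_mask] <- 1L
  labels[ph$myocardium_mask] <- 2L
  utils::write.csv(data.frame(label = as.integer(labels)),
                   file.path(dir, "labels.csv"), row.names = FALSE)
  utils::write.csv(data.frame(perfusion = as.numeric(ph$true_perfusion)),
                   file.path(dir, "true_perfusion.csv"), row.names = FALSE)
  for (k in seq_along(series$volumes))
    utils::write.csv(data.frame(hu = as.numeric(series$volumes[[k]])),
                     file.path(dir, gate_files[k]), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_dynamic_series
#' @export
read_dynamic_series <- function(dir) {
  m <- jsonlite::read_json(file.path(dir, "manifest.json"),
                           simplifyVector = TRUE)
  shape <- as.integer(m$grid_shape)
  labels <- array(utils::read.csv(file.path(dir, "labels.csv"))$label, shape)
  perf <- array(utils::read.csv(file.path(dir, "true_perfusion.csv"))$perfusion,
                shape)
  ph <- phantom_spec(grid_shape = shape, voxel_size = m$voxel_size,
                     aorta_mask = labels == 1L, myocardium_mask = labels == 2L,
                     true_perfusion = perf, tissue_density = m$tissue_density,
                     baseline_hu_myo = m$baseline_hu_myo)
  spec <- acquisition_spec(m$weight, m$condition, heart_rate = m$heart_rate,
                           gating_phase = m$gating_phase)
  volumes <- lapply(m$gate_files, function(f)
    array(utils::read.csv(file.path(dir, f))$hu, shape))
  ao_idx <- which(ph$aorta_mask)
  measured <- vapply(volumes, function(v) mean(v[ao_idx]), numeric(1))
  structure(
    list(gate_times = as.numeric(m$gate_times), volumes = volumes,
         spec = spec, phantom = ph, true_params = NULL,
         aortic_curve = aortic_curve(as.numeric(m$gate_times), measured,
                                     baseline = m$baseline_hu_aorta)),
    class = "dynamic_series"
  )
}

#' Read / write an experiment configuration as YAML
#'
#' @param path YAML file path.
#' @param config an [experiment_config()].
#' @return `read_experiment_config` returns an [experiment_config()].
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(experiment_config))
  do.call(experiment_config, y[intersect(names(y), known)])
}

#' @rdname read_experiment_config
#' @export
write_experiment_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
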