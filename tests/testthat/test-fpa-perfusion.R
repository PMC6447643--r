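# First-pass-analysis perfusion: arterial input, voxel maps, round trips.

make_pair <- function(series, i1, i2) fpact:::series_pair(series, i1, i2)

test_that("two-point and integral inputs agree exactly on a linear curve", {
  # aorta enhancing linearly in t: trapezoid (two-point) is exact
  ph <- small_phantom()
  shape <- ph$grid_shape
  mk <- function(val) {
    v <- array(0, shape); v[ph$aorta_mask] <- val; v
  }
  pair <- volume_pair(mk(100), mk(300), t1 = 10, t2 = 14,
                      myocardium_mask = ph$myocardium_mask,
                      aorta_mask = ph$aorta_mask, voxel_volume = 0.001,
                      baseline_aorta = 0)
  two <- compute_cin(pair, "two_point")
  expect_equal(two, 200)
  # linear fitted stand-in via quadrature on the same line
  expect_equal(two, integrate(function(t) 100 + 50 * (t - 10), 10, 14)$value / 4)
})

test_that("integral-mode input matches adaptive quadrature", {
  p <- gamma_params(A = 400, tau = 12, b = 3, C = 30, t0 = 0)
  ph <- small_phantom()
  v <- array(0, ph$grid_shape)
  pair <- volume_pair(v, v + 1, t1 = 8, t2 = 15,
                      myocardium_mask = ph$myocardium_mask,
                      aorta_mask = ph$aorta_mask, voxel_volume = 0.001)
  got <- compute_cin(pair, "integral", fitted = p)
  oracle <- integrate(function(t) gamma_value(p, t) - p$C, 8, 15,
                      rel.tol = 1e-10)$value / 7
  expect_equal(got, oracle, tolerance = 1e-6)
})

test_that("non-physiological arterial input is refused", {
  ph <- small_phantom()
  v <- array(0, ph$grid_shape)       # aorta at baseline in both scans
  pair <- volume_pair(v, v, t1 = 1, t2 = 2,
                      myocardium_mask = ph$myocardium_mask,
                      aorta_mask = ph$aorta_mask, voxel_volume = 0.001)
  expect_error(compute_cin(pair, "two_point"),
               class = "fpact_non_physiological_input")
  # empty aorta mask
  pair2 <- volume_pair(v, v + 100, t1 = 1, t2 = 2,
                       myocardium_mask = ph$myocardium_mask,
                       aorta_mask = array(FALSE, ph$grid_shape),
                       voxel_volume = 0.001)
  expect_error(compute_cin(pair2, "two_point"), class = "fpact_invalid_parameter")
})

test_that("fpa_map guards, scale invariance, and mask-mean identity", {
  spec <- acquisition_spec(50, "rest", seed = 8)
  ser <- generate_dynamic_phantom(spec, small_phantom(P = 1.5), noiseless_model())
  pair <- make_pair(ser, 12, 25)
  # v2 = v1 errors; with the guard disabled the map is all zero
  same <- volume_pair(pair$v1, pair$v1, pair$t1, pair$t2,
                      pair$myocardium_mask, pair$aorta_mask, pair$voxel_volume,
                      pair$baseline_aorta)
  expect_error(fpa_map(same, C_in = 100), class = "fpact_invalid_enhancement")
  expect_equal(fpa_map(same, C_in = 100, guard = FALSE)$global_mean, 0)
  map <- fpa_map(pair, C_in = 150)
  # mean of the voxel map equals the global mean exactly by construction
  expect_equal(mean(map$voxel_perfusion), map$global_mean, tolerance = 1e-10)
  # scaling enhancements and C_in together leaves the map unchanged
  scaled <- volume_pair(pair$v1 * 3, pair$v2 * 3, pair$t1, pair$t2,
                        pair$myocardium_mask, pair$aorta_mask,
                        pair$voxel_volume, pair$baseline_aorta * 3)
  map3 <- fpa_map(scaled, C_in = 450)
  expect_equal(map3$voxel_perfusion, map$voxel_perfusion, tolerance = 1e-12)
  expect_equal(map3$global_mean, map$global_mean, tolerance = 1e-12)
})

test_that("noiseless uniform phantom round-trips through the reference map", {
  spec <- acquisition_spec(52, "rest", seed = 3)
  ser <- generate_dynamic_phantom(spec, small_phantom(P = 1.5), noiseless_model())
  map <- reference_retrospective(ser)
  expect_equal(map$global_mean, 1.5, tolerance = 1e-6)
  expect_equal(max(abs(map$voxel_perfusion - 1.5)), 0, tolerance = 1e-5)
  # doubling true perfusion doubles the recovered map
  ser2 <- generate_dynamic_phantom(spec, small_phantom(P = 3.0), noiseless_model())
  expect_equal(reference_retrospective(ser2)$global_mean, 2 * map$global_mean,
               tolerance = 1e-6)
})

test_that("low-dose equals reference when the selections coincide", {
  # engineered geometry: sparse gates (HR 30), a steep near-symmetric bolus
  # (b = 8), and a low trigger threshold put the first-gate-after-trigger on
  # the base-nearest gate, and some d in the grid lands V2 on the peak gate
  spec <- acquisition_spec(40, "rest", heart_rate = 30, seed = 2)  # T_i = 8
  model <- curve_model_config("rest", b = 8, t0 = 5.71, noise_sd = 0,
                              dispersion_delay = 2.3)
  ser <- generate_dynamic_phantom(spec, small_phantom(P = 2), model)
  fitted <- fit_gamma(ser$aortic_curve)
  lm_ <- timing_landmarks(fitted)
  ref_gates <- c(which.min(abs(ser$gate_times - lm_$t_base)),
                 which.min(abs(ser$gate_times - lm_$t_peak)))
  hit <- FALSE
  for (d in seq(0, 4, by = 0.5)) {
    cfg <- protocol_config(trigger_delta = 20, dispersion_delay_d = d)
    prot <- tryCatch(
      run_protocol(list(curve = ser$aortic_curve, spec = spec, fit = fitted), cfg),
      fpact_error = function(e) NULL)
    if (is.null(prot)) next
    low_gates <- c(which.min(abs(ser$gate_times - prot$v1_time)),
                   which.min(abs(ser$gate_times - prot$v2_time)))
    if (identical(low_gates, ref_gates)) {
      hit <- TRUE
      low <- lowdose_fpa(ser, cfg, cin_mode = "integral", fitted = fitted)
      ref <- reference_retrospective(ser, fitted = fitted)
      expect_equal(low$voxel_perfusion, ref$voxel_perfusion, tolerance = 1e-12)
      break
    }
  }
  expect_true(hit)
})

test_that("a low-perfusion insert stays below the surrounding myocardium", {
  grid <- c(12L, 12L, 6L)
  P <- array(1.8, grid)
  insert <- array(FALSE, grid); insert[3:5, 3:5, ] <- TRUE
  ph0 <- small_phantom()
  insert <- insert & ph0$myocardium_mask
  P[insert] <- 0.5                          # stenosis emulation
  ph <- phantom_spec(grid_shape = grid, true_perfusion = P,
                     aorta_mask = ph0$aorta_mask,
                     myocardium_mask = ph0$myocardium_mask)
  spec <- acquisition_spec(50, "rest", seed = 21)
  ser <- generate_dynamic_phantom(spec, ph, noiseless_model())
  map <- reference_retrospective(ser)
  full <- array(NA_real_, grid)
  full[map$mask_index] <- map$voxel_perfusion
  expect_lt(mean(full[insert]), mean(full[ph$myocardium_mask & !insert]))
})

test_that("maps stay finite when V2 is placed beyond the peak", {
  spec <- acquisition_spec(50, "rest", seed = 8)
  ser <- generate_dynamic_phantom(spec, small_phantom(P = 1.5), noiseless_model())
  fitted <- fit_gamma(ser$aortic_curve)
  i_pk <- which.min(abs(ser$gate_times - timing_landmarks(fitted)$t_peak))
  late <- min(i_pk + 6, length(ser$gate_times))
  pair <- make_pair(ser, i_pk - 4, late)
  map <- fpa_map(pair, compute_cin(pair, "integral", fitted))
  expect_true(all(is.finite(map$voxel_perfusion)))
  expect_true(is.finite(map$global_mean))
})
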