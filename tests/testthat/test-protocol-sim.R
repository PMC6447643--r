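# Bolus-tracking protocol: trigger, V1/V2 selection, peak offsets, sweep.

test_that("trigger fires at the first gate reaching the threshold", {
  # crossing sits between gates 5 and 6
  t <- 1:10
  y <- c(40, 40, 40, 45, 100, 200, 400, 500, 450, 300)
  cv <- aortic_curve(t, y, baseline = 40)
  expect_equal(detect_trigger(cv), 6)
  # threshold above the maximum never fires
  expect_error(detect_trigger(cv, protocol_config(trigger_delta = 1000)),
               class = "fpact_no_trigger")
  # raising the threshold never yields an earlier trigger
  trig <- vapply(c(20, 60, 140, 300, 400),
                 function(d) detect_trigger(cv, protocol_config(trigger_delta = d)),
                 numeric(1))
  expect_true(all(diff(trig) >= 0))
})

test_that("trigger agrees with the analytic root on a noiseless curve", {
  spec <- acquisition_spec(52, "rest", seed = 1)
  gen <- generate_aortic_curve(spec, noiseless_model())
  # oracle: root of the analytic model at baseline + 140
  root <- uniroot(function(t) gamma_value(gen$params, t) - (40 + 140),
                  c(gen$params$t0, gen$params$t0 + gen$params$tau))$root
  trig <- detect_trigger(gen$curve)
  gates <- gen$curve$times
  expect_equal(trig, gates[which(gates >= root)[1]])
})

test_that("V1/V2 selection follows the delay rule on an explicit gate grid", {
  gates <- 0:40                                  # HR 60, one gate per second
  spec <- acquisition_spec(45, "rest")           # T_i = 9 s
  cfg <- protocol_config(dispersion_delay_d = 1)
  sel <- select_v1_v2(10.2, spec, cfg, gates)
  expect_equal(sel$v1_time, 11)                  # first gate after trigger
  expect_equal(sel$v2_time, 17)                  # first gate >= 11 + 5.5
  # d = 0 with T_i/2 an exact gate multiple lands V2 exactly on a gate
  spec8 <- acquisition_spec(40, "rest")          # T_i = 8, T_i/2 = 4
  sel0 <- select_v1_v2(10.2, spec8, protocol_config(dispersion_delay_d = 0), gates)
  expect_equal(sel0$v2_time, sel0$v1_time + 4)
  # exhausted windows error
  expect_error(select_v1_v2(41, spec, cfg, gates),
               class = "fpact_acquisition_window")
  expect_error(select_v1_v2(38, spec, cfg, gates),
               class = "fpact_acquisition_window")
})

test_that("peak offset counts gated-scan indices", {
  gates <- (0:29) * 0.8 + 0.6                    # HR 75
  expect_equal(peak_offset(gates[10], gates[10] + 0.1, gates), 0L)
  expect_equal(peak_offset(gates[12], gates[10], gates), 2L)
  # enumeration oracle for peak 14.3 s, v2 13.0 s
  i_v2 <- which.min(abs(gates - 13.0))
  i_pk <- which.min(abs(gates - 14.3))
  expect_equal(peak_offset(13.0, 14.3, gates), as.integer(i_v2 - i_pk))
  expect_equal(peak_offset(13.0, 14.3, gates, continuous = TRUE,
                           heart_rate = 75), -1.3 * 75 / 60)
})

test_that("v2 time is non-decreasing in the dispersion delay", {
  cohort <- tiny_cohort()
  for (acq in cohort) {
    trig <- detect_trigger(acq$curve)
    v2 <- vapply(seq(0, 4, by = 0.5), function(d)
      select_v1_v2(trig, acq$spec, protocol_config(dispersion_delay_d = d),
                   acq$curve$times)$v2_time, numeric(1))
    expect_true(all(diff(v2) >= 0))
  }
})

test_that("dispersion sweep summarizes offsets per delay", {
  cohort <- tiny_cohort()
  sw <- dispersion_sweep(cohort, protocol_config(d_grid = seq(0, 4, by = 1)))
  expect_s3_class(sw, "sweep_summary")
  expect_equal(sw$d, seq(0, 4, by = 1))
  expect_equal(sw$n, rep(length(cohort), nrow(sw)))
  # rmse dominates |mean|, and the mean offset grows with d
  expect_true(all(sw$rmse >= abs(sw$mean) - 1e-12))
  expect_true(all(diff(sw$mean) >= 0))
  # mean |offset| at the best d beats d = 4.0
  expect_lt(min(abs(sw$mean)), abs(sw$mean[sw$d == 4]))
})

test_that("a degenerate cohort with V2 on the peak gate gives zero offsets", {
  # constructed acquisition: gates 1 s apart, threshold first reached at the
  # 10-s gate, V1 = 11 s, T_i/2 + d = 4 -> V2 = 15 s, and the fitted peak at
  # 15.2 s has 15 s as its nearest gate: V2 lands exactly on the peak gate
  gates <- 1:30
  params <- gamma_params(A = 500, tau = 9.2, b = 3, C = 40, t0 = 6)
  curve <- aortic_curve(gates, gamma_value(params, gates), baseline = 40)
  spec <- acquisition_spec(40, "rest")           # T_i = 8 -> T_i/2 = 4
  acq <- list(curve = curve, spec = spec, fit = params)
  cfg <- protocol_config(dispersion_delay_d = 0, d_grid = 0)
  res <- run_protocol(acq, cfg)
  expect_equal(res$ideal_peak_time, 15.2)
  expect_equal(res$v1_time, 11)
  expect_equal(res$v2_time, 15)
  expect_identical(res$offset_beats, 0L)
  sw <- dispersion_sweep(list(acq, acq), cfg)
  expect_equal(sw$mean, 0)
  expect_equal(sw$rmse, 0)
  expect_equal(sw$n, 2L)
})

test_that("window-exhausted acquisitions are skipped with a warning", {
  gates <- 1:12
  params <- gamma_params(A = 500, tau = 9.2, b = 3, C = 40, t0 = 6)
  curve <- aortic_curve(gates, gamma_value(params, gates), baseline = 40)
  acq <- list(curve = curve, spec = acquisition_spec(60, "rest"), fit = params)
  expect_warning(sw <- dispersion_sweep(list(acq), protocol_config(d_grid = 4)),
                 "skipped")
  expect_equal(sw$n, 0L)
})
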