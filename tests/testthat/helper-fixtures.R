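# Shared fixtures: small, deterministic builders used across test files.

ref_params <- function(A = 300, tau = 12, b = 3, C = 50, t0 = 6)
  gamma_params(A = A, tau = tau, b = b, C = C, t0 = t0)

noiseless_model <- function(condition = "rest", dispersion_delay = 2.3, b = 3)
  curve_model_config(condition, b = b, dispersion_delay = dispersion_delay,
                     noise_sd = 0)

small_phantom <- function(P = 1.5, grid = c(12L, 12L, 6L), ...)
  phantom_spec(grid_shape = grid, true_perfusion = P, ...)

# independent landmark oracle: brute-force maximization of the numerical
# second difference of the curve values on a dense grid (no analytic
# derivatives involved)
oracle_t_base <- function(params, n = 1e6) {
  h <- params$tau * 1e-5
  t <- seq(params$t0 + h, params$t0 + params$tau - h, length.out = n)
  d2 <- (gamma_value(params, t + h) - 2 * gamma_value(params, t) +
           gamma_value(params, t - h)) / h^2
  t[which.max(d2)]
}

# a small fitted cohort shared by protocol tests (kept tiny for speed)
tiny_cohort <- function(n_subjects = 4, seed = 202, ...) {
  fit_cohort(simulate_cohort(experiment_config(n_subjects = n_subjects,
                                               seed = seed, ...)))
}
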