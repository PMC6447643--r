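# Nonlinear least-squares fitting of aortic time-density curves.

#' Fit a gamma-variate model to an aortic time-density curve
#'
#' Least-squares fit of the gamma-variate model with free arrival delay.
#' Initialization follows curve heuristics (baseline from the minimum,
#' amplitude from the range, arrival from the 10%-of-range crossing, peak
#' time from the sample maximum, shape 3); five jittered restarts guard
#' against local minima, best residual sum of squares wins, ties broken by
#' the smallest shape exponent.
#'
#' @param curve an [aortic_curve()] object, or anything with numeric
#'   `times`/`enhancement` components, with at least 6 samples spanning the
#'   base through the peak.
#' @param n_starts number of jittered initializations (default 5).
#' @return a [gamma_params()] object with `fit_rss` filled in.
#' @export
fit_gamma <- function(curve, n_starts = 5) {
  t <- as.numeric(curve$times)
  y <- as.numeric(curve$enhancement)
  if (length(t) != length(y))
    fpact_abort("times and enhancement must have equal length", "fpact_dimension")
  if (length(t) < 6)
    fpact_abort("need at least 6 samples to fit a gamma variate", "fpact_insufficient_data")

  rng <- diff(range(y))
  # noise scale from first differences; a flat curve has nothing to fit
  noise <- stats::mad(diff(y)) / sqrt(2)
  if (rng < 5 * max(noise, .Machine$double.eps))
    fpact_abort("curve is flat: range below 5x the noise estimate",
                "fpact_degenerate_curve")

  C0 <- min(y)
  A0 <- max(y) - C0
  i_arr <- which(y > C0 + 0.1 * rng)[1]
  t_arr <- if (is.na(i_arr)) t[1] else t[i_arr]
  t_max <- t[which.max(y)]
  tau0 <- max(t_max - t_arr, diff(range(t)) / 10)
  b0 <- 3

  # optimize over theta = (log A, log tau, log b, C, t0)
  rss <- function(theta) {
    p <- list(A = exp(theta[1]), tau = exp(theta[2]), b = exp(theta[3]),
              C = theta[4], t0 = theta[5])
    if (!is.finite(p$A) || !is.finite(p$tau) || p$t0 < 0) return(1e300)
    u <- (t - p$t0) / p$tau
    f <- rep(p$C, length(t))
    i <- which(u > 0)
    if (length(i)) f[i] <- p$C + p$A * u[i]^p$b * exp(p$b * (1 - u[i]))
    s <- sum((y - f)^2)
    if (!is.finite(s)) 1e300 else s
  }

  starts <- vector("list", n_starts)
  starts[[1]] <- c(log(A0), log(tau0), log(b0), C0, max(t_arr, 0))
  if (n_starts > 1) {
    jit <- with_seed(1407L, lapply(seq_len(n_starts - 1), function(i)
      c(stats::rnorm(3, 0, 0.25), stats::rnorm(1, 0, 0.05 * max(rng, 1)),
        stats::rnorm(1, 0, 0.1 * max(tau0, 1)))))
    for (i in seq_len(n_starts - 1))
      starts[[i + 1]] <- starts[[1]] + jit[[i]] * c(1, 1, 1, 1, 1)
  }

  best <- NULL
  for (s0 in starts) {
    s0[5] <- max(s0[5], 0)
    fit <- tryCatch({
      nm <- stats::optim(s0, rss, method = "Nelder-Mead",
                         control = list(maxit = 4000, reltol = 1e-14))
      stats::optim(nm$par, rss, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-14))
    }, error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$value)) next
    if (is.null(best) ||
        fit$value < best$value - 1e-12 ||
        (abs(fit$value - best$value) <= 1e-12 && fit$par[3] < best$par[3]))
      best <- fit
  }
  if (is.null(best))
    fpact_abort("gamma-variate fit failed to converge after restarts",
                "fpact_fit_failure")

  gamma_params(A = exp(best$par[1]), tau = exp(best$par[2]),
               b = exp(best$par[3]), C = best$par[4],
               t0 = max(best$par[5], 0), fit_rss = best$value)
}
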