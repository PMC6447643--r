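# Agreement statistics: OLS + Pearson r, identity-line RMSE / fit-line RMSD,
# Bland-Altman limits, Lin's concordance correlation, paired t tests.

#' Agreement between two paired measurement sets
#'
#' Regression of `y` on `x` with Pearson correlation; root-mean-square error
#' about the identity line and root-mean-square deviation about the fitted
#' line; Lin's concordance correlation coefficient (population moments,
#' `2 s_xy / (s_x^2 + s_y^2 + (mean x - mean y)^2)`); Bland-Altman bias and
#' 1.96-SD limits of agreement; and a two-sided paired t test.
#'
#' @param x reference measurements.
#' @param y comparison measurements, same length, n >= 3.
#' @param literal use the sqrt-of-SD reading of RMSE/RMSD (see
#'   [timing_regression()]).
#' @return an object of class `agreement_result` with fields `slope`,
#'   `intercept`, `pearson_r`, `ccc`, `rmse`, `rmsd`, `bias`, `loa_low`,
#'   `loa_high`, `t_stat`, `p_value`, `n`.
#' @export
agreement <- function(x, y, literal = FALSE) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (n != length(y))
    fpact_abort("x and y must have equal length", "fpact_dimension")
  if (n < 3)
    fpact_abort("need at least 3 pairs", "fpact_insufficient_data")
  if (stats::sd(x) == 0 && stats::sd(y) == 0)
    fpact_abort("both measurement sets are constant", "fpact_degenerate_data")

  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2]); intercept <- unname(stats::coef(fit)[1])
  r <- if (stats::sd(x) > 0 && stats::sd(y) > 0) stats::cor(x, y) else NA_real_

  # population (1/n) moments for the concordance coefficient
  sxy <- mean((x - mean(x)) * (y - mean(y)))
  sx2 <- mean((x - mean(x))^2); sy2 <- mean((y - mean(y))^2)
  ccc <- 2 * sxy / (sx2 + sy2 + (mean(x) - mean(y))^2)

  agg <- if (literal) function(r_) sqrt(stats::sd(r_)) else
    function(r_) sqrt(mean(r_^2))
  rmse <- agg(y - x)
  rmsd <- agg(stats::residuals(fit))

  d <- y - x
  bias <- mean(d); sd_d <- stats::sd(d)
  tt <- if (sd_d > 0) paired_t(y, x) else list(t_stat = NA_real_, p_value = NA_real_)

  structure(
    list(slope = slope, intercept = intercept, pearson_r = r, ccc = ccc,
         rmse = rmse, rmsd = rmsd, bias = bias,
         loa_low = bias - 1.96 * sd_d, loa_high = bias + 1.96 * sd_d,
         t_stat = tt$t_stat, p_value = tt$p_value, n = n),
    class = "agreement_result"
  )
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("y = %.3f x + %.3f  (n = %d)\n", x$slope, x$intercept, x$n))
  cat(sprintf("  r = %.3f, CCC = %.3f, RMSE = %.3f, RMSD = %.3f\n",
              x$pearson_r, x$ccc, x$rmse, x$rmsd))
  cat(sprintf("  bias = %.3f [%.3f, %.3f], paired t = %.3f, p = %.4g\n",
              x$bias, x$loa_low, x$loa_high, x$t_stat, x$p_value))
  invisible(x)
}

#' Paired sample t test
#'
#' Standard paired t with n-1 degrees of freedom and two-sided p-value,
#' computed from the closed form `t = mean(d) / (sd(d)/sqrt(n))`.
#'
#' @param a,b paired measurements of equal length, n >= 2.
#' @param zero_variance `"error"` (default) to refuse identical pairs, or
#'   `"zero"` to return `t = 0`, `p = 1` by convention.
#' @return list with `t_stat`, `p_value`, `df`.
#' @export
paired_t <- function(a, b, zero_variance = c("error", "zero")) {
  zero_variance <- match.arg(zero_variance)
  a <- as.numeric(a); b <- as.numeric(b)
  n <- length(a)
  if (n != length(b))
    fpact_abort("a and b must have equal length", "fpact_dimension")
  if (n < 2)
    fpact_abort("need at least 2 pairs", "fpact_insufficient_data")
  d <- a - b
  sd_d <- stats::sd(d)
  if (sd_d == 0) {
    if (zero_variance == "error")
      fpact_abort("zero variance of paired differences", "fpact_degenerate_test")
    return(list(t_stat = 0, p_value = 1, df = n - 1))
  }
  t_stat <- mean(d) / (sd_d / sqrt(n))
  list(t_stat = t_stat,
       p_value = 2 * stats::pt(-abs(t_stat), df = n - 1),
       df = n - 1)
}
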