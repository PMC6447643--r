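# Regression of the base-to-peak interval on half the injection time.

#' Regress time-to-peak on half injection time
#'
#' Ordinary least squares of the base-to-peak interval `T_g` on half the
#' contrast injection time `T_i/2`. Repeated measurements are averaged per
#' subject before regression when a grouping vector is supplied, so the
#' regression operates on subject means. The intercept estimates the fixed
#' dispersion delay of the timing rule `T_p = T_i/2 + T_d`.
#'
#' RMSE is the root-mean-square of residuals about the identity line
#' `T_g = T_i/2`; RMSD is the root-mean-square of residuals about the fitted
#' line. With `literal = TRUE` both are instead the square root of the
#' standard deviation of the respective residuals (an alternative reading of
#' the same definitions; see the methods vignette).
#'
#' @param half_ti half injection times (s).
#' @param t_g base-to-peak intervals (s).
#' @param grouping optional subject identifiers; measurements sharing an id
#'   are averaged before regression.
#' @param literal use the literal sqrt-of-SD reading of RMSE/RMSD.
#' @return an object of class `timing_regression`: list with `slope`,
#'   `intercept` (s), `pearson_r`, `rmse` (s), `rmsd` (s), `n`.
#' @export
timing_regression <- function(half_ti, t_g, grouping = NULL, literal = FALSE) {
  x <- as.numeric(half_ti); y <- as.numeric(t_g)
  if (length(x) != length(y))
    fpact_abort("half_ti and t_g must have equal length", "fpact_dimension")
  if (!is.null(grouping)) {
    if (length(grouping) != length(x))
      fpact_abort("grouping must match the measurements", "fpact_dimension")
    x <- as.numeric(tapply(x, grouping, mean))
    y <- as.numeric(tapply(y, grouping, mean))
  }
  n <- length(x)
  if (n < 3)
    fpact_abort("need at least 3 subjects for the timing regression",
                "fpact_insufficient_data")
  if (stats::sd(x) == 0)
    fpact_abort("degenerate regressor: half injection times are constant",
                "fpact_degenerate_regressor")

  fit <- stats::lm(y ~ x)
  res_fit <- stats::residuals(fit)
  res_id <- y - x
  agg <- if (literal) function(r) sqrt(stats::sd(r)) else
    function(r) sqrt(mean(r^2))
  structure(
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         pearson_r = stats::cor(x, y),
         rmse = agg(res_id),
         rmsd = agg(res_fit),
         n = n),
    class = "timing_regression"
  )
}

#' @export
print.timing_regression <- function(x, ...) {
  cat(sprintf("T_g = %.3f * (T_i/2) + %.3f s   (n = %d subjects)\n",
              x$slope, x$intercept, x$n))
  cat(sprintf("  r = %.3f, RMSE = %.3f s, RMSD = %.3f s\n",
              x$pearson_r, x$rmse, x$rmsd))
  invisible(x)
}
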