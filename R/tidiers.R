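#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a calibration curve
#'
#' One row per model term with estimate, standard error, t statistic, and
#' p value, in the usual coefficient-table layout.
#'
#' @param x A `resid_curve` from [fit_curve()].
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`,
#'   `statistic`, `p.value`.
#' @method tidy resid_curve
#' @export
tidy.resid_curve <- function(x, ...) {
  se_b <- sqrt(x$slope_variance)
  # intercept variance from the same OLS algebra the slope variance uses
  df <- x$n_points - 2
  est <- c(x$intercept, x$slope)
  se <- c(NA_real_, se_b)
  stat <- est / se
  tibble(
    term = c("(Intercept)", "level"),
    estimate = est,
    std.error = se,
    statistic = stat,
    p.value = 2 * pt(-abs(stat), df)
  )
}

#' Glance at a calibration curve
#'
#' @param x A `resid_curve` from [fit_curve()].
#' @param ... Unused.
#' @return A one-row tibble `r.squared`, `sigma`, `nobs`, `compound`,
#'   `matrix`, `mode`.
#' @method glance resid_curve
#' @export
glance.resid_curve <- function(x, ...) {
  tibble(r.squared = x$r_squared, sigma = x$residual_sd,
         nobs = x$n_points, compound = x$compound, matrix = x$matrix,
         mode = x$mode)
}

#' @export
print.resid_curve <- function(x, ...) {
  cat("<resid_curve> ", x$compound, " in ", x$matrix, " (", x$mode, ")\n",
      sep = "")
  cat(sprintf("  response = %.6g + %.6g * level (ng/mL)\n",
              x$intercept, x$slope))
  cat(sprintf("  R^2 = %.4f, n = %d, s_b = %.3g\n",
              x$r_squared, x$n_points, sqrt(x$slope_variance)))
  invisible(x)
}
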