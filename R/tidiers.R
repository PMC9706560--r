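# broom-style tidiers for the package's fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a nearest-neighbor fit
#'
#' @param x An `nn_fit` object.
#' @param magnitudes Report magnitudes (`abs(estimate)`) instead of signed
#'   estimates.
#' @param ... Unused.
#' @return A tibble with one row per term: `term`, `estimate`, `se`,
#'   `p_value`, `wc_hbonds`.
#' @method tidy nn_fit
#' @export
tidy.nn_fit <- function(x, magnitudes = FALSE, ...) {
  out <- x$terms
  if (magnitudes) out$estimate <- abs(out$estimate)
  out
}

#' @rdname tidy.nn_fit
#' @method glance nn_fit
#' @export
glance.nn_fit <- function(x, ...) {
  tibble::tibble(
    observable = x$observable, weighting = x$weighting,
    n = x$n, df_residual = x$df_residual, sigma = x$sigma,
    r_squared = x$r_squared, calibrated = x$calibrated
  )
}

#' Tidy a van't Hoff fit
#'
#' @param x A `vant_hoff` object.
#' @param ... Unused.
#' @return `tidy`: one row per thermodynamic quantity (`dH`, `dS`,
#'   `dG`) with estimate, SE and units. `glance`: one-row fit summary.
#' @method tidy vant_hoff
#' @export
tidy.vant_hoff <- function(x, ...) {
  tibble::tibble(
    quantity = c("dH", "dS", "dG"),
    estimate = c(x$dH, x$dS, x$dG),
    se = c(x$dH_se, x$dS_se, x$dG_se),
    units = c("kcal/mol", "cal/K/mol",
              paste0("kcal/mol at ", x$ref_temp, " K"))
  )
}

#' @rdname tidy.vant_hoff
#' @method glance vant_hoff
#' @export
glance.vant_hoff <- function(x, ...) {
  tibble::tibble(tm_K = x$tm, r_squared = x$r_squared,
                 n_points = x$n_points, ct = x$ct,
                 self_complementary = x$self_complementary)
}

#' Tidy a calibration or benchmark
#'
#' @param x An `nn_calibration` or `nn_benchmark` object.
#' @param ... Unused.
#' @return `tidy`: per-pair residual tibble. `glance`: one-row summary.
#' @method tidy nn_calibration
#' @export
tidy.nn_calibration <- function(x, ...) x$residuals

#' @rdname tidy.nn_calibration
#' @method glance nn_calibration
#' @export
glance.nn_calibration <- function(x, ...) {
  tibble::tibble(a = x$a, b = x$b, a_se = x$a_se, b_se = x$b_se,
                 r_squared = x$r_squared, n = x$n)
}

#' @rdname tidy.nn_calibration
#' @method tidy nn_benchmark
#' @export
tidy.nn_benchmark <- function(x, ...) x$residuals

#' @rdname tidy.nn_calibration
#' @method glance nn_benchmark
#' @export
glance.nn_benchmark <- function(x, ...) {
  tibble::tibble(mean_absolute_difference = x$mean_absolute_difference,
                 mean_relative_error_percent = x$mean_relative_error_percent,
                 r_squared = x$r_squared, n = x$n)
}
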