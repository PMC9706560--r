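# Post-processing of end-point (MM-GBSA) binding-energy tables.
#
# This module never evaluates generalized Born energies: it consumes
# per-sequence tables of computed binding quantities and (i) applies the
# standard-state volume correction, (ii) calibrates computed against
# experimental values by an affine fit chi_exp = a * chi_com + b,
# (iii) reports benchmark error metrics, and (iv) propagates an affine
# calibration into nearest-neighbor terms.

#' Standard-state correction for simulated binding free energies
#'
#' Binding free energies computed in a finite periodic box refer to the
#' box concentration; referencing them to the 1 M standard state adds
#' `dG_ss = -R T ln(V_standard / V_box)` with `V_standard = 1661` cubic
#' Angstroms (the volume per molecule at 1 M). Larger boxes make the
#' binding free energy more positive. Only the magnitude
#' `|R T ln(V_box / V_standard)|` is convention-independent; the sign
#' convention here follows the standard-state literature.
#'
#' @param v_box Simulation box volume, cubic Angstroms.
#' @param temperature Temperature, K.
#' @param v_standard Standard-state volume per molecule, cubic Angstroms.
#' @return Correction in kcal/mol, to be added to the computed binding
#'   free energy.
#' @export
#' @examples
#' standard_state_correction(1661)            # 0
#' standard_state_correction(1661 * exp(1), 298)
standard_state_correction <- function(v_box, temperature = 298,
                                      v_standard = 1661) {
  if (any(v_box <= 0) || v_standard <= 0) {
    stop("volumes must be positive", call. = FALSE)
  }
  if (any(temperature <= 0)) stop("temperature must be > 0", call. = FALSE)
  -(.R_cal / 1000) * temperature * log(v_standard / v_box)
}

#' Affine calibration of computed against experimental observables
#'
#' Ordinary least squares of the experimental values on the computed
#' values: `chi_exp = a * chi_com + b`. Used to correct systematic
#' disagreement between end-point estimates and thermal-melting data.
#'
#' @param data A data frame holding both columns.
#' @param experimental,computed Column names (tidy-select style strings or
#'   bare names) of the experimental and computed values.
#' @return An object of class `nn_calibration`: list with `a` (slope),
#'   `b` (intercept), `a_se`, `b_se`, `r_squared`, `n` and per-pair
#'   `residuals`. Supports [tidy()] and [glance()].
#' @export
#' @examples
#' d <- data.frame(com = c(1, 2, 3), exp = c(7, 9, 11))
#' fit_calibration(d, exp, com) # a = 2, b = 5
fit_calibration <- function(data, experimental, computed) {
  stopifnot(is.data.frame(data))
  y <- dplyr::pull(data, {{ experimental }})
  x <- dplyr::pull(data, {{ computed }})
  if (length(x) != length(y)) stop("column lengths differ", call. = FALSE)
  if (length(x) < 3) {
    stop("need at least 3 pairs to fit a calibration; got ", length(x),
         call. = FALSE)
  }
  if (stats::sd(x) == 0) {
    stop("computed values have zero variance; slope unidentifiable",
         call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  a <- unname(stats::coef(fit)["x"])
  b <- unname(stats::coef(fit)["(Intercept)"])
  res <- unname(stats::residuals(fit))
  n <- length(x)
  # closed-form simple-regression errors (avoids summary.lm's
  # perfect-fit warning on exact affine inputs)
  sxx <- sum((x - mean(x))^2)
  syy <- sum((y - mean(y))^2)
  sigma2 <- sum(res^2) / (n - 2)
  structure(
    list(a = a, b = b,
         a_se = sqrt(sigma2 / sxx),
         b_se = sqrt(sigma2 * (1 / n + mean(x)^2 / sxx)),
         r_squared = if (syy > 0) 1 - sum(res^2) / syy else NA_real_,
         n = n,
         residuals = tibble::tibble(experimental = y, computed = x,
                                    fitted = unname(stats::fitted(fit)),
                                    residual = res)),
    class = "nn_calibration"
  )
}

#' @export
print.nn_calibration <- function(x, ...) {
  cat(sprintf("Affine calibration: exp = %.4f * com + %.4f (R^2 = %.4f, n = %d)\n",
              x$a, x$b, x$r_squared, x$n))
  invisible(x)
}

#' Apply an affine calibration elementwise
#'
#' @param values Numeric vector of computed observables.
#' @param calibration An `nn_calibration` object (or a list with `a`, `b`).
#' @return `a * values + b`.
#' @export
apply_calibration <- function(values, calibration) {
  stopifnot(is.numeric(values), !is.null(calibration$a), !is.null(calibration$b))
  calibration$a * values + calibration$b
}

#' Benchmark predicted against reference observables
#'
#' Mean absolute difference (taken as the error of the prediction), mean
#' relative error in percent (`100 |ref - pred| / |ref|`), and the R
#' squared of the linear association between predicted and reference
#' values. Entries with a zero reference are excluded from the relative
#' error with a warning.
#'
#' @param data A data frame holding both columns.
#' @param reference,predicted Column names (bare or quoted).
#' @return An object of class `nn_benchmark`: list with
#'   `mean_absolute_difference`, `mean_relative_error_percent`,
#'   `r_squared`, `n` and a `residuals` tibble with per-entry absolute
#'   and percent differences. Supports [tidy()] and [glance()].
#' @export
#' @examples
#' benchmark_predictions(data.frame(ref = 10, pred = 11), ref, pred)
benchmark_predictions <- function(data, reference, predicted) {
  stopifnot(is.data.frame(data))
  ref <- dplyr::pull(data, {{ reference }})
  pred <- dplyr::pull(data, {{ predicted }})
  if (length(ref) != length(pred) || length(ref) < 1) {
    stop("reference and predicted must be equal-length, non-empty",
         call. = FALSE)
  }
  abs_diff <- abs(ref - pred)
  rel_ok <- ref != 0
  if (any(!rel_ok)) {
    warning(sum(!rel_ok), " zero reference value(s) excluded from the ",
            "relative error", call. = FALSE)
  }
  pct_diff <- ifelse(rel_ok, 100 * abs_diff / abs(ref), NA_real_)
  r2 <- if (length(ref) >= 2 && stats::sd(ref) > 0 && stats::sd(pred) > 0) {
    stats::cor(ref, pred)^2
  } else if (all(abs_diff == 0)) 1 else NA_real_
  structure(
    list(mean_absolute_difference = mean(abs_diff),
         mean_relative_error_percent = mean(pct_diff, na.rm = TRUE),
         r_squared = r2, n = length(ref),
         residuals = tibble::tibble(reference = ref, predicted = pred,
                                    abs_diff = abs_diff,
                                    pct_diff = pct_diff)),
    class = "nn_benchmark"
  )
}

#' @export
print.nn_benchmark <- function(x, ...) {
  cat(sprintf(
    "Benchmark over %d pairs: MAE = %.2f, mean relative error = %.2f%%, R^2 = %s\n",
    x$n, x$mean_absolute_difference, x$mean_relative_error_percent,
    format(x$r_squared, digits = 4)))
  invisible(x)
}

#' Propagate an affine calibration into nearest-neighbor terms
#'
#' Fitting nearest-neighbor terms to calibrated observables
#' `a * chi + b` is, by linearity of least squares, equivalent to scaling
#' every stack and terminal-GC term by `a` and mapping the initiation
#' term to `a * init + b` (the intercept is absorbed entirely by the
#' per-duplex constant column). The result is flagged `calibrated`:
#' because slope coefficients differ between state variables, the
#' identity `ddG = ddH - T ddS` need not survive calibration, and the
#' calibrated initiation term may be dominated by the intercept, i.e. by
#' a metric of computational error rather than a physical quantity.
#'
#' @param params An `nn_fit` object.
#' @param calibration An `nn_calibration` object.
#' @return A new `nn_fit` object with scaled terms (SEs scaled by `|a|`,
#'   intercept treated as exact) and `calibrated = TRUE`.
#' @export
propagate_calibration <- function(params, calibration) {
  stopifnot(inherits(params, "nn_fit"), !is.null(calibration$a))
  a <- calibration$a
  b <- calibration$b
  out <- params
  is_init <- params$terms$term == "Init"
  out$terms$estimate <- a * params$terms$estimate + ifelse(is_init, b, 0)
  out$terms$se <- abs(a) * params$terms$se
  out$cov <- a^2 * params$cov
  out$calibrated <- TRUE
  out
}
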