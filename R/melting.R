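# Two-state UV-melting analysis.
#
# Absorbance at 260 nm rises on melting (single strands are hyperchromic
# relative to the duplex). Min-max normalization turns a melting curve
# into an alpha curve (duplexed fraction); a two-state equilibrium
# constant follows from alpha and the total strand concentration, and a
# linear van't Hoff fit of ln K against 1/T yields dH and dS under the
# assumption that both are temperature-independent.

#' Gas constant in cal/(K mol)
#' @keywords internal
.R_cal <- 1.987204

#' Normalize a melting curve to a duplexed-fraction (alpha) curve
#'
#' Min-max normalization (the default): `alpha(T) = (A_max - A(T)) /
#' (A_max - A_min)`, so `alpha = 1` is all duplex and `alpha = 0` all
#' single strands. With `baseline = "linear"` the duplex and
#' single-strand plateaus are instead fitted as straight lines through
#' the `n_baseline` lowest- and highest-temperature points and
#' `alpha(T) = (A_ss(T) - A(T)) / (A_ss(T) - A_ds(T))` (clamped to
#' [0, 1]); this removes sloping baselines and averages plateau noise,
#' at the cost of assuming the plateaus are reached at the grid ends.
#'
#' @param data A data frame with columns `temperature_K` (strictly
#'   increasing) and `absorbance`.
#' @param baseline `"none"` (default, plain min-max) or `"linear"`.
#' @param n_baseline Number of points fitted per plateau for
#'   `baseline = "linear"` (at least 2).
#' @return A tibble with columns `temperature_K` and `alpha`.
#' @export
normalize_to_alpha <- function(data, baseline = c("none", "linear"),
                               n_baseline = 4) {
  baseline <- match.arg(baseline)
  stopifnot(is.data.frame(data),
            all(c("temperature_K", "absorbance") %in% names(data)))
  tt <- as.numeric(data$temperature_K)
  aa <- as.numeric(data$absorbance)
  if (length(tt) < 4) stop("need at least 4 points", call. = FALSE)
  if (any(diff(tt) <= 0)) {
    stop("temperatures must be strictly increasing", call. = FALSE)
  }
  if (baseline == "linear") {
    nb <- max(2, min(n_baseline, floor(length(tt) / 3)))
    lo <- seq_len(nb)                      # duplex plateau (low T)
    hi <- seq(length(tt) - nb + 1, length(tt))  # single-strand plateau
    f_ds <- stats::lm(aa[lo] ~ tt[lo])
    f_ss <- stats::lm(aa[hi] ~ tt[hi])
    a_ds <- stats::coef(f_ds)[1] + stats::coef(f_ds)[2] * tt
    a_ss <- stats::coef(f_ss)[1] + stats::coef(f_ss)[2] * tt
    if (all(a_ss == a_ds)) {
      stop("flat absorbance curve: cannot normalize", call. = FALSE)
    }
    alpha <- pmin(1, pmax(0, (a_ss - aa) / (a_ss - a_ds)))
    return(tibble::tibble(temperature_K = tt, alpha = alpha))
  }
  rng <- range(aa)
  if (diff(rng) == 0) {
    stop("flat absorbance curve: cannot normalize", call. = FALSE)
  }
  tibble::tibble(temperature_K = tt,
                 alpha = (rng[2] - aa) / (rng[2] - rng[1]))
}

#' Melting temperature at alpha = 0.5
#'
#' Returns the temperature of the first downward crossing of
#' `alpha = 0.5`, linearly interpolated between the bracketing points.
#'
#' @param data A data frame with columns `temperature_K` and `alpha`.
#' @return Melting temperature in K.
#' @export
melting_temperature <- function(data) {
  stopifnot(is.data.frame(data),
            all(c("temperature_K", "alpha") %in% names(data)))
  tt <- as.numeric(data$temperature_K)
  al <- as.numeric(data$alpha)
  hit <- which(al == 0.5)
  cross <- which(al[-length(al)] > 0.5 & al[-1] < 0.5)
  if (length(hit) > 0 && (length(cross) == 0 || hit[1] <= cross[1])) {
    return(tt[hit[1]])
  }
  if (length(cross) == 0) {
    stop("alpha never crosses 0.5 downward (observed range [",
         format(min(al), digits = 4), ", ", format(max(al), digits = 4),
         "])", call. = FALSE)
  }
  i <- cross[1]
  tt[i] + (al[i] - 0.5) / (al[i] - al[i + 1]) * (tt[i + 1] - tt[i])
}

#' Two-state equilibrium constant from the duplexed fraction
#'
#' For self-complementary strands (2 A -> A2):
#' `K = alpha / (2 (1 - alpha)^2 C_T)`; for non-self-complementary
#' duplexes at equal strand concentrations: `K = 2 alpha /
#' ((1 - alpha)^2 C_T)`. `C_T` is the TOTAL strand concentration in
#' mol/L; K is dimensionless relative to 1 M. At `alpha = 0.5` the
#' self-complementary form gives `K = 1 / C_T`.
#'
#' @param alpha Duplexed fraction, strictly inside (0, 1); vectorized.
#' @param ct Total strand concentration, mol/L.
#' @param self_complementary Logical.
#' @return Equilibrium constant(s).
#' @export
#' @examples
#' equilibrium_constant(0.5, 1e-6, TRUE) # 1e6
equilibrium_constant <- function(alpha, ct, self_complementary) {
  if (ct <= 0) stop("`ct` must be positive", call. = FALSE)
  if (any(alpha <= 0 | alpha >= 1)) {
    stop("K diverges at alpha = 0 or 1; alpha must lie strictly in (0, 1)",
         call. = FALSE)
  }
  if (self_complementary) {
    alpha / (2 * (1 - alpha)^2 * ct)
  } else {
    2 * alpha / ((1 - alpha)^2 * ct)
  }
}

#' Van't Hoff analysis of an alpha curve
#'
#' Converts alpha values inside `alpha_window` to equilibrium constants
#' and fits `ln K = -dH/(R T) + dS/R` by ordinary least squares of ln K
#' on 1/T, so `dH = -R * slope` and `dS = R * intercept`
#' (R = 1.987204 cal/K/mol). Standard errors come from the regression
#' covariance; dG at `ref_temp` is `dH - T dS / 1000` with independent
#' error propagation. The window default avoids the divergent tails of
#' the K(alpha) transform.
#'
#' @param data A data frame with columns `temperature_K` and `alpha`.
#' @param ct Total strand concentration, mol/L.
#' @param self_complementary Logical.
#' @param alpha_window Inclusive `[lo, hi]` window of alpha values used
#'   in the regression.
#' @param ref_temp Reference temperature for dG, K.
#' @return An object of class `vant_hoff`: list with `dH` (kcal/mol),
#'   `dS` (cal/K/mol), `dG` (kcal/mol at `ref_temp`), their SEs, `tm`
#'   (K, from [melting_temperature()], NA if alpha never crosses 0.5),
#'   `r_squared`, `n_points`, and the regression data. Supports
#'   [tidy()], [glance()] and [autoplot()].
#' @export
vant_hoff_fit <- function(data, ct, self_complementary,
                          alpha_window = c(0.15, 0.85), ref_temp = 298) {
  stopifnot(is.data.frame(data),
            all(c("temperature_K", "alpha") %in% names(data)),
            length(alpha_window) == 2, alpha_window[1] < alpha_window[2])
  keep <- data$alpha >= alpha_window[1] & data$alpha <= alpha_window[2] &
    data$alpha > 0 & data$alpha < 1
  pts <- data[keep, ]
  if (nrow(pts) < 3) {
    stop("need at least 3 points with alpha inside [",
         alpha_window[1], ", ", alpha_window[2], "]; got ", nrow(pts),
         call. = FALSE)
  }
  lnK <- log(equilibrium_constant(pts$alpha, ct, self_complementary))
  invT <- 1 / pts$temperature_K
  fit <- stats::lm(lnK ~ invT)
  cf <- summary(fit)$coefficients
  dH <- -.R_cal * cf["invT", "Estimate"] / 1000       # kcal/mol
  dH_se <- .R_cal * cf["invT", "Std. Error"] / 1000
  dS <- .R_cal * cf["(Intercept)", "Estimate"]        # cal/K/mol
  dS_se <- .R_cal * cf["(Intercept)", "Std. Error"]
  dG <- gibbs_energy(dH, dS, ref_temp)
  dG_se <- sqrt(dH_se^2 + (ref_temp * dS_se / 1000)^2)
  tm <- tryCatch(melting_temperature(data), error = function(e) NA_real_)

  structure(
    list(dH = dH, dH_se = dH_se, dS = dS, dS_se = dS_se,
         dG = dG, dG_se = dG_se, ref_temp = ref_temp, tm = tm,
         r_squared = summary(fit)$r.squared, n_points = nrow(pts),
         ct = ct, self_complementary = self_complementary,
         alpha_window = alpha_window,
         data = tibble::tibble(temperature_K = pts$temperature_K,
                               inv_T = invT, ln_K = lnK,
                               fitted = stats::fitted(fit))),
    class = "vant_hoff"
  )
}

#' @export
print.vant_hoff <- function(x, ...) {
  cat("Two-state van't Hoff fit (", x$n_points, " points, R^2 = ",
      format(x$r_squared, digits = 5), ")\n", sep = "")
  cat(sprintf("  dH = %.2f +/- %.2f kcal/mol\n", x$dH, x$dH_se))
  cat(sprintf("  dS = %.2f +/- %.2f cal/K/mol\n", x$dS, x$dS_se))
  cat(sprintf("  dG(%g K) = %.2f +/- %.2f kcal/mol\n",
              x$ref_temp, x$dG, x$dG_se))
  if (!is.na(x$tm)) cat(sprintf("  Tm = %.1f K\n", x$tm))
  invisible(x)
}

#' Fit two-state thermodynamics to a raw melting curve
#'
#' Convenience wrapper: normalizes an absorbance curve with
#' [normalize_to_alpha()] and runs [vant_hoff_fit()]. Because the
#' normalization itself injects (correlated) error that the regression
#' standard errors cannot see, `se_method = "bootstrap"` re-estimates the
#' SEs by a parametric bootstrap of the whole pipeline: absorbance noise
#' is estimated from the residuals around a smoothing spline, replicate
#' curves are resampled, renormalized and refitted, and the SEs of dH,
#' dS, dG are replaced by the bootstrap spreads.
#'
#' @param data A data frame with columns `temperature_K`, `absorbance`.
#' @param ct Total strand concentration, mol/L.
#' @param self_complementary Logical.
#' @param baseline Passed to [normalize_to_alpha()]; `"linear"` is
#'   recommended for noisy curves (it averages plateau noise instead of
#'   anchoring the range on two extreme points).
#' @param se_method `"regression"` (plain [vant_hoff_fit()] SEs) or
#'   `"bootstrap"`.
#' @param n_boot Bootstrap replicates.
#' @param seed Optional seed for the bootstrap resampling.
#' @inheritParams vant_hoff_fit
#' @return A `vant_hoff` object (with an `se_method` field; bootstrap SEs
#'   when requested).
#' @export
melt_fit <- function(data, ct, self_complementary,
                     baseline = c("none", "linear"),
                     alpha_window = c(0.15, 0.85), ref_temp = 298,
                     se_method = c("regression", "bootstrap"),
                     n_boot = 200, seed = NULL) {
  baseline <- match.arg(baseline)
  se_method <- match.arg(se_method)
  alpha <- normalize_to_alpha(data, baseline = baseline)
  fit <- vant_hoff_fit(alpha, ct, self_complementary,
                       alpha_window = alpha_window, ref_temp = ref_temp)
  fit$se_method <- se_method
  if (se_method == "bootstrap") {
    tt <- as.numeric(data$temperature_K)
    aa <- as.numeric(data$absorbance)
    sm <- stats::smooth.spline(tt, aa)
    mu <- stats::predict(sm, tt)$y
    # residual sd understates the noise by the spline's fitted df
    n <- length(tt)
    noise_sd <- stats::sd(aa - mu) * sqrt(n / max(1, n - sm$df))
    boots <- .with_seed(seed, {
      purrr::map(seq_len(n_boot), function(b) {
        rep_curve <- tibble::tibble(
          temperature_K = tt,
          absorbance = mu + stats::rnorm(length(tt), sd = noise_sd)
        )
        tryCatch({
          f <- vant_hoff_fit(
            normalize_to_alpha(rep_curve, baseline = baseline),
            ct, self_complementary,
            alpha_window = alpha_window, ref_temp = ref_temp
          )
          c(f$dH, f$dS)
        }, error = function(e) c(NA_real_, NA_real_))
      })
    })
    bm <- do.call(rbind, boots)
    fit$dH_se <- stats::sd(bm[, 1], na.rm = TRUE)
    fit$dS_se <- stats::sd(bm[, 2], na.rm = TRUE)
    fit$dG_se <- stats::sd(bm[, 1] - ref_temp * bm[, 2] / 1000,
                           na.rm = TRUE)
    fit$n_boot <- sum(stats::complete.cases(bm))
  }
  fit
}

#' Gibbs free energy from enthalpy and entropy
#'
#' `dG = dH - T dS / 1000` with dH in kcal/mol and dS in cal/K/mol
#' (the /1000 reconciles the units). Vectorized over all arguments.
#'
#' @param dH Enthalpy, kcal/mol.
#' @param dS Entropy, cal/K/mol.
#' @param temperature Temperature, K (> 0).
#' @return Free energy, kcal/mol.
#' @export
#' @examples
#' gibbs_energy(-58.78, -151.42, 298) # about -13.66
gibbs_energy <- function(dH, dS, temperature) {
  if (any(temperature <= 0)) stop("temperature must be > 0", call. = FALSE)
  dH - temperature * dS / 1000
}
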