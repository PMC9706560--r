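# Nearest-neighbor decomposition of PNA homoduplex binding enthalpies.
#
# The binding observable of a duplex is modelled as the sum of its stack
# terms, a per-duplex helix-initiation term, and a terminal-GC term added
# only when both terminal base pairs are G.C:
#
#   d_chi = sum_i j_i * dd_chi_i + d_chi_init + B * d_chi_T.GC
#
# with j_i the occurrence count of canonical stack i and B in {0, 1}.
# All quantities are stored SIGNED (binding enthalpies negative =
# stabilizing); published tables print magnitudes (-dH), which are
# converted at I/O boundaries.

#' Build the nearest-neighbor design matrix
#'
#' One row per duplex: the 10 canonical stack occurrence counts, a
#' constant initiation column, and the terminal-GC indicator (1 only when
#' both terminal base pairs are G.C).
#'
#' @param data A data frame with a `sequence` column (or a character
#'   vector), or an output of [describe_duplex()].
#' @return A numeric matrix with `length(sequences)` rows and 12 columns
#'   (AA ... CG, Init, T.GC), with sequences as row names.
#' @export
#' @examples
#' build_design_matrix(c("CGATCG", "AACGTT"))
build_design_matrix <- function(data) {
  desc <- if (is.data.frame(data) && all(.stack_order %in% names(data))) {
    data
  } else {
    describe_duplex(data)
  }
  mat <- cbind(
    as.matrix(desc[, .stack_order]),
    Init = 1,
    T.GC = desc$terminal_gc
  )
  storage.mode(mat) <- "double"
  rownames(mat) <- desc$sequence
  mat
}

#' Fit nearest-neighbor parameters by error-weighted least squares
#'
#' Solves the weighted linear least-squares problem that minimizes
#' `|| W (chi - S eps) ||^2` where `S` is the design matrix of
#' [build_design_matrix()], `chi` the observed signed binding quantities,
#' and `W` a diagonal matrix of reciprocal standard errors (or the
#' identity for `weighting = "unweighted"`). Term standard errors come
#' from the weighted normal-equations covariance; p-values are two-sided
#' t-tests on `n - 12` degrees of freedom.
#'
#' Observations with a reported standard error of zero cannot be weighted
#' by a reciprocal; their SE is clamped to `se_floor` (default: the
#' smallest positive SE in the data) with a warning.
#'
#' When the per-observation SEs are themselves estimated from a small
#' number of replicates they are noisy, and the classical weighted
#' covariance (which treats the weights as known) understates the term
#' errors. `se_type = "hc3"` instead reports heteroscedasticity-robust
#' (HC3 sandwich) standard errors, which stay calibrated under
#' mis-estimated weights.
#'
#' @param data A data frame with columns `sequence`, `value` (signed
#'   binding observable) and, for reciprocal-SE weighting, `se`.
#' @param weighting `"reciprocal_se"` (default) or `"unweighted"`.
#' @param observable One of `"enthalpy"`, `"entropy"`, `"free_energy"`;
#'   recorded on the result, units kcal/mol for enthalpy and free energy,
#'   cal/K/mol for entropy.
#' @param se_floor Positive clamp for zero standard errors, or `NULL` to
#'   use the smallest positive SE present.
#' @param se_type `"classical"` (weighted normal-equations covariance) or
#'   `"hc3"` (sandwich covariance robust to mis-estimated weights).
#' @return An object of class `nn_fit`: a list with `terms` (tibble of
#'   `term`, `estimate`, `se`, `p_value`, `wc_hbonds`), the term
#'   covariance matrix `cov`, `observable`, `weighting`, `n`, `sigma`
#'   (residual standard deviation of the weighted problem), `r_squared`
#'   and `residuals`. Supports [tidy()], [glance()] and [autoplot()].
#' @export
nn_fit <- function(data,
                   weighting = c("reciprocal_se", "unweighted"),
                   observable = c("enthalpy", "entropy", "free_energy"),
                   se_floor = NULL,
                   se_type = c("classical", "hc3")) {
  weighting <- match.arg(weighting)
  observable <- match.arg(observable)
  se_type <- match.arg(se_type)
  stopifnot(is.data.frame(data), all(c("sequence", "value") %in% names(data)))

  S <- build_design_matrix(data$sequence)
  y <- as.numeric(data$value)
  n <- length(y)
  p <- ncol(S)
  if (n < p) {
    stop("need at least ", p, " observations to identify ", p,
         " nearest-neighbor terms; got ", n, call. = FALSE)
  }

  if (weighting == "reciprocal_se") {
    if (!"se" %in% names(data)) {
      stop("reciprocal_se weighting requires an `se` column", call. = FALSE)
    }
    se <- as.numeric(data$se)
    if (any(se < 0)) stop("standard errors must be non-negative", call. = FALSE)
    if (any(se == 0)) {
      floor_val <- se_floor %||% {
        pos <- se[se > 0]
        if (length(pos) == 0) {
          stop("all standard errors are zero; supply `se_floor` or use ",
               "unweighted fitting", call. = FALSE)
        }
        min(pos)
      }
      warning(sum(se == 0), " observation(s) with zero standard error ",
              "clamped to SE floor ", format(floor_val), call. = FALSE)
      se[se == 0] <- floor_val
    }
    w <- 1 / se
  } else {
    w <- rep(1, n)
  }

  Sw <- S * w
  yw <- y * w
  sv <- svd(Sw)
  tol <- 1e-10 * sv$d[1]
  if (any(sv$d < tol)) {
    null_dirs <- sv$v[, sv$d < tol, drop = FALSE]
    implicated <- colnames(S)[apply(abs(null_dirs) > 1e-6, 1, any)]
    stop("design matrix is rank-deficient after weighting; ",
         "unidentifiable term(s): ", paste(implicated, collapse = ", "),
         call. = FALSE)
  }

  fit <- stats::lm.wfit(S, y, w = w^2)
  est <- fit$coefficients
  res_w <- yw - Sw %*% est
  df_resid <- n - p
  sigma2 <- sum(res_w^2) / df_resid
  XtX_inv <- sv$v %*% (t(sv$v) / sv$d^2)
  if (se_type == "classical") {
    cov_mat <- sigma2 * XtX_inv
  } else {
    # HC3 sandwich on the weighted problem, with leverage correction
    raw_res <- y - as.numeric(S %*% est)
    H <- (S %*% XtX_inv) * (S * w^2)
    lev <- pmin(rowSums(H), 1 - 1e-8)
    meat <- crossprod(S * (w^2 * raw_res / (1 - lev)))
    cov_mat <- XtX_inv %*% meat %*% XtX_inv
  }
  dimnames(cov_mat) <- list(colnames(S), colnames(S))
  se_est <- sqrt(diag(cov_mat))
  tval <- est / se_est
  pval <- 2 * stats::pt(abs(tval), df = df_resid, lower.tail = FALSE)

  classes <- stack_classes()
  terms <- tibble::tibble(
    term = colnames(S),
    estimate = unname(est),
    se = unname(se_est),
    p_value = unname(pval),
    wc_hbonds = classes$wc_hbonds[match(colnames(S), classes$stack)]
  )

  raw_resid <- y - as.numeric(S %*% est)
  tss <- sum((yw - stats::weighted.mean(y, w^2) * w)^2)
  r2 <- if (tss > 0) 1 - sum(res_w^2) / tss else NA_real_

  structure(
    list(
      terms = terms, cov = cov_mat, observable = observable,
      weighting = weighting, se_type = se_type, n = n, sigma = sqrt(sigma2),
      df_residual = df_resid, r_squared = r2,
      residuals = tibble::tibble(sequence = data$sequence,
                                 observed = y,
                                 fitted = y - raw_resid,
                                 residual = raw_resid),
      calibrated = FALSE
    ),
    class = "nn_fit"
  )
}

#' @export
print.nn_fit <- function(x, ...) {
  cat("Nearest-neighbor fit (", x$observable, ", ", x$weighting, ")\n",
      sep = "")
  cat("  n = ", x$n, ", residual df = ", x$df_residual,
      ", weighted R^2 = ", format(x$r_squared, digits = 4), "\n", sep = "")
  if (isTRUE(x$calibrated)) cat("  (linearly calibrated parameters)\n")
  print(x$terms, n = nrow(x$terms))
  invisible(x)
}

#' Assemble a nearest-neighbor parameter set by hand
#'
#' Builds the same object as [nn_fit()] from known term values, e.g. a
#' published parameter table or a ground truth for simulation. Values are
#' signed; pass magnitudes through `-` at the call site if needed.
#'
#' @param estimates Named numeric vector with names AA ... CG, Init, T.GC
#'   (any order; all 12 required).
#' @param se Named numeric vector of standard errors (defaults to 0).
#' @param observable As in [nn_fit()].
#' @return An `nn_fit` object with no residual diagnostics.
#' @export
nn_params <- function(estimates, se = NULL,
                      observable = c("enthalpy", "entropy", "free_energy")) {
  observable <- match.arg(observable)
  if (!all(.term_order %in% names(estimates))) {
    stop("`estimates` must name all 12 terms: ",
         paste(.term_order, collapse = ", "), call. = FALSE)
  }
  estimates <- estimates[.term_order]
  se <- if (is.null(se)) stats::setNames(rep(0, 12), .term_order)
        else se[.term_order]
  if (any(is.na(se)) || any(se < 0)) {
    stop("standard errors must be non-negative for all 12 terms",
         call. = FALSE)
  }
  classes <- stack_classes()
  terms <- tibble::tibble(
    term = .term_order,
    estimate = unname(estimates),
    se = unname(se),
    p_value = NA_real_,
    wc_hbonds = classes$wc_hbonds[match(.term_order, classes$stack)]
  )
  structure(
    list(terms = terms, cov = diag(unname(se)^2,
                                   nrow = 12, ncol = 12) |>
           `dimnames<-`(list(.term_order, .term_order)),
         observable = observable, weighting = NA_character_,
         n = NA_integer_, sigma = NA_real_, df_residual = NA_integer_,
         r_squared = NA_real_, residuals = NULL, calibrated = FALSE),
    class = "nn_fit"
  )
}

#' Predict binding observables from sequence
#'
#' Evaluates the nearest-neighbor sum for each sequence and propagates a
#' standard error assuming independent term errors (the full covariance in
#' `params$cov` is used when available, which reduces to the independence
#' formula for diagonal covariance). For entropy parameter sets the C2
#' symmetry decrement is applied to self-complementary duplexes (see
#' [symmetry_correction()]).
#'
#' @param data A data frame with a `sequence` column, or a character
#'   vector.
#' @param params An `nn_fit` object ([nn_fit()] / [nn_params()] /
#'   [pna_nn_params()]).
#' @return The input as a tibble with added columns `.pred` (signed) and
#'   `.pred_se`.
#' @export
#' @examples
#' nn_predict("CGATCG", pna_nn_params())
nn_predict <- function(data, params) {
  stopifnot(inherits(params, "nn_fit"))
  tbl <- if (is.data.frame(data)) tibble::as_tibble(data)
         else tibble::tibble(sequence = data)
  S <- build_design_matrix(tbl$sequence)
  est <- stats::setNames(params$terms$estimate, params$terms$term)[colnames(S)]
  pred <- as.numeric(S %*% est)
  cov_mat <- params$cov[colnames(S), colnames(S)]
  pred_se <- unname(sqrt(rowSums((S %*% cov_mat) * S)))

  if (params$observable == "entropy") {
    sc <- is_self_complementary(tbl$sequence)
    pred <- symmetry_correction(pred, sc)
  }
  tbl$.pred <- pred
  tbl$.pred_se <- pred_se
  tbl
}

#' C2-symmetry entropy decrement for self-complementary duplexes
#'
#' A self-complementary homoduplex has C2 rotational symmetry, which
#' reduces the degrees of freedom lost on binding; its binding entropy is
#' made 1.4 cal/K/mol more negative. Applied only to entropies, never to
#' the enthalpy fit.
#'
#' @param entropy Signed binding entropy (cal/K/mol), vectorized.
#' @param self_complementary Logical, recycled against `entropy`.
#' @param decrement Size of the decrement (cal/K/mol).
#' @return Corrected entropies.
#' @export
#' @examples
#' symmetry_correction(-35, TRUE) # -36.4
symmetry_correction <- function(entropy, self_complementary,
                                decrement = 1.4) {
  entropy - ifelse(self_complementary, decrement, 0)
}

#' Mean stack magnitude by Watson-Crick hydrogen-bond count
#'
#' Groups the 10 stack terms by the number of canonical Watson-Crick
#' hydrogen bonds their base pairs share (4, 5 or 6) and reports the
#' unweighted arithmetic mean of the term magnitudes, with the standard
#' deviation across members.
#'
#' @param params An `nn_fit` object.
#' @return A tibble with columns `wc_hbonds`, `n_stacks`,
#'   `mean_magnitude`, `sd_magnitude`.
#' @export
#' @examples
#' stack_group_means(pna_nn_params())
stack_group_means <- function(params) {
  stopifnot(inherits(params, "nn_fit"))
  params$terms |>
    dplyr::filter(!is.na(.data$wc_hbonds)) |>
    dplyr::group_by(.data$wc_hbonds) |>
    dplyr::summarise(
      n_stacks = dplyr::n(),
      mean_magnitude = mean(abs(.data$estimate)),
      sd_magnitude = stats::sd(abs(.data$estimate)),
      .groups = "drop"
    )
}
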