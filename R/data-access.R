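# Packaged reference tables: published PNA homoduplex thermodynamics used
# as fixtures and worked examples. All CSVs live under inst/extdata and
# print magnitudes (-dH etc.); accessors convert to the package's signed
# convention where appropriate.

.extdata <- function(file) {
  system.file("extdata", file, package = "pnatherm", mustWork = TRUE)
}

#' Published nearest-neighbor enthalpy parameters for PNA homoduplexes
#'
#' The reference parameter set: 10 stack terms, the helix-initiation term
#' and the terminal-GC term, fitted to MM-GBSA binding enthalpies of 49
#' PNA homoduplexes by error-weighted least squares. Stored as magnitudes
#' (-dH, kcal/mol) in the packaged CSV; returned signed. Note that, unlike
#' DNA and RNA, PNA has a stabilizing (negative) helix-initiation
#' enthalpy, attributed to its uncharged backbone.
#'
#' @return An `nn_fit` parameter object (enthalpy, kcal/mol, signed).
#' @export
#' @examples
#' pna_nn_params()$terms
pna_nn_params <- function() {
  tbl <- readr::read_csv(.extdata("pna_nn_enthalpy_params.csv"),
                         show_col_types = FALSE)
  nn_params(
    estimates = stats::setNames(-tbl$neg_dH_kcal, tbl$term),
    se = stats::setNames(tbl$se, tbl$term),
    observable = "enthalpy"
  )
}

#' Experimental melting thermodynamics for 10 PNA homoduplexes
#'
#' Standard binding free energies, enthalpies and entropies at 298 K for
#' 10 PNA homoduplexes from UV thermal melting: three hexamers measured
#' in triplicate and seven literature values. Magnitude columns as
#' printed in the source tables; an SE of 0 marks literature entries
#' reported without a standard error.
#'
#' @param signed If `TRUE` (default), convert magnitudes to signed binding
#'   quantities (negative = stabilizing).
#' @return A tibble with columns `sequence`, `source`, `dG`/`dH` (kcal/mol)
#'   and `dS` (cal/K/mol) with their SEs, signed or as magnitudes.
#' @export
pna_melting_data <- function(signed = TRUE) {
  tbl <- readr::read_csv(.extdata("pna_melting_thermo.csv"),
                         show_col_types = FALSE)
  sgn <- if (signed) -1 else 1
  tibble::tibble(
    sequence = tbl$sequence,
    source = tbl$source,
    dG = sgn * tbl$neg_dG_kcal, dG_se = tbl$dG_se,
    dH = sgn * tbl$neg_dH_kcal, dH_se = tbl$dH_se,
    dS = sgn * tbl$neg_dS_cal, dS_se = tbl$dS_se
  )
}

#' Benchmark table: experimental vs nearest-neighbor predicted enthalpies
#'
#' The 10-sequence benchmark set with experimental binding-enthalpy
#' magnitudes and the reference nearest-neighbor predictions. Two rows are
#' flagged `anomalous`: their printed predictions cannot be reproduced
#' from the published parameter table under any stack-equivalence
#' convention and are excluded from exact regression checks.
#'
#' @return A tibble with columns `sequence`, `neg_dH_exp_kcal`, `exp_se`,
#'   `neg_dH_nn_kcal`, `anomalous`.
#' @export
pna_benchmark_data <- function() {
  readr::read_csv(.extdata("pna_benchmark_enthalpies.csv"),
                  show_col_types = FALSE,
                  col_types = readr::cols(anomalous = readr::col_logical()))
}
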