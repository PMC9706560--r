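# File-format dialects and the end-to-end pipeline.
#
# Boundary convention: CSV files mirror the published tables and store
# MAGNITUDES in columns named `neg_*`; everything in memory is signed
# (negative = stabilizing). Readers fail fast with row context; writers
# round-trip exactly with the readers.

#' Read a binding-observation table
#'
#' Expects columns `sequence` plus either a magnitude column (`neg_dH_kcal`,
#' `neg_dS_cal` or `neg_dG_kcal`, matching `observable`) or a signed
#' `value` column, and `se`. Magnitudes are negated to the signed
#' convention on read. Duplicate sequences, non-numeric values and
#' negative SEs are errors naming the offending rows.
#'
#' @param path CSV path.
#' @param observable `"enthalpy"`, `"entropy"` or `"free_energy"`.
#' @return A tibble `sequence`, `value` (signed), `se` ready for
#'   [nn_fit()].
#' @export
read_observations <- function(path,
                              observable = c("enthalpy", "entropy",
                                             "free_energy")) {
  observable <- match.arg(observable)
  tbl <- readr::read_csv(path, show_col_types = FALSE, comment = "#")
  if (nrow(tbl) == 0) stop("no observations in '", path, "'", call. = FALSE)
  if (!"sequence" %in% names(tbl)) {
    stop("'", path, "' lacks a `sequence` column", call. = FALSE)
  }
  mag_col <- c(enthalpy = "neg_dH_kcal", entropy = "neg_dS_cal",
               free_energy = "neg_dG_kcal")[[observable]]
  value <- if (mag_col %in% names(tbl)) {
    -as.numeric(tbl[[mag_col]])
  } else if ("value" %in% names(tbl)) {
    as.numeric(tbl$value)
  } else {
    stop("'", path, "' needs a `", mag_col, "` (magnitude) or `value` ",
         "(signed) column", call. = FALSE)
  }
  if (!"se" %in% names(tbl)) {
    stop("'", path, "' lacks an `se` column", call. = FALSE)
  }
  se <- as.numeric(tbl$se)
  bad <- which(!is.finite(value) | !is.finite(se) | se < 0)
  if (length(bad) > 0) {
    stop("non-numeric or invalid value/se at data row(s) ",
         paste(bad, collapse = ", "), " of '", path, "'", call. = FALSE)
  }
  dup <- tbl$sequence[duplicated(tbl$sequence)]
  if (length(dup) > 0) {
    stop("duplicate sequence(s) in '", path, "': ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  tibble::tibble(sequence = validate_sequence(tbl$sequence),
                 value = value, se = se)
}

#' Write / read nearest-neighbor parameter sets as CSV
#'
#' The file layout mirrors the published parameter tables: columns
#' `term`, `value` (magnitude of the signed estimate), `se`, `p_value`.
#'
#' @param params An `nn_fit` object.
#' @param path CSV path.
#' @return `write_params`: the path, invisibly. `read_params`: an
#'   `nn_fit` parameter object.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "nn_fit"))
  readr::write_csv(
    tibble::tibble(term = params$terms$term,
                   value = abs(params$terms$estimate),
                   se = params$terms$se,
                   p_value = params$terms$p_value),
    path
  )
  invisible(path)
}

#' @rdname write_params
#' @param observable Observable kind recorded on the result.
#' @export
read_params <- function(path, observable = c("enthalpy", "entropy",
                                             "free_energy")) {
  observable <- match.arg(observable)
  tbl <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("term", "value", "se")
  if (!all(need %in% names(tbl))) {
    stop("'", path, "' must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  params <- nn_params(stats::setNames(-abs(tbl$value), tbl$term),
                      stats::setNames(tbl$se, tbl$term),
                      observable = observable)
  if ("p_value" %in% names(tbl)) {
    params$terms$p_value <- tbl$p_value[match(params$terms$term, tbl$term)]
  }
  params
}

#' Read a melting curve with sidecar metadata
#'
#' CSV with columns `temperature_K`, `absorbance`; header comment lines
#' of the form `# ct: 1e-6` and `# self_complementary: true` carry the
#' per-file metadata.
#'
#' @param path CSV path.
#' @return A tibble with columns `temperature_K`, `absorbance` and
#'   attributes `ct` and `self_complementary` (NA if absent).
#' @export
read_melting_curve <- function(path) {
  header <- readLines(path, n = 20, warn = FALSE)
  meta_line <- function(key) {
    hit <- grep(paste0("^#\\s*", key, "\\s*:"), header, value = TRUE)
    if (length(hit) == 0) return(NA_character_)
    trimws(sub(paste0("^#\\s*", key, "\\s*:"), "", hit[1]))
  }
  tbl <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  if (!all(c("temperature_K", "absorbance") %in% names(tbl))) {
    stop("'", path, "' must have columns temperature_K, absorbance",
         call. = FALSE)
  }
  attr(tbl, "ct") <- as.numeric(meta_line("ct"))
  attr(tbl, "self_complementary") <-
    isTRUE(tolower(meta_line("self_complementary")) %in%
             c("true", "yes", "1"))
  tbl
}

#' Read a hydrogen-bond count series
#'
#' Wide CSV: a `time_ns` column and one column per base pair named
#' `<class>_<type>_<id>` (e.g. `terminal_AT_1`, `internal_GC_3`), holding
#' bonded-bond counts. Pivoted to the long layout the statistics
#' functions consume; `max_bonds` is inferred from the pair type (AT 2,
#' GC 3).
#'
#' @param path CSV path.
#' @return A long tibble: `time_ns`, `pair`, `pair_class`, `pair_type`,
#'   `n_bonded`, `max_bonds`.
#' @export
read_hbond_series <- function(path) {
  tbl <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  if (!"time_ns" %in% names(tbl)) {
    stop("'", path, "' lacks a `time_ns` column", call. = FALSE)
  }
  long <- tidyr::pivot_longer(tbl, -"time_ns", names_to = "pair",
                              values_to = "n_bonded")
  parts <- stringr::str_match(long$pair,
                              "^(terminal|internal)_(AT|GC)_([0-9]+)$")
  if (any(is.na(parts[, 1]))) {
    bad <- unique(long$pair[is.na(parts[, 1])])
    stop("pair column name(s) not of the form <class>_<type>_<id>: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  long$pair_class <- parts[, 2]
  long$pair_type <- parts[, 3]
  long$max_bonds <- ifelse(long$pair_type == "GC", 3L, 2L)
  .check_series(long)
  long
}

#' Run the full enthalpy pipeline
#'
#' End-to-end orchestration: fit (or accept) a nearest-neighbor parameter
#' set, predict the benchmark sequences, and benchmark predicted against
#' experimental values. The prediction table mirrors the published
#' benchmark layout (sequence, experimental and predicted magnitudes,
#' absolute and percent difference).
#'
#' @param observations Tibble `sequence`, `value`, `se` used for fitting,
#'   or `NULL` when `params` is supplied.
#' @param benchmark Tibble with `sequence` and experimental signed
#'   `value` (and optionally `se`) to predict and score.
#' @param params Optional pre-fitted `nn_fit`; when `NULL`, fitted from
#'   `observations`.
#' @param weighting Passed to [nn_fit()].
#' @return A list of class `nn_pipeline`: `params` (`nn_fit`),
#'   `predictions` (tibble `sequence`, `neg_dH_exp`, `neg_dH_pred`,
#'   `abs_diff`, `pct_diff`), `benchmark` (`nn_benchmark`).
#' @export
run_pipeline <- function(observations = NULL, benchmark, params = NULL,
                         weighting = "reciprocal_se") {
  if (is.null(params)) {
    if (is.null(observations)) {
      stop("supply either `observations` or `params`", call. = FALSE)
    }
    params <- tryCatch(
      nn_fit(observations, weighting = weighting),
      error = function(e) stop("fit stage failed: ", conditionMessage(e),
                               call. = FALSE)
    )
  }
  if (nrow(benchmark) == 0 || !"sequence" %in% names(benchmark)) {
    stop("predict stage failed: `benchmark` needs a non-empty `sequence` ",
         "column", call. = FALSE)
  }
  pred <- nn_predict(benchmark, params)
  predictions <- tibble::tibble(
    sequence = pred$sequence,
    neg_dH_exp = abs(pred$value),
    neg_dH_pred = abs(pred$.pred),
    abs_diff = abs(pred$value - pred$.pred),
    pct_diff = 100 * abs(pred$value - pred$.pred) / abs(pred$value)
  )
  bench <- benchmark_predictions(
    tibble::tibble(ref = abs(pred$value), est = abs(pred$.pred)),
    ref, est
  )
  structure(list(params = params, predictions = predictions,
                 benchmark = bench),
            class = "nn_pipeline")
}

#' @export
print.nn_pipeline <- function(x, ...) {
  cat("Nearest-neighbor enthalpy pipeline\n\n")
  print(x$params)
  cat("\nPredictions (magnitudes, kcal/mol):\n")
  print(x$predictions, n = nrow(x$predictions))
  cat("\n")
  print(x$benchmark)
  invisible(x)
}
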