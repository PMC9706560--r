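# Watson-Crick hydrogen-bond detection and melting-event statistics.
#
# A base pair is "fully bonded" at a frame when all of its canonical
# Watson-Crick hydrogen bonds (2 for A.T, 3 for G.C) are formed. A
# melting event is a maximal uninterrupted run of frames with at least
# one bond broken; its duration is the run length times the frame
# spacing. Events touching either end of the series are counted but
# flagged as censored.

#' Geometric hydrogen-bond criterion for a donor/hydrogen/acceptor triplet
#'
#' A bond is formed when the donor-acceptor distance is less than
#' `dist_cutoff` AND the hydrogen-donor-acceptor angle is less than
#' `angle_cutoff` (both strict, matching the usual trajectory-analysis
#' convention). By default the angle is measured at the donor, between
#' the donor->hydrogen and donor->acceptor vectors; `angle_at =
#' "hydrogen"` instead measures the angle at the hydrogen between
#' hydrogen->donor and hydrogen->acceptor.
#'
#' @param donor,hydrogen,acceptor Numeric length-3 coordinates in nm, or
#'   n-by-3 matrices for vectorized evaluation.
#' @param dist_cutoff Donor-acceptor distance cutoff, nm.
#' @param angle_cutoff Angle cutoff, degrees.
#' @param angle_at `"donor"` (default) or `"hydrogen"`.
#' @return Logical (vector): bond formed?
#' @export
#' @examples
#' detect_hbond(c(0, 0, 0), c(0.1, 0, 0), c(0.3, 0, 0))
detect_hbond <- function(donor, hydrogen, acceptor,
                         dist_cutoff = 0.325, angle_cutoff = 30,
                         angle_at = c("donor", "hydrogen")) {
  angle_at <- match.arg(angle_at)
  as_mat <- function(x) if (is.matrix(x)) x else matrix(x, nrow = 1)
  d <- as_mat(donor); h <- as_mat(hydrogen); a <- as_mat(acceptor)
  stopifnot(ncol(d) == 3, ncol(h) == 3, ncol(a) == 3)
  if (any(!is.finite(d)) || any(!is.finite(h)) || any(!is.finite(a))) {
    stop("coordinates must be finite", call. = FALSE)
  }
  if (angle_at == "donor") {
    v1 <- h - d
    v2 <- a - d
  } else {
    v1 <- d - h
    v2 <- a - h
  }
  n1 <- sqrt(rowSums(v1^2))
  n2 <- sqrt(rowSums(v2^2))
  if (any(n1 == 0) || any(n2 == 0)) {
    stop("coincident atoms: hydrogen-bond angle undefined", call. = FALSE)
  }
  dist_da <- sqrt(rowSums((a - d)^2))
  cosang <- pmin(1, pmax(-1, rowSums(v1 * v2) / (n1 * n2)))
  angle <- acos(cosang) * 180 / pi
  dist_da < dist_cutoff & angle < angle_cutoff
}

.check_series <- function(data) {
  need <- c("time_ns", "pair", "n_bonded", "max_bonds")
  stopifnot(is.data.frame(data))
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0) {
    stop("hydrogen-bond series must have columns ",
         paste(need, collapse = ", "), "; missing: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(data$n_bonded < 0 | data$n_bonded > data$max_bonds)) {
    stop("n_bonded must lie in [0, max_bonds]", call. = FALSE)
  }
  invisible(data)
}

#' Mean normalized bonded fraction per base-pair group, as a percentage
#'
#' For each base pair, the bonded count is normalized by its maximum
#' (2 for A.T, 3 for G.C) and averaged over frames; the per-pair means
#' are then averaged within groups (by default pair class x pair type,
#' plus any extra grouping columns present, e.g. run or sequence length)
#' and reported as mean +/- SD in percent.
#'
#' @param data A long hydrogen-bond series: columns `time_ns`, `pair`,
#'   `n_bonded`, `max_bonds`, and optionally `pair_class`
#'   (terminal/internal), `pair_type` (AT/GC) and further grouping
#'   columns named in `groups`.
#' @param groups Character vector of grouping columns (those present are
#'   used).
#' @return A tibble with the grouping columns, `n_pairs`, `mean_percent`,
#'   `sd_percent`.
#' @export
percent_bonded <- function(data, groups = c("pair_class", "pair_type")) {
  .check_series(data)
  groups <- intersect(groups, names(data))
  per_pair <- data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(groups, "pair")))) |>
    dplyr::summarise(
      frac = mean(.data$n_bonded / .data$max_bonds),
      .groups = "drop"
    )
  per_pair |>
    dplyr::group_by(dplyr::across(dplyr::all_of(groups))) |>
    dplyr::summarise(
      n_pairs = dplyr::n(),
      mean_percent = 100 * mean(.data$frac),
      sd_percent = 100 * stats::sd(.data$frac),
      .groups = "drop"
    )
}

#' Segment a hydrogen-bond series into melting events
#'
#' Per base pair, finds the maximal runs of consecutive frames with at
#' least one Watson-Crick bond broken (`n_bonded < max_bonds`). Duration
#' is the run length times the frame spacing `dt` (a single broken frame
#' is an event of duration `dt`). Runs touching the first or last frame
#' are included and flagged `censored`.
#'
#' @param data A long hydrogen-bond series (see [percent_bonded()]);
#'   frame times must be uniformly spaced per pair.
#' @return A tibble with one row per event: `pair`, carried-over pair
#'   metadata, `start_ns`, `duration_ns`, `n_frames`, `censored`.
#' @export
find_melting_events <- function(data) {
  .check_series(data)
  meta_cols <- intersect(c("pair_class", "pair_type", "run"), names(data))
  data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c("pair", meta_cols)))) |>
    dplyr::arrange(.data$time_ns, .by_group = TRUE) |>
    dplyr::group_modify(function(df, key) {
      tt <- df$time_ns
      if (length(tt) < 2) {
        stop("need at least 2 frames per pair", call. = FALSE)
      }
      dts <- diff(tt)
      if (max(dts) - min(dts) > 1e-9 * max(dts)) {
        stop("frame times must be uniformly spaced", call. = FALSE)
      }
      dt <- dts[1]
      broken <- df$n_bonded < df$max_bonds
      r <- rle(broken)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      keep <- which(r$values)
      tibble::tibble(
        start_ns = tt[starts[keep]],
        duration_ns = r$lengths[keep] * dt,
        n_frames = r$lengths[keep],
        censored = starts[keep] == 1 | ends[keep] == length(tt)
      )
    }) |>
    dplyr::ungroup()
}

#' Occurrence rate of melting events of at least a given duration
#'
#' For each duration threshold tau, the number of events with
#' `duration_ns >= tau` divided by the total observation time: the rate,
#' per nanosecond, at which a melting event of at least that duration
#' initiates. Non-increasing in tau by construction.
#'
#' @param events An event table from [find_melting_events()] (optionally
#'   pre-filtered, e.g. by pair class).
#' @param total_time_ns Total observed time, ns.
#' @param thresholds Numeric vector of duration thresholds, ns.
#' @return A tibble with columns `threshold_ns`, `n_events`,
#'   `occurrences_per_ns`.
#' @export
event_occurrence_curve <- function(events, total_time_ns, thresholds) {
  stopifnot(total_time_ns > 0)
  durations <- if (nrow(events) > 0) events$duration_ns else numeric(0)
  tibble::tibble(
    threshold_ns = thresholds,
    n_events = vapply(thresholds,
                      function(tau) sum(durations >= tau), integer(1)),
    occurrences_per_ns = n_events / total_time_ns
  )
}

#' Total melting time per base pair (and run)
#'
#' Aggregates all individual melting events: the summed event duration
#' per pair (within any `run` column present). Together with the fully
#' bonded time this partitions the series duration exactly.
#'
#' @param events An event table from [find_melting_events()].
#' @return A tibble with `pair` (and `run` if present), carried metadata,
#'   and `total_melting_ns`.
#' @export
total_melting_time <- function(events) {
  keys <- intersect(c("run", "pair", "pair_class", "pair_type"),
                    names(events))
  events |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(total_melting_ns = sum(.data$duration_ns),
                     .groups = "drop")
}
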