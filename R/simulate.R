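# Synthetic-data generators emulating every input the analysis consumes:
# sequence panels, replicated binding-observable tables (standing in for
# end-point simulation output), two-state melting curves, and per-frame
# Watson-Crick bond-count series from two-state Markov chains.
#
# Defaults mirror the study conditions of the reference data set: 49
# homoduplexes of lengths 6-18, triplicate observations, enthalpies on
# the 50-160 kcal/mol magnitude scale set by the packaged parameter
# fixture.

.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate random PNA sequences
#'
#' Draws sequences of uniformly random length within `length_range`, with
#' per-position G/C probability `gc_fraction`. A fraction
#' `self_complementary_fraction` of the panel is built as a random
#' even-length half followed by its antiparallel complement, which is
#' self-complementary by construction (odd lengths are rounded up to the
#' next even length for those).
#'
#' @param n Number of sequences.
#' @param length_range Integer `c(min, max)` sequence lengths.
#' @param gc_fraction Probability that a position is G or C.
#' @param self_complementary_fraction Fraction built self-complementary.
#' @param seed Optional integer seed; the caller's RNG state is restored.
#' @return A tibble with columns `label`, `sequence`,
#'   `self_complementary`.
#' @export
#' @examples
#' generate_sequences(3, seed = 1)
generate_sequences <- function(n, length_range = c(6, 18),
                               gc_fraction = 0.5,
                               self_complementary_fraction = 0,
                               seed = NULL) {
  stopifnot(n >= 1, length(length_range) == 2,
            length_range[1] >= 2, length_range[1] <= length_range[2],
            gc_fraction >= 0, gc_fraction <= 1,
            self_complementary_fraction >= 0,
            self_complementary_fraction <= 1)
  .with_seed(seed, {
    p <- c(A = (1 - gc_fraction) / 2, T = (1 - gc_fraction) / 2,
           G = gc_fraction / 2, C = gc_fraction / 2)
    lens <- sample(seq(length_range[1], length_range[2]), n, replace = TRUE)
    selfc <- seq_len(n) <= round(n * self_complementary_fraction)
    seqs <- vapply(seq_len(n), function(i) {
      L <- lens[i]
      if (selfc[i]) {
        half <- ceiling(L / 2)
        left <- paste(sample(names(p), half, replace = TRUE, prob = p),
                      collapse = "")
        paste0(left, antiparallel_complement(left))
      } else {
        paste(sample(names(p), L, replace = TRUE, prob = p), collapse = "")
      }
    }, character(1))
    tibble::tibble(label = sprintf("syn%03d", seq_len(n)),
                   sequence = seqs,
                   self_complementary = is_self_complementary(seqs))
  })
}

#' Generate replicated binding observations from a ground-truth model
#'
#' For each sequence, draws `n_replicates` values from a normal
#' distribution centred on the nearest-neighbor prediction under `truth`,
#' with standard deviation `noise_sd` (optionally scaled by
#' `length / 10` when `length_scaled_noise = TRUE`, mimicking the larger
#' spread of longer duplexes). The reported observation is the replicate
#' mean; its `se` is the standard error of that mean (0 when
#' `noise_sd = 0`).
#'
#' @param sequences Character vector or data frame with a `sequence`
#'   column.
#' @param truth An `nn_fit` parameter object (e.g. [pna_nn_params()]).
#' @param noise_sd Replicate noise standard deviation, kcal/mol.
#' @param n_replicates Replicates per sequence.
#' @param length_scaled_noise Scale the noise by `length / 10`.
#' @param seed Optional integer seed.
#' @return A tibble with columns `sequence`, `value` (signed), `se`,
#'   `n_replicates` -- the observation-table layout [nn_fit()] consumes.
#' @export
generate_observations <- function(sequences, truth, noise_sd = 1,
                                  n_replicates = 3,
                                  length_scaled_noise = FALSE,
                                  seed = NULL) {
  stopifnot(inherits(truth, "nn_fit"), noise_sd >= 0, n_replicates >= 1)
  seqs <- if (is.data.frame(sequences)) sequences$sequence else sequences
  pred <- nn_predict(seqs, truth)
  .with_seed(seed, {
    sds <- if (length_scaled_noise) noise_sd * nchar(seqs) / 10
           else rep(noise_sd, length(seqs))
    reps <- purrr::map2(pred$.pred, sds, function(mu, s) {
      stats::rnorm(n_replicates, mean = mu, sd = s)
    })
    tibble::tibble(
      sequence = seqs,
      value = vapply(reps, mean, numeric(1)),
      se = if (noise_sd == 0) 0 else
        vapply(reps, function(r) stats::sd(r) / sqrt(length(r)), numeric(1)),
      n_replicates = n_replicates
    )
  })
}

#' Generate a two-state UV melting curve
#'
#' Solves the two-state equilibrium for the duplexed fraction alpha(T)
#' from `K(T) = exp(dS/R - dH/(R T))` and the concentration relation of
#' [equilibrium_constant()], then maps alpha to absorbance via
#' `A = A_ss - (A_ss - A_ds) * alpha`, optionally adding linear
#' single-strand/duplex baselines and Gaussian noise. For a
#' self-complementary duplex the analytic melting point is
#' `Tm = dH / (dS / 1000 + (R / 1000) * ln(C_T))` (dH kcal/mol, dS
#' cal/K/mol).
#'
#' @param dH Binding enthalpy, kcal/mol (must be negative for a melting
#'   transition).
#' @param dS Binding entropy, cal/K/mol.
#' @param ct Total strand concentration, mol/L.
#' @param self_complementary Logical.
#' @param temperatures Temperature grid, K (default 2 K steps around the
#'   physiological-to-melting range).
#' @param noise_sd Gaussian absorbance noise SD.
#' @param a_ds,a_ss Duplex and single-strand baseline absorbances at the
#'   first grid temperature.
#' @param baseline_slopes Length-2 numeric: linear slopes (per K) of the
#'   duplex and single-strand baselines (0 disables).
#' @param seed Optional integer seed.
#' @return A tibble with columns `temperature_K`, `absorbance`, `alpha`
#'   (the generating duplexed fraction, for round-trip checks).
#' @export
generate_melting_curve <- function(dH, dS, ct, self_complementary,
                                   temperatures = seq(278, 368, by = 2),
                                   noise_sd = 0, a_ds = 0.5, a_ss = 1.0,
                                   baseline_slopes = c(0, 0),
                                   seed = NULL) {
  stopifnot(ct > 0, length(baseline_slopes) == 2)
  if (dH >= 0) {
    stop("`dH` must be negative (stabilizing) for a melting transition",
         call. = FALSE)
  }
  R <- .R_cal / 1000  # kcal/(K mol)
  K <- exp(dS / 1000 / R - dH / (R * temperatures))
  # invert K(alpha): self-complementary 2 K ct (1-a)^2 = a;
  # non-self-complementary K ct (1-a)^2 = 2 a. Both are
  # q (1-a)^2 = a with q = 2 K ct or K ct / 2.
  q <- if (self_complementary) 2 * K * ct else K * ct / 2
  alpha <- (2 * q + 1 - sqrt(4 * q + 1)) / (2 * q)
  if (max(alpha) < 0.5 || min(alpha) > 0.5) {
    warning("no melting transition (alpha = 0.5 crossing) inside the ",
            "temperature grid", call. = FALSE)
  }
  .with_seed(seed, {
    dT <- temperatures - temperatures[1]
    base_ds <- a_ds + baseline_slopes[1] * dT
    base_ss <- a_ss + baseline_slopes[2] * dT
    absorb <- base_ss - (base_ss - base_ds) * alpha +
      stats::rnorm(length(temperatures), sd = noise_sd)
    tibble::tibble(temperature_K = temperatures, absorbance = absorb,
                   alpha = alpha)
  })
}

#' Generate a Watson-Crick hydrogen-bond count series
#'
#' Each individual bond of each base pair is an independent two-state
#' discrete-time Markov chain: per frame, a formed bond breaks with
#' probability `1 - exp(-open_rate * dt)` and a broken bond reforms with
#' probability `1 - exp(-close_rate * dt)`. Chains start in the bonded
#' state. The per-pair record is the number of formed bonds per frame;
#' the stationary bonded fraction per bond is
#' `close_rate / (open_rate + close_rate)` (for rates in 1/ns and small
#' `dt`).
#'
#' @param pairs A data frame describing the base pairs: columns `pair`
#'   (id), `pair_type` (`"AT"` -> 2 bonds, `"GC"` -> 3), `pair_class`
#'   (`"terminal"`/`"internal"`), and optionally per-pair `open_rate`,
#'   `close_rate` overriding the defaults.
#' @param open_rate,close_rate Default opening/closing rates, 1/ns.
#' @param duration_ns Series length, ns.
#' @param dt Frame spacing, ns.
#' @param seed Optional integer seed.
#' @return A long tibble: `time_ns`, `pair`, `pair_type`, `pair_class`,
#'   `n_bonded`, `max_bonds` -- the layout the hydrogen-bond statistics
#'   consume.
#' @export
generate_hbond_series <- function(pairs, open_rate = 1, close_rate = 9,
                                  duration_ns = 100, dt = 0.01,
                                  seed = NULL) {
  stopifnot(is.data.frame(pairs),
            all(c("pair", "pair_type", "pair_class") %in% names(pairs)),
            all(pairs$pair_type %in% c("AT", "GC")),
            open_rate >= 0, close_rate >= 0, dt > 0, duration_ns > dt)
  n_frames <- floor(duration_ns / dt)
  times <- (seq_len(n_frames) - 1) * dt
  .with_seed(seed, {
    out <- purrr::pmap(pairs, function(pair, pair_type, pair_class, ...) {
      extra <- list(...)
      ko <- extra$open_rate %||% open_rate
      kc <- extra$close_rate %||% close_rate
      p_open <- 1 - exp(-ko * dt)
      p_close <- 1 - exp(-kc * dt)
      max_bonds <- if (pair_type == "GC") 3L else 2L
      counts <- integer(n_frames)
      state <- rep(TRUE, max_bonds)
      u <- matrix(stats::runif(n_frames * max_bonds), nrow = n_frames)
      for (f in seq_len(n_frames)) {
        flip_open <- state & (u[f, ] < p_open)
        flip_close <- !state & (u[f, ] < p_close)
        state <- (state & !flip_open) | flip_close
        counts[f] <- sum(state)
      }
      tibble::tibble(time_ns = times, pair = pair,
                     pair_type = pair_type, pair_class = pair_class,
                     n_bonded = counts, max_bonds = max_bonds)
    })
    dplyr::bind_rows(out)
  })
}
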