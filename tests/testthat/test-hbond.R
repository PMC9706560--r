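test_that("geometric hydrogen-bond criterion applies strict cutoffs", {
  d <- c(0, 0, 0)
  # distance 0.30 nm, angle 0
  expect_true(detect_hbond(d, c(0.1, 0, 0), c(0.30, 0, 0)))
  # distance violation at 0.33 nm
  expect_false(detect_hbond(d, c(0.1, 0, 0), c(0.33, 0, 0)))
  # boundary cases are excluded (strict inequalities)
  expect_false(detect_hbond(d, c(0.1, 0, 0), c(0.325, 0, 0)))
  ang <- 30 * pi / 180
  expect_false(detect_hbond(d, c(0.1, 0, 0),
                            0.3 * c(cos(ang), sin(ang), 0)))
  # 10 degrees off-axis passes
  a10 <- 10 * pi / 180
  expect_true(detect_hbond(d, c(0.1, 0, 0), 0.3 * c(cos(a10), sin(a10), 0)))
  expect_error(detect_hbond(d, d, c(0.3, 0, 0)), "coincident")
})

test_that("hydrogen-bond detection is rigid-motion invariant", {
  set.seed(41)
  donor <- c(0, 0, 0)
  hydrogen <- c(0.10, 0.02, 0)
  acceptor <- c(0.29, 0.05, 0.03)
  base <- detect_hbond(donor, hydrogen, acceptor)
  for (i in 1:10) {
    Q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
    shift <- stats::rnorm(3)
    tr <- function(x) as.numeric(Q %*% x + shift)
    expect_equal(detect_hbond(tr(donor), tr(hydrogen), tr(acceptor)), base)
  }
})

test_that("angle can be measured at the donor or at the hydrogen", {
  donor <- c(0, 0, 0)
  hydrogen <- c(0.1, 0.05, 0)
  acceptor <- c(0.3, 0, 0)
  at_d <- detect_hbond(donor, hydrogen, acceptor, angle_at = "donor")
  at_h <- detect_hbond(donor, hydrogen, acceptor, angle_at = "hydrogen")
  # donor-angle ~27 deg passes; hydrogen-angle (between H->D and H->A) is
  # obtuse-complementary and fails
  expect_true(at_d)
  expect_false(at_h)
})

test_that("bonded percentages summarise normalized counts by group", {
  full <- tibble::tibble(
    time_ns = rep(c(0, 0.1, 0.2, 0.3), 2),
    pair = rep(1:2, each = 4),
    pair_class = rep(c("terminal", "internal"), each = 4),
    pair_type = "GC",
    n_bonded = 3L, max_bonds = 3L
  )
  pb <- percent_bonded(full)
  expect_equal(pb$mean_percent, c(100, 100))
  expect_equal(pb$sd_percent, c(NA_real_, NA_real_))

  alt <- tibble::tibble(time_ns = c(0, 0.1, 0.2, 0.3), pair = 1,
                        n_bonded = c(3L, 0L, 3L, 0L), max_bonds = 3L)
  expect_equal(percent_bonded(alt, groups = character(0))$mean_percent, 50)

  bad <- dplyr::mutate(alt, n_bonded = 4L)
  expect_error(percent_bonded(bad), "max_bonds")
})

test_that("melting events are maximal broken runs with exact durations", {
  mk <- function(counts, dt = 0.1) {
    tibble::tibble(time_ns = (seq_along(counts) - 1) * dt, pair = 1,
                   n_bonded = counts, max_bonds = 3L)
  }
  expect_equal(nrow(find_melting_events(mk(c(3L, 3L, 3L)))), 0)

  ev <- find_melting_events(mk(c(3L, 2L, 2L, 3L, 0L, 3L)))
  expect_equal(ev$duration_ns, c(0.2, 0.1))
  expect_equal(ev$start_ns, c(0.1, 0.4))
  expect_equal(ev$censored, c(FALSE, FALSE))

  ev2 <- find_melting_events(mk(rep(0L, 5)))
  expect_equal(nrow(ev2), 1)
  expect_equal(ev2$duration_ns, 0.5)
  expect_true(ev2$censored)

  expect_error(find_melting_events(mk(c(3L, 2L, 3L, 2L), dt = 0.1)[c(1, 2, 4), ]),
               "uniformly spaced")
})

test_that("occurrence curves count events above a duration threshold", {
  none <- tibble::tibble(pair = integer(0), start_ns = numeric(0),
                         duration_ns = numeric(0), censored = logical(0))
  oc0 <- event_occurrence_curve(none, 100, c(0.1, 1))
  expect_equal(oc0$occurrences_per_ns, c(0, 0))

  ev <- tibble::tibble(duration_ns = rep(1, 10))
  oc <- event_occurrence_curve(ev, 100, c(0.5, 2))
  expect_equal(oc$occurrences_per_ns, c(0.1, 0))

  # monotone non-increasing in the threshold, on random event sets
  set.seed(51)
  ev2 <- tibble::tibble(duration_ns = stats::rexp(200, 2))
  oc2 <- event_occurrence_curve(ev2, 50, seq(0, 3, by = 0.1))
  expect_true(all(diff(oc2$occurrences_per_ns) <= 0))
})

test_that("melted and bonded time partition the series exactly", {
  pairs <- tibble::tibble(pair = 1:4,
                          pair_type = c("AT", "GC", "AT", "GC"),
                          pair_class = rep(c("terminal", "internal"), 2))
  hs <- generate_hbond_series(pairs, open_rate = 3, close_rate = 6,
                              duration_ns = 10, dt = 0.01, seed = 61)
  ev <- find_melting_events(hs)
  melt <- total_melting_time(ev)
  dt <- 0.01
  for (p in pairs$pair) {
    sub <- hs[hs$pair == p, ]
    bonded_frames <- sum(sub$n_bonded == sub$max_bonds)
    melted <- melt$total_melting_ns[melt$pair == p]
    if (length(melted) == 0) melted <- 0
    expect_equal(melted + bonded_frames * dt, nrow(sub) * dt)
  }
  # and summed event durations reproduce a direct frame count
  expect_equal(sum(ev$duration_ns),
               sum(hs$n_bonded < hs$max_bonds) * dt)
})

test_that("Markov series reproduce stationary fractions and dwell times", {
  open_rate <- 2
  close_rate <- 8
  dt <- 0.01
  p_open <- 1 - exp(-open_rate * dt)
  p_close <- 1 - exp(-close_rate * dt)
  pairs <- tibble::tibble(pair = 1:6, pair_type = "GC",
                          pair_class = "internal")

  n_runs <- 60
  frac <- numeric(n_runs)
  mean_dur <- numeric(n_runs)
  for (r in seq_len(n_runs)) {
    hs <- generate_hbond_series(pairs, open_rate, close_rate,
                                duration_ns = 25, dt = dt, seed = 7000 + r)
    frac[r] <- mean(hs$n_bonded / hs$max_bonds)
    ev <- find_melting_events(hs)
    mean_dur[r] <- mean(ev$duration_ns[!ev$censored])
  }

  stat_frac <- p_close / (p_open + p_close)
  expect_lt(abs(mean(frac) - stat_frac),
            3 * stats::sd(frac) / sqrt(n_runs))

  expected_dur <- analytic_event_frames(3, p_open, p_close) * dt
  expect_lt(abs(mean(mean_dur) - expected_dur),
            3 * stats::sd(mean_dur) / sqrt(n_runs))
})

test_that("faster terminal opening raises terminal variability", {
  pairs <- tibble::tibble(
    pair = 1:12,
    pair_type = rep(c("AT", "GC"), 6),
    pair_class = rep(c("terminal", "internal"), each = 6),
    open_rate = rep(c(4, 0.5), each = 6),
    close_rate = 8
  )
  hs <- generate_hbond_series(pairs, duration_ns = 40, dt = 0.02, seed = 71)
  pb <- percent_bonded(hs, groups = "pair_class")
  term <- pb[pb$pair_class == "terminal", ]
  intl <- pb[pb$pair_class == "internal", ]
  expect_gt(term$sd_percent, intl$sd_percent)
  expect_lt(term$mean_percent, intl$mean_percent)
})
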