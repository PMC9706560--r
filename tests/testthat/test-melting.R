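test_that("min-max normalization produces a unit-range alpha curve", {
  curve <- tibble::tibble(temperature_K = c(300, 310, 320, 330),
                          absorbance = c(0.50, 0.60, 0.70, 0.80))
  a <- normalize_to_alpha(curve)
  expect_equal(a$alpha, c(1, 2 / 3, 1 / 3, 0))

  flat <- tibble::tibble(temperature_K = c(300, 310, 320, 330),
                         absorbance = rep(0.5, 4))
  expect_error(normalize_to_alpha(flat), "flat")

  bad <- tibble::tibble(temperature_K = c(300, 310, 305, 330),
                        absorbance = 1:4)
  expect_error(normalize_to_alpha(bad), "strictly increasing")
})

test_that("linear baseline subtraction removes sloping baselines", {
  mc <- generate_melting_curve(-58.78, -151.42, 1e-6, TRUE,
                               temperatures = seq(260, 400, 2),
                               baseline_slopes = c(0.002, 0.002))
  a_raw <- normalize_to_alpha(mc)
  a_corr <- normalize_to_alpha(mc, baseline = "linear")
  err_raw <- max(abs(a_raw$alpha - mc$alpha))
  err_corr <- max(abs(a_corr$alpha - mc$alpha))
  expect_lt(err_corr, err_raw)
})

test_that("melting temperature interpolates the first downward 0.5 crossing", {
  a <- tibble::tibble(temperature_K = c(300, 310, 320, 330),
                      alpha = c(1, 0.75, 0.25, 0))
  expect_equal(melting_temperature(a), 315)

  exact <- tibble::tibble(temperature_K = c(300, 310, 320),
                          alpha = c(1, 0.5, 0))
  expect_equal(melting_temperature(exact), 310)

  high <- tibble::tibble(temperature_K = c(300, 310, 320),
                         alpha = c(0.9, 0.8, 0.7))
  expect_error(melting_temperature(high), "never crosses")
})

test_that("two-state equilibrium constants follow the concentration relations", {
  expect_equal(equilibrium_constant(0.5, 1e-6, TRUE), 1e6)
  expect_equal(equilibrium_constant(0.5, 1e-6, FALSE), 4e6)
  expect_error(equilibrium_constant(1, 1e-6, TRUE), "diverges")
  expect_error(equilibrium_constant(0, 1e-6, TRUE), "diverges")
  expect_error(equilibrium_constant(0.5, 0, TRUE), "positive")
})

test_that("van't Hoff analysis inverts noise-free synthetic curves", {
  dH <- -58.78
  dS <- -151.42
  ct <- 1e-6
  mc <- generate_melting_curve(dH, dS, ct, TRUE,
                               temperatures = seq(250, 380, 2))
  vh <- vant_hoff_fit(normalize_to_alpha(mc), ct, TRUE)
  expect_lt(abs(vh$dH - dH) / abs(dH), 0.001)
  expect_lt(abs(vh$dS - dS) / abs(dS), 0.001)
  expect_equal(vh$dG, gibbs_energy(vh$dH, vh$dS, 298), tolerance = 1e-9)

  # different windows inside (0, 1) give the same answer on clean data
  vh2 <- vant_hoff_fit(normalize_to_alpha(mc), ct, TRUE,
                       alpha_window = c(0.3, 0.7))
  expect_lt(abs(vh2$dH - dH) / abs(dH), 0.001)

  expect_error(
    vant_hoff_fit(tibble::tibble(temperature_K = c(300, 330),
                                 alpha = c(0.6, 0.4)), ct, TRUE),
    "at least 3"
  )
})

test_that("bootstrap errors keep noisy melting fits calibrated", {
  # normalization error is invisible to the regression SEs, so calibrated
  # inference on noisy curves needs the whole-pipeline bootstrap; at
  # 3-sigma its empirical coverage sits near 94%, so the check uses a
  # bound with binomial headroom
  dH <- -58.78
  dS <- -151.42
  ct <- 1e-6
  n_rep <- 100
  ok <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    mc <- generate_melting_curve(dH, dS, ct, TRUE,
                                 temperatures = seq(278, 368, 2),
                                 noise_sd = 0.005, seed = 2000 + r)
    f <- melt_fit(mc, ct, TRUE, baseline = "linear",
                  se_method = "bootstrap", n_boot = 60, seed = r)
    ok[r] <- abs(f$dH - dH) <= 3 * f$dH_se
  }
  expect_gte(mean(ok), 0.88)
})

test_that("melting temperature rises with strand concentration", {
  tms <- vapply(c(1e-7, 1e-6, 1e-5, 1e-4), function(ct) {
    mc <- generate_melting_curve(-58.78, -151.42, ct, TRUE,
                                 temperatures = seq(270, 390, 2))
    melting_temperature(normalize_to_alpha(mc))
  }, numeric(1))
  expect_true(all(diff(tms) > 0))
})

test_that("Gibbs energy combines enthalpy and entropy with unit conversion", {
  expect_equal(round(gibbs_energy(-58.78, -151.42, 298), 2), -13.66)
  expect_equal(gibbs_energy(-10, 0, 298), -10)
  expect_equal(gibbs_energy(0, -10, 300), 3)
  expect_error(gibbs_energy(-10, -10, 0), "> 0")

  # linear in T with slope -dS/1000
  Ts <- c(280, 300, 320)
  g <- gibbs_energy(-50, -120, Ts)
  expect_equal(diff(g) / diff(Ts), rep(0.12, 2))
})
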