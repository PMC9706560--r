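test_that("design matrix has the documented layout", {
  S <- build_design_matrix(c("CGATCG", "AACGTT", "GTAGATCACT"))
  expect_equal(colnames(S),
               c(stack_classes()$stack, "Init", "T.GC"))
  expect_equal(unname(S["CGATCG", c("CG", "GA", "AT", "Init", "T.GC")]),
               c(2, 2, 1, 1, 1))
  expect_equal(unname(S["AACGTT", c("AA", "AC", "CG", "Init", "T.GC")]),
               c(2, 2, 1, 1, 0))
  # one A.T terminus zeroes the terminal-GC indicator
  expect_equal(unname(S["GTAGATCACT", "T.GC"]), 0)
  expect_true(all(S[, "Init"] == 1))
  expect_equal(unname(rowSums(S[, stack_classes()$stack])),
               nchar(rownames(S)) - 1)
})

test_that("noise-free fits recover the generating parameters exactly", {
  truth <- pna_nn_params()
  seqs <- generate_sequences(30, seed = 101)
  obs <- generate_observations(seqs, truth, noise_sd = 0, seed = 101)

  fit_u <- nn_fit(dplyr::mutate(obs, se = 1), weighting = "unweighted")
  expect_equal(fit_u$terms$estimate, truth$terms$estimate,
               tolerance = 1e-8)

  # equal SEs: reciprocal-SE weighting must match the unweighted fit
  fit_w <- nn_fit(dplyr::mutate(obs, se = 2.5), weighting = "reciprocal_se")
  expect_equal(fit_w$terms$estimate, fit_u$terms$estimate, tolerance = 1e-10)
})

test_that("production solver matches the explicit normal-equations oracle", {
  truth <- pna_nn_params()
  set.seed(202)
  for (rep in 1:5) {
    seqs <- generate_sequences(sample(14:20, 1))
    obs <- generate_observations(seqs, truth, noise_sd = 1.5)
    obs$se <- stats::runif(nrow(obs), 0.2, 2)
    fit <- nn_fit(obs, weighting = "reciprocal_se")

    S <- build_design_matrix(obs$sequence)
    oracle <- brute_force_wls(S, obs$value, obs$se)
    expect_equal(fit$terms$estimate, unname(oracle$estimate),
                 tolerance = 1e-10)
    expect_equal(fit$terms$se, unname(oracle$se), tolerance = 1e-10)
  }
})

test_that("rank-deficient designs are rejected with the offending term named", {
  truth <- pna_nn_params()
  # a panel of identical sequences cannot identify anything
  obs <- generate_observations(rep("CGATCG", 15), truth, noise_sd = 0.5,
                               seed = 3)
  obs$se <- 1
  expect_error(nn_fit(obs), "rank-deficient")
})

test_that("zero standard errors are clamped to a floor with a warning", {
  truth <- pna_nn_params()
  seqs <- generate_sequences(20, seed = 44)
  obs <- generate_observations(seqs, truth, noise_sd = 0.5, seed = 44)
  obs$se <- stats::runif(nrow(obs), 0.5, 1)
  obs$se[c(1, 5)] <- 0
  expect_warning(fit <- nn_fit(obs), "zero standard error")
  expect_true(all(is.finite(fit$terms$estimate)))

  # explicit floor is honored: equivalent to substituting it by hand
  fit2 <- suppressWarnings(nn_fit(obs, se_floor = 0.25))
  obs3 <- obs
  obs3$se[obs3$se == 0] <- 0.25
  fit3 <- nn_fit(obs3)
  expect_equal(fit2$terms$estimate, fit3$terms$estimate, tolerance = 1e-12)
})

test_that("predictions are strand-symmetric and additive in stacks", {
  params <- pna_nn_params()
  set.seed(55)
  for (i in 1:10) {
    s <- random_seq(sample(4:16, 1))
    p1 <- nn_predict(s, params)$.pred
    p2 <- nn_predict(antiparallel_complement(s), params)$.pred
    expect_equal(p1, p2)

    # dropping the C-terminal base removes exactly one stack term plus
    # any change in the terminal-GC contribution
    trimmed <- substr(s, 1, nchar(s) - 1)
    p3 <- nn_predict(trimmed, params)$.pred
    est <- setNames(params$terms$estimate, params$terms$term)
    lost_stack <- canonical_stack(substr(s, nchar(s) - 1, nchar(s)))
    dB <- describe_duplex(s)$terminal_gc - describe_duplex(trimmed)$terminal_gc
    expect_equal(p1 - p3, unname(est[lost_stack]) + dB * est["T.GC"],
                 ignore_attr = TRUE)
  }
})

test_that("prediction SEs propagate the term covariance", {
  params <- pna_nn_params()
  pred <- nn_predict("CGATCG", params)
  # diagonal covariance: sqrt(sum(j_i^2 se_i^2))
  se <- setNames(params$terms$se, params$terms$term)
  manual <- sqrt((2 * se["CG"])^2 + (2 * se["GA"])^2 + se["AT"]^2 +
                   se["Init"]^2 + se["T.GC"]^2)
  expect_equal(pred$.pred_se, unname(manual))
})

test_that("the symmetry decrement applies only to self-complementary entropies", {
  expect_equal(symmetry_correction(-35, TRUE), -36.4)
  expect_equal(symmetry_correction(-35, FALSE), -35)
  expect_equal(symmetry_correction(0, TRUE), -1.4)

  # entropy parameter sets trigger it inside nn_predict; enthalpy sets do not
  est <- setNames(rep(-10, 12), c(stack_classes()$stack, "Init", "T.GC"))
  p_ent <- nn_params(est, observable = "entropy")
  p_enth <- nn_params(est, observable = "enthalpy")
  base <- sum(c(2, 2, 1) * -10) + -10 + -10  # CGATCG: 5 stacks + init + T.GC
  expect_equal(nn_predict("CGATCG", p_enth)$.pred, base)
  expect_equal(nn_predict("CGATCG", p_ent)$.pred, base - 1.4)
  expect_equal(nn_predict("GTAGATCACT", p_ent)$.pred,
               9 * -10 + -10)  # not self-complementary, B = 0
})

test_that("reference stack magnitudes grow with the hydrogen-bond count", {
  gm <- stack_group_means(pna_nn_params())
  expect_equal(gm$wc_hbonds, c(4L, 5L, 6L))
  expect_true(all(diff(gm$mean_magnitude) > 0))

  # constant parameter set: every class mean equals the constant
  est <- setNames(rep(-7, 12), c(stack_classes()$stack, "Init", "T.GC"))
  gm2 <- stack_group_means(nn_params(est))
  expect_equal(gm2$mean_magnitude, rep(7, 3))
})

test_that("Monte-Carlo parameter recovery stays within reported errors", {
  truth <- pna_nn_params()
  seqs <- generate_sequences(49, seed = 777)
  n_rep <- 50
  ok <- logical(n_rep)
  # triplicate SEs carry only 2 df, so the classical weighted covariance
  # (weights treated as known) understates the term errors; robust
  # (sandwich) SEs stay calibrated
  for (r in seq_len(n_rep)) {
    obs <- generate_observations(seqs, truth, noise_sd = 1, seed = 1000 + r)
    fit <- suppressWarnings(nn_fit(obs, se_type = "hc3"))
    ok[r] <- all(abs(fit$terms$estimate - truth$terms$estimate) <=
                   3 * fit$terms$se)
  }
  expect_gte(mean(ok), 0.9)
})
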