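test_that("structure-factor extraction inverts the composite model exactly", {
  gen <- make_sans(sans_truth_horse(), rel_err_peak = 0)
  expect_warning(
    S_exp <- extract_structure_factor(gen$curve, 1e-4, 2.2, 1.0,
                                      list(type = "sphere", R = 23.6)),
    "truncating")
  expect_true(attr(S_exp, "truncated"))
  expect_equal(S_exp$I, gen$S_true[seq_along(S_exp$q)], tolerance = 1e-10)
})

test_that("extraction with no power law and unit form factor is the identity", {
  q <- seq(0.02, 0.15, by = 0.01)
  cv <- sas_curve(q, 1 + sin(q * 30) * 0.2, rep(0.01, length(q)))
  S <- extract_structure_factor(cv, 0, 2, 1, function(q) rep(1, length(q)))
  expect_equal(S$I, cv$I)
  expect_equal(S$sigma, cv$sigma)
})

test_that("extracted peak position is stable to one grid step under 3% multiplicative noise", {
  truth <- sans_truth_horse()
  gen0 <- make_sans(truth, rel_err_peak = 0)     # noiseless forward model
  q <- gen0$curve$q
  miss <- 0L
  for (s in 1:50) {
    set.seed(s)
    I_obs <- gen0$curve$I * (1 + 0.03 * rnorm(length(q)))
    cv <- sas_curve(q, I_obs, 0.03 * gen0$curve$I)
    S_exp <- suppressWarnings(
      extract_structure_factor(cv, truth$I1, truth$d, truth$I2,
                               list(type = "sphere", R = 23.6)))
    n <- length(S_exp$q)
    q_true <- peak_position(list(q = S_exp$q, I = gen0$S_true[1:n]))
    q_obs <- peak_position(S_exp)
    step <- q_true * (log(0.45) - log(0.01)) / 119   # local log-grid spacing
    if (abs(q_obs - q_true) > step) miss <- miss + 1L
  }
  expect_lte(miss, 5)    # peak within one grid step in >= 90% of draws
})

test_that("volume fraction converts to concentration through upsilon = 0.75", {
  expect_equal(concentration_from_phi(0.256), 341, tolerance = 2e-3)
  expect_equal(concentration_from_phi(0), 0)
  expect_equal(concentration_from_phi(0.249), 332, tolerance = 1e-3)
  expect_error(concentration_from_phi(1.2), "phi")
})

test_that("noiseless joint fit is self-consistent to high precision", {
  gen <- make_sans(sans_truth_horse(), rel_err_peak = 0)
  f <- fit_sans(gen$curve, list(type = "sphere", R = 23.6), n_starts = 1)
  expect_rel(f$par$contact_potential, 2.5, 1e-4)
  expect_rel(f$par$phi, 0.256, 1e-4)
  expect_rel(f$par$R_eff, 23.6, 1e-4)
  expect_rel(f$par$I1, 1e-4, 1e-3)
  expect_rel(f$par$d, 2.2, 1e-4)
  expect_rel(f$par$I2, 1.0, 1e-4)
  expect_true(f$converged)
  # the c-phi invariant holds exactly
  expect_equal(f$c_mg_ml, f$par$phi / 0.75 * 1000, tolerance = 1e-9)
  # Z consistent with the forward charge computation
  expect_equal(f$Z, charge_from_contact_potential(f$yukawa), tolerance = 1e-12)
})

test_that("fixing R_eff keeps the remaining parameters identifiable", {
  gen <- make_sans(sans_truth_horse(), rel_err_peak = 0.03, seed = 2)
  f <- fit_sans(gen$curve, list(type = "sphere", R = 23.6), fix_reff = 22.6,
                n_starts = 2)
  expect_true(f$cond_ok)
  expect_equal(f$par$R_eff, 22.6)
  expect_identical(f$se$R_eff, 0)
})

test_that("kinetic series: constant truth averages correctly, zero drift when noiseless", {
  truth <- sans_truth_horse()
  truth$yukawa <- yukawa_interaction(3.3, 22.6, 0.249, ionic_strength = 0.15)
  times <- c(0.5, 4, 8, 12, 16, 20)
  kin0 <- make_sans_kinetic(truth, times, rel_err_peak = 0, seed = 1)
  ks0 <- fit_kinetic_series(kin0$curves, times, list(type = "sphere", R = 23.6),
                            fix_reff = 22.6, n_starts = 1)
  expect_false(ks0$drift)
  expect_rel(ks0$c_mean, 332, 1e-3)
  kin <- make_sans_kinetic(truth, times, rel_err_peak = 0.03, seed = 5)
  ks <- fit_kinetic_series(kin$curves, times, list(type = "sphere", R = 23.6),
                           fix_reff = 22.6, n_starts = 2)
  expect_rel(ks$c_mean, 332, 0.03)
})

test_that("kinetic series flags a lysis-like step change", {
  truth <- sans_truth_horse()
  truth$yukawa <- yukawa_interaction(1.3, 22.6, 0.26, ionic_strength = 0.15)
  times <- c(1, 5, 9, 13, 17, 21, 25)
  kin <- make_sans_kinetic(truth, times, step = list(t = 13, dphi = -0.05),
                           rel_err_peak = 0.02, seed = 11)
  ks <- fit_kinetic_series(kin$curves, times, list(type = "sphere", R = 23.6),
                           fix_reff = 22.6, n_starts = 2)
  expect_true(ks$drift)
  expect_lt(ks$drift_p, 0.05)
})
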