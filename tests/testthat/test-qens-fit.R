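test_that("noiseless spectra are refitted to their generating parameters", {
  gen <- make_qens(qens_truth_horse(), counts_peak = 0)
  for (i in c(3, 7)) {
    f <- fit_spectrum(gen$spectra[[i]])
    expect_true(f$converged)
    expect_rel(f$par$A0, gen$truth$A0[i], 1e-5)
    expect_rel(f$par$Gamma_G, gen$truth$Gamma_G[i], 1e-5)
    expect_rel(f$par$Gamma_I, 2.84, 1e-4)
  }
})

test_that("label-swapped initialization converges to the same solution", {
  gen <- make_qens(qens_truth_horse(), q = c(1.21), seed = 5)
  f1 <- fit_spectrum(gen$spectra[[1]],
                     init = list(Gamma_G = 0.3, Gamma_I = 5))
  f2 <- fit_spectrum(gen$spectra[[1]],
                     init = list(Gamma_G = 5, Gamma_I = 0.3))
  expect_rel(f1$par$Gamma_G, f2$par$Gamma_G, 1e-4)
  expect_rel(f1$par$Gamma_I, f2$par$Gamma_I, 1e-3)
  expect_rel(f1$par$A0, f2$par$A0, 1e-4)
})

test_that("per-q narrow widths are unbiased at counting-statistics noise", {
  pulls <- c()
  for (s in 1:10) {
    gen <- make_qens(qens_truth_horse(), q = c(0.86, 1.39, 1.92), seed = 200 + s)
    for (i in seq_along(gen$spectra)) {
      f <- fit_spectrum(gen$spectra[[i]])
      if (f$converged && is.finite(f$se$Gamma_G) && f$se$Gamma_G > 0)
        pulls <- c(pulls, (f$par$Gamma_G - gen$truth$Gamma_G[i]) / f$se$Gamma_G)
    }
  }
  expect_lt(abs(mean(pulls)), 1 / sqrt(length(pulls)) * 3 + 0.3)
})

test_that("dispersion fit inverts the width-to-diffusion conversion exactly", {
  q <- seq(0.34, 1.92, length.out = 8)
  hbar <- physical_constants()$hbar_ueV_s
  G <- hbar * 1.0e9 * q^2                      # D = 10.0e-8 cm^2/s in A^2/s
  expect_equal(G[8], 2.43, tolerance = 2e-3)   # width at the last detector
  d <- fit_global_diffusion(G, q, T_K = 288)
  expect_equal(d$D_eff, 10.0e-8, tolerance = 1e-12)
  expect_equal(d$D_trans, 10.0e-8 / 1.27, tolerance = 1e-12)
  z <- fit_global_diffusion(rep(0, 5), q[1:5])
  expect_equal(z$D_eff, 0)
  expect_error(fit_global_diffusion(G[1:3], q[1:3]), "at least 4")
})

test_that("correlation times reproduce the measured-state table", {
  expect_equal(correlation_time(2.84)$tau_ps, 232, tolerance = 2e-3)
  expect_equal(correlation_time(2.40)$tau_ps, 274, tolerance = 1.5e-3)
  hbar_ps <- physical_constants()$hbar_ueV_ps
  expect_equal(correlation_time(hbar_ps)$tau_ps, 1)
  # tau * <Gamma> = hbar to machine precision
  ct <- correlation_time(c(2.1, 2.9, 3.3), q = c(0.5, 1, 1.5),
                         se = c(0.5, 0.4, 0.6))
  expect_equal(ct$tau_ps * ct$Gamma_mean, hbar_ps, tolerance = 1e-14)
})

test_that("flat internal widths show no significant q^2 slope in most runs", {
  flat <- 0L; n <- 20L
  for (s in seq_len(n)) {
    gen <- make_qens(qens_truth_horse(), seed = 400 + s)
    fits <- fit_spectra(gen$spectra)
    ok <- vapply(fits, `[[`, TRUE, "converged")
    gi <- vapply(fits[ok], function(f) f$par$Gamma_I, numeric(1))
    gise <- vapply(fits[ok], function(f) f$se$Gamma_I, numeric(1))
    qv <- vapply(fits[ok], `[[`, numeric(1), "q")
    ct <- correlation_time(gi, qv, gise)
    if (is.finite(ct$flat_p_value) && ct$flat_p_value > 0.05) flat <- flat + 1L
  }
  expect_gte(flat / n, 0.9)
})

test_that("Gaussian-confinement EISF is recovered exactly without noise", {
  q <- seq(0.34, 1.92, length.out = 10)
  A0 <- (1 - 0.5) * exp(-1.3 * q^2) + 0.5
  f <- fit_eisf(A0, q)
  expect_equal(f$x2, 1.3, tolerance = 1e-8)
  expect_equal(f$p_immobile, 0.5, tolerance = 1e-8)
})

test_that("fully immobile sample gives a flat EISF and a degeneracy flag", {
  q <- seq(0.34, 1.92, length.out = 10)
  gen <- make_qens(list(D_eff = 10e-8, x2 = 1.3, p = 1, Gamma_I = 2.84),
                   q = q, counts_peak = 0)
  expect_equal(gen$truth$A0, rep(1, 10))
  # spectra are then single Lorentzians of the global width
  sp <- gen$spectra[[4]]
  one <- convolve_resolution(
    function(x) rbcneutron:::.lorentzian(x, gen$truth$Gamma_G[4]),
    list(omega = sp$res_omega, R = sp$res), sp$omega)
  ratio <- sp$S / max(sp$S)
  expect_equal(ratio, (one + 0.005 * max(one)) / max(one + 0.005 * max(one)),
               tolerance = 1e-10)
  f <- fit_eisf(rep(1, 10) + rnorm(10, 0, 1e-4), q, se = rep(1e-4, 10))
  expect_true(f$degenerate)
})

test_that("EISF interval coverage lies in a sane band at the measured uncertainties", {
  q <- seq(0.34, 1.92, length.out = 10)
  A0_true <- (1 - 0.5) * exp(-1.3 * q^2) + 0.5
  se <- rep(0.04, length(q))        # magnitude of the reported EISF errors
  set.seed(99)
  hits <- 0L; n <- 100L
  for (s in seq_len(n)) {
    f <- fit_eisf(pmin(pmax(A0_true + rnorm(length(q), 0, se), 0), 1), q, se)
    if (is.finite(f$x2_se) && abs(f$x2 - 1.3) <= f$x2_se) hits <- hits + 1L
  }
  expect_gte(hits / n, 0.60)
  expect_lte(hits / n, 0.99)
})

test_that("sphere-confinement radii convert to Gaussian mean-square displacements", {
  expect_equal(sphere_to_gaussian_msd(2.8), 1.568)   # reported as 1.6 A^2
  expect_equal(sphere_to_gaussian_msd(0), 0)
  expect_equal(sphere_to_gaussian_msd(sqrt(5)), 1)
})
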