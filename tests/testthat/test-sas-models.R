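test_that("correlation-peak model hits I0 at q* and I0*alpha at high q", {
  set.seed(11)
  for (i in 1:25) {
    p <- butler_params(I0 = runif(1, 0.1, 10), alpha = runif(1, 0.02, 0.95),
                       xi = runif(1, 1e4, 1e5), d = runif(1, 1, 4.5))
    qstar <- 2 * pi / p$xi
    expect_equal(butler_empirical(qstar, p), p$I0, tolerance = 1e-12)
    # the plateau is approached as x^-d: evaluate where x^-d ~ 1e-9
    expect_equal(butler_empirical(qstar * 10^(9 / p$d), p), p$I0 * p$alpha,
                 tolerance = 1e-6)
  }
})

test_that("correlation peak of the 4.61 um state sits at 1.363e-4 1/A", {
  p <- butler_params(1, 0.1, 4.61e4, 3.6)
  qs <- seq(2e-5, 1e-3, length.out = 200001)
  qmax <- qs[which.max(butler_empirical(qs, p))]
  # brute-force argmax against the analytic peak position 2 pi / xi
  expect_equal(qmax, 1.363e-4, tolerance = 2e-3)
  expect_equal(2 * pi / 4.61e4, 1.3630e-4, tolerance = 1e-4)
})

test_that("correlation-peak model rejects invalid parameters", {
  expect_error(butler_params(1, 1.0, 4.6e4, 3.6), "alpha")
  expect_error(butler_params(1, 0, 4.6e4, 3.6), "alpha")
  expect_error(butler_params(1, -0.2, 4.6e4, 3.6), "alpha")
  p <- butler_params(1, 0.1, 4.6e4, 3.6)
  expect_error(butler_empirical(c(-1e-4, 1e-4), p), "positive")
  expect_error(butler_empirical(0, p), "positive")
})

test_that("Guinier-Porod crossover is continuous in value and slope", {
  p <- guinier_porod_params(scale = 3, Rg = 1.15e4, d = 3.9)
  expect_equal(guinier_porod(0, p), 3)
  eps <- p$q1 * 1e-9
  expect_equal(guinier_porod(p$q1 - eps, p) / guinier_porod(p$q1 + eps, p), 1,
               tolerance = 1e-6)
  # numerical derivative continuity at machine-tolerance scale
  h <- p$q1 * 1e-6
  d_lo <- (guinier_porod(p$q1 - h, p) - guinier_porod(p$q1 - 2 * h, p)) / h
  d_hi <- (guinier_porod(p$q1 + 2 * h, p) - guinier_porod(p$q1 + h, p)) / h
  expect_equal(d_lo / d_hi, 1, tolerance = 1e-3)
  # crossover where the smooth branches meet with common slope: locate
  # numerically the q at which the log-log slopes of the two branches agree
  guin <- function(q) p$scale * exp(-q^2 * p$Rg^2 / 3)
  slope_g <- function(q) -2 * q^2 * p$Rg^2 / 3       # dlogI/dlogq
  q1_num <- uniroot(function(q) slope_g(q) + p$d, c(1e-6, 1e-2), tol = 1e-12)$root
  expect_equal(p$q1, q1_num, tolerance = 1e-9)
  expect_equal(p$q1, sqrt(3 * 3.9 / 2) / 1.15e4, tolerance = 1e-12)
  expect_error(guinier_porod_params(1, -1, 3), "Rg")
  expect_error(guinier_porod_params(1, 1, 0), "d")
})

test_that("sphere form factor matches its analytic anchors and a quadrature oracle", {
  expect_equal(sphere_form_factor(0, 23.6), 1)
  # first zero of the Rayleigh amplitude: tan(x) = x
  x0 <- uniroot(function(x) tan(x) - x, c(pi + 0.1, 1.5 * pi))$root
  expect_lt(sphere_form_factor(x0 / 23.6, 23.6), 1e-12)
  # independent oracle: numerical integration of the scattering amplitude of
  # a uniform sphere, A(q) = int_0^R 4 pi r^2 sinc(qr) dr / V
  R <- 23.6; q <- 0.05
  amp <- integrate(function(r) 4 * pi * r^2 * sin(q * r) / (q * r),
                   0, R, rel.tol = 1e-12)$value / (4 / 3 * pi * R^3)
  expect_equal(sphere_form_factor(q, R), amp^2, tolerance = 1e-10)
  # series branch agrees with the direct Rayleigh formula just below the
  # cutover (the direct formula is still accurate to ~1e-13 there)
  x <- 0.0499
  direct <- (3 * (sin(x) - x * cos(x)) / x^3)^2
  expect_equal(sphere_form_factor(x, 1), direct, tolerance = 1e-10)
  expect_error(sphere_form_factor(0.1, -2), "R")
})

test_that("Debye length reproduces the physiological value and scaling identities", {
  expect_equal(debye_length(0.15), 7.85, tolerance = 1e-3)     # printed as 7.8
  expect_equal(debye_length(9.2416), 1.0, tolerance = 1e-4)
  expect_equal(debye_length(0.0375), 15.7, tolerance = 1e-3)
  expect_error(debye_length(0), "> 0")
  expect_error(debye_length(-0.1), "> 0")
})

test_that("effective charge reproduces the fitted-state values within 1 e", {
  for (nm in names(table1_rows)) {
    r <- table1_rows[[nm]]
    y <- yukawa_interaction(r$cp, r$reff, r$phi, kappa_inv = 7.8)
    expect_lt(abs(charge_from_contact_potential(y) - r$Z), 1)
  }
})

test_that("effective charge is zero at zero coupling and monotone", {
  y0 <- yukawa_interaction(0, 23.6, 0.256, kappa_inv = 7.8)
  expect_equal(charge_from_contact_potential(y0), 0)
  cps <- seq(0.1, 5, by = 0.1)
  Z <- vapply(cps, function(cp)
    charge_from_contact_potential(
      yukawa_interaction(cp, 23.6, 0.256, kappa_inv = 7.8)), numeric(1))
  expect_true(all(diff(Z) > 0))
  # also monotone in the diameter
  Zr <- vapply(seq(18, 30, 2), function(r)
    charge_from_contact_potential(
      yukawa_interaction(2.5, r, 0.256, kappa_inv = 7.8)), numeric(1))
  expect_true(all(diff(Zr) > 0))
})

test_that("composite intensity degenerates correctly and decomposes exactly", {
  q <- exp(seq(log(0.01), log(0.45), length.out = 80))
  Fq <- sphere_form_factor(q, 23.6)
  S <- 1 + 0.4 * sin(20 * q) * exp(-q)          # arbitrary smooth S
  # I1 = 0, S = 1: pure scaled form factor
  expect_equal(composite_sans_intensity(q, list(I1 = 0, d = 2.2), 2, Fq, rep(1, 80)),
               2 * Fq)
  # I2 = 0: log-log slope is exactly -d
  I <- composite_sans_intensity(q, list(I1 = 3, d = 2.7), 0, Fq, S)
  sl <- diff(log(I)) / diff(log(q))
  expect_equal(max(abs(sl + 2.7)), 0, tolerance = 1e-10)
  # algebraic round trip
  I <- composite_sans_intensity(q, list(I1 = 5e-4, d = 2.2), 1.3, Fq, S)
  S_back <- (I - 5e-4 * q^(-2.2)) / (1.3 * Fq)
  expect_equal(S_back, S, tolerance = 1e-10)
  expect_error(composite_sans_intensity(0, list(I1 = 1, d = 2), 1, 1, 1), "q = 0")
})
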