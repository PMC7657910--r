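test_that("zero internal width collapses the model to one Lorentzian", {
  om <- seq(-31, 31, by = 0.2)
  p <- list(A0 = 0.35, Gamma_G = 1.2, Gamma_I = 0, scale = 2.5)
  one <- 2.5 * 1.2 / (pi * (1.2^2 + om^2))
  expect_equal(model_total_sqw(om, p), one, tolerance = 1e-14)
})

test_that("model integrates to its scale over a wide window", {
  p <- list(A0 = 0.6, Gamma_G = 0.8, Gamma_I = 2.5, scale = 3,
            bkg_a = 0.01, bkg_b = 2e-4)
  G <- 0.8 + 2.5
  om <- seq(-200 * G, 200 * G, length.out = 200001)
  tot <- rbcneutron:::trapz(om, model_total_sqw(om, p))
  bkg <- 0.01 * diff(range(om))                      # odd term integrates out
  expect_equal(tot - bkg, 3, tolerance = 0.005 * 3)  # slow Lorentzian tails
})

test_that("peak value matches the closed form", {
  p <- list(A0 = 0.6, Gamma_G = 0.8, Gamma_I = 2.5, scale = 3, bkg_a = 0.07)
  expect_equal(model_total_sqw(0, p),
               3 * (0.6 / (pi * 0.8) + 0.4 / (pi * 3.3)) + 0.07,
               tolerance = 1e-14)
})

test_that("convolving a numerical spike returns the resolution shape", {
  om <- seq(-20, 20, by = 0.3)
  sd_res <- 1.0 / (2 * sqrt(2 * log(2)))
  res <- list(omega = om, R = exp(-om^2 / (2 * sd_res^2)))
  h <- 0.3 / 4
  spike <- function(x) ifelse(abs(x) < h / 2, 1 / h, 0)
  out <- convolve_resolution(spike, res, om)
  rn <- res$R / rbcneutron:::trapz(om, res$R)
  expect_lt(max(abs(out - rn)) / max(rn), 0.02)
})

test_that("Lorentzian x Gaussian convolution matches a Voigt quadrature oracle", {
  om <- seq(-20, 20, by = 0.3)
  sd_res <- 1.0 / (2 * sqrt(2 * log(2)))             # FWHM 1.0 ueV
  res <- list(omega = om, R = exp(-om^2 / (2 * sd_res^2)))
  G <- 1.7
  conv <- convolve_resolution(function(x) rbcneutron:::.lorentzian(x, G), res, om)
  voigt <- vapply(om, function(w0)
    integrate(function(t) rbcneutron:::.lorentzian(w0 - t, G) * dnorm(t, 0, sd_res),
              -Inf, Inf, rel.tol = 1e-10)$value, numeric(1))
  expect_lt(max(abs(conv - voigt)) / max(voigt), 1e-4)
})

test_that("convolution commutes with scaling and preserves the integral", {
  om <- seq(-31, 31, by = 0.2)
  sd_res <- 1.0 / (2 * sqrt(2 * log(2)))
  res <- list(omega = om, R = exp(-om^2 / (2 * sd_res^2)))
  m <- function(x) rbcneutron:::.lorentzian(x, 2.2)
  c1 <- convolve_resolution(m, res, om)
  c3 <- convolve_resolution(function(x) 3 * m(x), res, om)
  expect_equal(c3, 3 * c1, tolerance = 1e-12)
  # integral preservation within 0.1% (window-truncated on both sides)
  expect_equal(rbcneutron:::trapz(om, c1), rbcneutron:::trapz(om, m(om)),
               tolerance = 1e-3)
})

test_that("buffer subtraction behaves like a linear operation with error propagation", {
  om <- seq(-20, 20, by = 0.3)
  res <- list(omega = om, R = dnorm(om, 0, 0.42))
  s <- qens_spectrum(0.91, om, 5 + dnorm(om, 0, 2), rep(0.2, length(om)), res)
  b <- qens_spectrum(0.91, om, rep(1, length(om)), rep(0.1, length(om)), res)
  expect_equal(subtract_buffer(s, b, 0)$S, s$S)
  z <- subtract_buffer(s, s, 1)
  expect_true(all(z$S == 0))
  expect_equal(z$sigma, sqrt(2) * s$sigma, tolerance = 1e-12)
  expect_true(z$negative_bins || all(z$S >= 0))
  bad <- qens_spectrum(0.91, om + 0.05, b$S, b$sigma, res)
  expect_error(subtract_buffer(s, bad), "grids differ")
})

test_that("synthetic buffer component subtracts away within noise", {
  tr <- qens_truth_horse()
  tr$buffer_frac <- 0.3
  chi2 <- vapply(1:20, function(s) {
    gen <- make_qens(tr, q = c(0.91), seed = s)
    clean <- make_qens(modifyList(tr, list(buffer_frac = 0)),
                       q = c(0.91), counts_peak = 0, seed = s)
    sub <- subtract_buffer(gen$spectra[[1]], gen$buffer[[1]], 0.3)
    ref <- clean$spectra[[1]]$S                  # noiseless signal shape
    a <- sum(ref * sub$S / sub$sigma^2) / sum(ref^2 / sub$sigma^2)
    mean(((sub$S - a * ref) / sub$sigma)^2)
  }, numeric(1))
  # after removing the buffer, the residual is the signal alone within
  # counting noise: reduced chi-square against the scaled clean shape ~ 1
  expect_lt(mean(chi2), 1.15)
  expect_gt(mean(chi2), 0.85)
})
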