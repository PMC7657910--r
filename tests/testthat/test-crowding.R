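test_that("relative viscosity has the right limits and a second implementation agrees", {
  p <- crowding_params()
  expect_equal(relative_viscosity(0, p), 1)
  cs <- seq(0, 600, by = 10)
  expect_true(all(diff(relative_viscosity(cs, p)) > 0))
  # independent series-free arithmetic at 336 mg/ml
  c0 <- 336
  x <- p$intrinsic_viscosity * c0
  alt <- exp(x / (1 - p$k_over_v * x))
  expect_equal(relative_viscosity(c0, p), alt, tolerance = 1e-14)
  expect_error(relative_viscosity(700, p), "c_max")
})

test_that("diffusion law decreases with concentration and round-trips through the inverse", {
  p <- crowding_params()
  expect_equal(diffusion_at_concentration(0, p), p$D0)
  cs <- seq(0, 600, by = 25)
  expect_true(all(diff(diffusion_at_concentration(cs, p)) < 0))
  for (c0 in c(100, 250, 400)) {
    D <- diffusion_at_concentration(c0, p)
    expect_equal(concentration_from_diffusion(D, p, rotation_factor = 1), c0,
                 tolerance = 1e-10)
  }
})

test_that("inverse consistency holds to 1e-10 across the working range", {
  p <- crowding_params()
  cs <- seq(50, 500, by = 5)
  back <- concentration_from_diffusion(diffusion_at_concentration(cs, p) * 1.27,
                                       p, rotation_factor = 1.27)
  expect_lt(max(abs(back - cs)), 1e-10 * 500)
})

test_that("all measured diffusion coefficients invert to the printed concentrations", {
  for (nm in names(table2_diffusion)) {
    r <- table2_diffusion[[nm]]
    p <- crowding_params(D0 = r$D0 * 1e-8)
    cc <- concentration_from_diffusion(r$D * 1e-8, p)
    expect_lt(abs(cc - r$c), 1)
  }
})

test_that("inversion is strictly decreasing in the measured diffusion coefficient", {
  p <- crowding_params(D0 = 63.4e-8)
  Ds <- seq(2e-8, 60e-8, length.out = 50)
  cc <- concentration_from_diffusion(Ds, p)
  expect_true(all(diff(cc) < 0))
  # boundary: corrected D equal to D0 means zero concentration
  expect_equal(concentration_from_diffusion(1.27 * p$D0, p), 0)
  expect_error(concentration_from_diffusion(1.4 * p$D0, p), "exceeds D0")
})

test_that("physiological average concentration corresponds to phi = 0.25", {
  c_h <- concentration_from_diffusion(10.0e-8, crowding_params(D0 = 46.8e-8))
  c_u <- concentration_from_diffusion(8.0e-8, crowding_params(D0 = 63.4e-8))
  c_avg <- mean(c(round(c_h), round(c_u)))
  expect_equal(c_avg, 336)
  phi <- c_avg * 0.75 / 1000
  expect_equal(phi, 0.25, tolerance = 0.01 / 0.25)
})

test_that("hydrodynamic function values match the lysate analysis", {
  expect_equal(hydrodynamic_function(19.0e-8 / 1.27, 63.4e-8), 0.24,
               tolerance = 0.02)
  expect_equal(hydrodynamic_function(1, 1), 1)
  expect_equal(hydrodynamic_function(31.7e-8, 63.4e-8), 0.5)
  expect_equal(hard_sphere_H(0.20), 0.6338)
  expect_equal(hard_sphere_H(0), 1)
  expect_equal(hard_sphere_H(1 / 1.831), 0)
  expect_error(hard_sphere_H(0.6), "phi")
})

test_that("volume changes follow the concentration ratios", {
  expect_equal(volume_change(300, 300), 0)
  expect_equal(volume_change(315, 362), -0.1298, tolerance = 1e-3)  # shrinkage
  expect_equal(volume_change(357, 295), 0.2102, tolerance = 1e-3)   # expansion
})

test_that("expected lysate concentrations bracket the haematocrit window", {
  expect_equal(expected_lysate_concentration(0.6, 357), 214, tolerance = 1e-2)
  expect_equal(expected_lysate_concentration(0.7, 357), 250, tolerance = 2e-3)
  expect_equal(expected_lysate_concentration(1, 357), 357)
  expect_error(expected_lysate_concentration(1.2, 357), "haematocrit")
})
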