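# The screened-Coulomb structure factor has two independent oracles: the
# Percus-Yevick closed form at zero coupling, and an Ornstein-Zernike
# iterative solver at finite coupling.

test_that("PY closed form equals direct quadrature of the PY direct correlation", {
  qg <- seq(0.5, 30, by = 0.5)
  phi <- 0.2
  A <- (1 + 2 * phi)^2 / (1 - phi)^4
  B <- -6 * phi * (1 + phi / 2)^2 / (1 - phi)^4
  C <- phi * A / 2
  S_num <- vapply(qg, function(qq) {
    chat <- integrate(function(r) -(A + B * r + C * r^3) * r * sin(qq * r) / qq * 4 * pi,
                      0, 1, rel.tol = 1e-12)$value
    1 / (1 - 6 * phi / pi * chat)
  }, numeric(1))
  expect_equal(py_hard_sphere_sq(qg, phi), S_num, tolerance = 1e-12)
})

test_that("MSA solver reduces exactly to Percus-Yevick at zero charge", {
  qg <- seq(0.5, 60, by = 0.25)
  for (phi in c(0.05, 0.2, 0.4)) {
    y <- yukawa_interaction(0, 23.6, phi, kappa_inv = 7.8)
    S <- rmsa_structure_factor(qg / y$sigma_hc, y)
    expect_lt(max(abs(S - py_hard_sphere_sq(qg, phi))), 1e-6)
  }
})

test_that("ideal-gas limit: S -> 1 at vanishing volume fraction", {
  y <- yukawa_interaction(2.5, 23.6, 1e-6, kappa_inv = 7.8)
  S <- rmsa_structure_factor(seq(0.01, 1, by = 0.01), y)
  expect_lt(max(abs(S - 1)), 1e-3)
})

test_that("OZ oracle matches PY for hard spheres and the ideal-gas limit", {
  y <- yukawa_interaction(0, 23.6, 0.1, kappa_inv = 7.8)
  oz <- oz_msa_oracle(y)
  keep <- oz$q > 0.4 & oz$q < 30
  expect_lt(max(abs(oz$S[keep] - py_hard_sphere_sq(oz$q[keep], 0.1))), 1e-3)
  y0 <- yukawa_interaction(0.5, 23.6, 1e-7, kappa_inv = 23.6)
  oz0 <- oz_msa_oracle(y0, n = 4096, dr = 0.01)
  expect_lt(max(abs(oz0$S - 1)), 1e-4)
})

test_that("factorization solution agrees with the OZ oracle at weak coupling", {
  # 0.5 kBT contact, phi = 0.15, k ~ 6 (physiological screening)
  y <- yukawa_interaction(0.5, 23.6, 0.15, kappa_inv = 7.8)
  oz <- oz_msa_oracle(y)
  keep <- oz$q > 0.5 & oz$q < 20
  S <- rmsa_structure_factor(oz$q[keep] / y$sigma_hc, y)
  expect_lt(max(abs(S - oz$S[keep])), 2e-3)
})

test_that("physiological-state structure factor has one dominant interaction peak", {
  y <- yukawa_interaction(2.5, 23.6, 0.256, kappa_inv = 7.8)
  q <- seq(0.02, 0.4, by = 0.001)
  S <- rmsa_structure_factor(q, y)
  expect_true(all(S >= 0))
  ipk <- which.max(S)
  # reported qualitatively as "approximately 0.1 1/A"
  expect_gt(q[ipk], 0.08)
  expect_lt(q[ipk], 0.15)
  # single dominant maximum below the large-q oscillation region: no other
  # local maximum within 90% of the peak height below q*sigma ~ 12
  loc <- which(diff(sign(diff(S))) == -2) + 1
  main <- loc[q[loc] < 12 / y$sigma_hc]
  expect_lte(sum(S[main] > 1 + 0.9 * (S[ipk] - 1)), 1)
})

test_that("S approaches 1 at large q and stays non-negative", {
  y <- yukawa_interaction(2.5, 23.6, 0.256, kappa_inv = 7.8)
  q60 <- 60 / y$sigma_hc
  S <- rmsa_structure_factor(c(seq(0.01, 0.5, by = 0.005), q60), y)
  expect_true(all(S >= 0))
  expect_lt(abs(S[length(S)] - 1), 0.02)
})

test_that("rescaling activates for dilute strongly charged fluids and zeroes g(sigma+)", {
  # long screening length + strong contact repulsion: plain MSA gives
  # negative contact correlation, triggering core inflation
  y <- yukawa_interaction(8, 30, 0.05, kappa_inv = 60)
  det <- rmsa_structure_factor(seq(0.005, 0.3, by = 0.002), y,
                               return_details = TRUE)
  expect_true(det$rescaled)
  expect_gt(det$s, 1)
  expect_true(all(det$S >= 0))
  # after rescaling, the contact value of g at the inflated core is zero
  expect_lt(abs(rbcneutron:::.msa_contact_g(det$coef, det$eta_solved,
                                            det$z_solved,
                                            (y$contact_potential / det$s) *
                                              exp(-y$k * (det$s - 1)))), 1e-6)
  # the physiological states do not need rescaling
  yh <- yukawa_interaction(2.5, 23.6, 0.256, kappa_inv = 7.8)
  deth <- rmsa_structure_factor(seq(0.02, 0.4, by = 0.01), yh,
                                return_details = TRUE)
  expect_false(deth$rescaled)
  expect_gt(deth$g_contact, 0)
})

test_that("invalid interaction states are rejected", {
  expect_error(yukawa_interaction(2.5, 23.6, 0.8, kappa_inv = 7.8), "0.74")
  expect_error(yukawa_interaction(-1, 23.6, 0.2, kappa_inv = 7.8), ">= 0")
  y <- yukawa_interaction(1, 23.6, 0.2, kappa_inv = 7.8)
  expect_error(rmsa_structure_factor(c(0, 0.1), y), "positive")
})
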