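# Shared fixtures: the fitted interaction states of the six measured cell
# conditions (contact potential kBT, effective radius A, volume fraction,
# printed effective charge), and convenience truth builders whose screening
# length is the exact Debye value at 0.15 M so that synthetic generation and
# refitting share one model.

table1_rows <- list(
  horse_phys  = list(cp = 2.5, reff = 23.6, phi = 0.256, Z = 16, c = 341),
  horse_val   = list(cp = 1.9, reff = 24.1, phi = 0.319, Z = 15, c = 426),
  horse_mon   = list(cp = 0.1, reff = 25.6, phi = 0.229, Z = 4,  c = 305),
  human_phys  = list(cp = 3.3, reff = 22.6, phi = 0.249, Z = 18, c = 332),
  human_val   = list(cp = 3.1, reff = 22.6, phi = 0.279, Z = 17, c = 372),
  human_mon   = list(cp = 1.3, reff = 22.6, phi = 0.224, Z = 12, c = 253)
)

# measured diffusion coefficients (1e-8 cm^2/s) and dilute limits per species
table2_diffusion <- list(
  horse_phys = list(D = 10.0, D0 = 46.8, T = 288, c = 315),
  horse_val  = list(D = 5.5,  D0 = 46.8, T = 288, c = 362),
  human_phys = list(D = 8.0,  D0 = 63.4, T = 298, c = 357),
  human_mon  = list(D = 16.6, D0 = 63.4, T = 298, c = 295),
  human_mon_glc = list(D = 16.2, D0 = 63.4, T = 298, c = 297),
  lysate     = list(D = 19.0, D0 = 63.4, T = 298, c = 281)
)

sans_truth_horse <- function() {
  list(I1 = 1e-4, d = 2.2, I2 = 1.0,
       yukawa = yukawa_interaction(2.5, 23.6, 0.256, ionic_strength = 0.15))
}

qens_truth_horse <- function() {
  list(D_eff = 10.0e-8, x2 = 1.3, p = 0.5, Gamma_I = 2.84, bkg_frac = 0.005)
}

butler_truth <- function() list(model = "butler", I0 = 2.3, alpha = 0.1,
                                xi_um = 4.61, d = 3.6)
gp_truth <- function() list(model = "gp", scale = 8, Rg_um = 1.15, d = 3.9)

expect_rel <- function(actual, expected, tol) {
  expect_lt(max(abs(actual / expected - 1)), tol)
}
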