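#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study datasets.
#
# Emulates the three measurements with known ground truth: USANS curves for
# the three cell states (physiological and monensin-swollen cells show a
# rouleaux correlation peak; valinomycin-shrunken cells show a micrometre
# Guinier regime), SANS curves for the fitted horse/human interaction
# states, and backscattering QENS spectra at the measured diffusion truths.
# Curves are written as plain ASCII under results/data/.

suppressPackageStartupMessages(library(rbcneutron))
seed <- 20260928L
outdir <- "results/data"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

truths <- list(
  usans = list(
    physiological = list(model = "butler", I0 = 2.3, alpha = 0.10,
                         xi_um = 4.61, d = 3.6),
    monensin      = list(model = "butler", I0 = 2.0, alpha = 0.12,
                         xi_um = 5.28, d = 3.8),
    valinomycin   = list(model = "gp", scale = 8, Rg_um = 1.15, d = 3.9)),
  sans = list(
    horse_physiological = list(I1 = 1e-4, d = 2.22, I2 = 1,
      yukawa = yukawa_interaction(2.5, 23.6, 0.256, ionic_strength = 0.15)),
    human_physiological = list(I1 = 1e-4, d = 2.35, I2 = 1,
      yukawa = yukawa_interaction(3.3, 22.6, 0.249, ionic_strength = 0.15))),
  qens = list(
    horse_physiological = list(D_eff = 10.0e-8, x2 = 1.3, p = 0.5,
                               Gamma_I = 2.84, T_K = 288, D0 = 46.8e-8),
    horse_valinomycin   = list(D_eff = 5.5e-8, x2 = 0.9, p = 0.35,
                               Gamma_I = 2.34, T_K = 288, D0 = 46.8e-8),
    human_physiological = list(D_eff = 8.0e-8, x2 = 1.3, p = 0.5,
                               Gamma_I = 2.40, T_K = 298, D0 = 63.4e-8),
    human_monensin      = list(D_eff = 16.6e-8, x2 = 1.3, p = 0.5,
                               Gamma_I = 3.68, T_K = 298, D0 = 63.4e-8),
    human_lysate        = list(D_eff = 19.0e-8, x2 = 1.3, p = 0.5,
                               Gamma_I = 2.48, T_K = 298, D0 = 63.4e-8)))

for (nm in names(truths$usans)) {
  gen <- make_usans(truths$usans[[nm]], noise_frac = 0.02, seed = seed)
  write_sas(gen$curve, file.path(outdir, sprintf("usans_%s.dat", nm)))
}
for (nm in names(truths$sans)) {
  gen <- make_sans(truths$sans[[nm]], rel_err_peak = 0.03, seed = seed)
  write_sas(gen$curve, file.path(outdir, sprintf("sans_%s.dat", nm)))
}
# QENS spectra are regenerated from the truth record by later stages (the
# per-q ASCII files would be bulky); only the truth bookkeeping is persisted.
saveRDS_free <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
}
saveRDS_free(list(seed = seed,
                  usans = truths$usans,
                  sans = lapply(truths$sans, function(t)
                    list(I1 = t$I1, d = t$d, I2 = t$I2,
                         contact_potential = t$yukawa$contact_potential,
                         R_eff = t$yukawa$sigma_hc / 2, phi = t$yukawa$phi)),
                  qens = truths$qens),
             "results/truths.json")
cat("wrote", length(truths$usans) + length(truths$sans),
    "synthetic curves under", outdir, "and results/truths.json\n")
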