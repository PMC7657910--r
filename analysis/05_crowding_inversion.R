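#!/usr/bin/env Rscript
# Stage 5: from diffusion coefficients to intracellular concentrations.
#
# The fitted apparent diffusion coefficients of stage 4 are corrected for
# rotational diffusion (/1.27) and inverted through the crowded-solution
# law to intracellular haemoglobin concentrations; the structure-factor
# concentrations of stage 3 provide the independent cross-check. Also
# computed: hydrodynamic functions, ionophore-induced volume changes and
# the expected lysate concentration window.

suppressPackageStartupMessages(library(rbcneutron))
qens <- read.csv("results/qens_dynamics.csv")
sans <- read.csv("results/sans_interactions.csv")
truths <- jsonlite::read_json("results/truths.json", simplifyVector = FALSE)

qens$D0 <- vapply(qens$sample, function(nm) truths$qens[[nm]]$D0, numeric(1))
qens$c_mg_ml <- mapply(function(D, D0) {
  concentration_from_diffusion(D * 1e-8, crowding_params(D0 = D0))
}, qens$D_eff_1e8, qens$D0)

cat("concentrations from diffusion (mg/ml):\n")
print(qens[, c("sample", "D_eff_1e8", "c_mg_ml")], row.names = FALSE)

# independent route: structure-factor volume fractions
for (nm in sans$sample) {
  cs <- sans$c_mg_ml[sans$sample == nm]
  nq <- sub("sans", "qens", nm)
  match <- qens$sample == nm
  if (any(match)) {
    cq <- qens$c_mg_ml[match]
    cat(sprintf("%-22s c_SANS = %.0f, c_QENS = %.0f mg/ml (discrepancy %.1f%%)\n",
                nm, cs, cq, 100 * abs(cs - cq) / mean(c(cs, cq))))
  }
}

h_lys <- hydrodynamic_function(
  qens$D_eff_1e8[qens$sample == "human_lysate"] * 1e-8 / 1.27, 63.4e-8)
phi_lys <- qens$c_mg_ml[qens$sample == "human_lysate"] * 0.75 / 1000
cat(sprintf("lysate hydrodynamic function H = %.2f at phi = %.2f (hard-sphere prediction %.2f)\n",
            h_lys, phi_lys, hard_sphere_H(round(phi_lys, 2))))

vc <- data.frame(
  pair = c("horse valinomycin/physiological", "human monensin/physiological"),
  volume_change = c(
    volume_change(qens$c_mg_ml[qens$sample == "horse_physiological"],
                  qens$c_mg_ml[qens$sample == "horse_valinomycin"]),
    volume_change(qens$c_mg_ml[qens$sample == "human_physiological"],
                  qens$c_mg_ml[qens$sample == "human_monensin"])))
print(vc, row.names = FALSE)

c_cell <- qens$c_mg_ml[qens$sample == "human_physiological"]
cat(sprintf("expected lysate window at haematocrit 0.6-0.7: %.0f-%.0f mg/ml; measured %.0f\n",
            expected_lysate_concentration(0.6, c_cell),
            expected_lysate_concentration(0.7, c_cell),
            qens$c_mg_ml[qens$sample == "human_lysate"]))

write.csv(qens[, c("sample", "T_K", "D_eff_1e8", "D0", "c_mg_ml")],
          "results/crowding_concentrations.csv", row.names = FALSE)
cat("wrote results/crowding_concentrations.csv\n")
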