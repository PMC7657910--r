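# rbcneutron

Neutron-scattering analysis of red blood cells (RBCs): cell-scale morphology
from ultra-small-angle scattering (USANS), haemoglobin–haemoglobin
interactions from small-angle scattering (SANS), and haemoglobin dynamics
from quasi-elastic neutron scattering (QENS), tied together by a
crowded-solution model that converts a measured self-diffusion coefficient
into an intracellular protein concentration.

The package is written for scattering practitioners and quantitative cell
biologists who want the full analysis chain of such an experiment —
ionophore-perturbed RBC suspensions measured on Bonse–Hart, pinhole-SANS and
backscattering instruments — as tested, seeded, reusable code, runnable
end-to-end on synthetic data with known ground truth.

## What it computes

**USANS morphology.** Curves with a rouleaux correlation peak are fitted
with the empirical peak model
I(q) = I₀·[α/(1−α) + 2x^(−d)] / [1/(1−α) + x^(−2d)], x = qξ/2π,
yielding the stacking correlation length ξ (peak at q* = 2π/ξ); peak-free
curves from shrunken cells use the generalized Guinier–Porod model, and the
morphology chain R = √(5/3)·R_g, V = 4πR³/3 gives an effective spherical
cell radius and volume. Slit smearing (infinite-slit kernel) and Lake's
iterative desmearing connect point-resolved models to slit-smeared data.

**SANS interactions.** Reduced curves are fitted with
I(q) = I₁q^(−d) + I₂·F(q)·S(q), where F is the protein form factor and S
the structure factor of charged hard spheres with screened Coulomb (Yukawa)
repulsion βU(x) = γe^(−kx)/x, computed in the (rescaled) mean spherical
approximation via Baxter's factorization — validated in-tree against the
Percus–Yevick closed form and an Ornstein–Zernike solver. Derived per state:
contact potential (k_BT), effective charge
Z = (2+k)·√(πεε₀σU_c)/e, volume fraction φ and concentration c = φ/υ
(υ = 0.75 ml/g). Kinetic series of fits provide a lysis drift flag.

**QENS dynamics.** Spectra are fitted per q with a resolution-convolved
two-Lorentzian model S(q,ω) = A₀L(Γ_G) + (1−A₀)L(Γ_G+Γ_I) plus linear
background. The narrow widths give the apparent diffusion coefficient
through Γ_G = ħD_eff·q² (rotational correction D_eff/1.27 for spheres), the
internal widths give the correlation time τ = ħ/⟨Γ⟩, and the EISF
A₀(q) = (1−p)e^(−⟨x²⟩q²) + p gives the confinement amplitude and immobile
fraction.

**Crowding inversion.** From the Mooney-type law
1/D(c) = (1/D₀)·exp([η]c/(1−(k/v)[η]c)) with the haemoglobin constants
[η] = 2.94×10⁻³ l/g and k/v = 0.52, the measured D inverts in closed form to
c = ln(D₀/D) / (ln(D₀/D)·(k/v)·[η] + [η]).

A seeded synthetic-data module emulates all three instruments (grids, noise
statistics, resolution) so every estimator is exercised against known truth
without any downloads.

## Worked example

Invert the measured apparent diffusion coefficients of haemoglobin into
intracellular concentrations, and compare the lysate's hydrodynamic slowdown
with the colloidal hard-sphere prediction:

```r
library(rbcneutron)

p288 <- crowding_params(D0 = 46.8e-8)          # dilute limit at 288 K, cm^2/s
p298 <- crowding_params(D0 = 63.4e-8)          # at 298 K

# horse RBCs, physiological state: D_eff = 10.0e-8 cm^2/s
concentration_from_diffusion(10.0e-8, p288)
#> [1] 314.6296
# horse + valinomycin (shrunken): 5.5e-8 -> more concentrated
concentration_from_diffusion(5.5e-8, p288)
#> [1] 361.7925
# human lysate: 19.0e-8 -> diluted by lysis
concentration_from_diffusion(19.0e-8, p298)
#> [1] 280.5244

# crowding slows the lysate's short-time self-diffusion 2.6x more than
# an ideal hard-sphere suspension at the same volume fraction would
hydrodynamic_function(19.0e-8 / 1.27, 63.4e-8)
#> [1] 0.2359721
hard_sphere_H(0.20)
#> [1] 0.6338
```

So a physiological horse RBC holds about 315 mg/ml haemoglobin, valinomycin
shrinkage raises it to ~362 mg/ml (a ~13% volume loss,
`volume_change(315, 362)`), and the lysate sits at ~281 mg/ml — inside the
214–250·(0.6–0.7 haematocrit) dilution window extended to its upper edge.

The interaction side of the same story:

```r
y <- yukawa_interaction(2.5, R_eff = 23.6, phi = 0.256, kappa_inv = 7.8)
charge_from_contact_potential(y)    # effective charge per haemoglobin
#> [1] 16.37817
S <- rmsa_structure_factor(seq(0.02, 0.4, 0.002), y)   # peaks near 0.1 1/A
concentration_from_phi(0.256)
#> [1] 341.3333
```

## Analysis workflow

The `analysis/` directory holds the numbered drivers of the full study on
synthetic data — `01_simulate.R` (generate all datasets),
`02_usans_morphology.R`, `03_sans_interactions.R`, `04_qens_dynamics.R`,
`05_crowding_inversion.R` — each a thin narrative script over the package
functions, writing tables under `results/`. Run them in order from the
repository root with `Rscript analysis/01_simulate.R` etc.

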