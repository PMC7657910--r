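---
title: "Models and methods: red-blood-cell neutron scattering analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: red-blood-cell neutron scattering analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbcneutron)
```

This package reconstructs, as tested reusable code, a three-technique
neutron-scattering characterization of red blood cells (RBCs): cell-scale
morphology from ultra-small-angle scattering (USANS), haemoglobin–haemoglobin
(Hb–Hb) interactions from small-angle scattering (SANS), and Hb dynamics from
quasi-elastic neutron scattering (QENS), closed by a crowded-solution
inversion that turns a measured self-diffusion coefficient into an
intracellular protein concentration. This vignette explains each model, its
assumptions and tunable parameters, the numerical choices, and what the
synthetic-data tests do and do not establish.

## USANS morphology

Intact discocytes at high haematocrit stack into rouleaux, producing a
correlation peak at $q^* = 2\pi/\xi$ in the micrometre regime. Curves with a
peak are described by the empirical form

$$I(q) = I_0\,
  \frac{\alpha/(1-\alpha) + 2 x^{-d}}{1/(1-\alpha) + x^{-2d}},
  \qquad x = \frac{q\xi}{2\pi},$$

which equals exactly $I_0$ at $x = 1$ and decays to the plateau $I_0\alpha$
at large $q$ with an intermediate power law of exponent $d$. Shrunken
(spherocyte-like) cells lose the peak; those curves use the generalized
Guinier–Porod model in its globular ($s = 0$) form: a Guinier factor
$\exp(-q^2 R_g^2/3)$ for $q \le q_1$ and $D q^{-d}$ beyond, with
$q_1 = \sqrt{3d/2}/R_g$ and $D$ fixed by continuity of value and slope. The
redundant product of the two historical scale factors is collapsed into a
single `scale` parameter. Derived morphology uses the uniform-sphere
relations $R = \sqrt{5/3}\,R_g$ and $V = 4\pi R^3/3$ (1 µm³ = 1 fl).

Two caveats are built into the interface rather than hidden: fits operate on
de-smeared curves (matching the facility workflow; a smeared-model path
exists through `slit_smear` for validation), and the Guinier-derived volume
of densely packed suspensions is biased low by interparticle correlations —
the analysis reports the naive value with that caveat, because no correction
is defined at this level of modelling.

Slit smearing uses the infinite-slit kernel with sharp cutoff
$\Delta q_v$, $I_s(q) = \Delta q_v^{-1}\int_0^{\Delta q_v}
I(\sqrt{q^2+u^2})\,du$, by 64-node Gauss–Legendre quadrature; intensities
beyond the measured range come from a power law fitted to the trailing
decade. Desmearing is the multiplicative fixed-point iteration
$I_{n+1} = I_n \cdot I_\mathrm{meas}/\mathrm{Smear}(I_n)$ (the variant is a
package choice; the facility software's variant is unpublished), stopped at
reduced $\chi^2 < 1.05$ or 200 iterations, both configurable. Noiseless
curves have no $\sigma$ column, so the stopping statistic falls back to a
pseudo-uncertainty of 0.05% of $I$; the smear-then-desmear round trip is
then accurate to ~0.01% over the central decades, comfortably inside the 1%
contract the tests enforce.

## SANS: charged hard spheres with screened Coulomb repulsion

Reduced SANS curves are modelled as

$$I(q) = I_1 q^{-d} + I_2\,F(q)\,S(q),$$

a power law for forward scattering (membranes and superstructure), a
single-particle form factor $F(q)$ (tabulated, or the analytic sphere —
synthetic work uses a 23.6 Å sphere matching the fitted effective Hb
radius), and an interparticle structure factor $S(q)$ for Hb–Hb repulsion.
The interaction model is the hard-core Yukawa (screened Coulomb) fluid in
dimensionless form $\beta U(x) = \gamma e^{-kx}/x$ for $x = r/\sigma > 1$,
with $\sigma = 2R_\mathrm{eff}$, $k = \sigma\kappa$, and contact potential
$\gamma e^{-k}$ in units of $k_BT$. The Debye length is fixed by ionic
strength, $\kappa^{-1} = 0.304/\sqrt{I(\mathrm{M})}$ nm (7.85 Å at 0.15 M),
not fitted. The effective charge follows from the contact potential as
$Z = (2+k)\sqrt{\pi\varepsilon\varepsilon_0\sigma U_c}/e$ with
$\varepsilon = 80$ at 293 K by default.

### The MSA solver and its two oracles

$S(q)$ is computed in the mean spherical approximation (MSA) via Baxter's
Wiener–Hopf factorization of the Ornstein–Zernike equation. The factor
function of the one-Yukawa fluid is

$$Q(r) = \tfrac{a}{2}(r^2-1) + b(r-1) + c_1(e^{-zr} - e^{-z}) + d_1 e^{-z}
\;\; (r<1), \qquad Q(r) = d_1 e^{-zr} \;\; (r>1),$$

carrying five scalar unknowns — $a$, $b$, $c_1$, $d_1$ and the Laplace
moment $G(z) = \int_0^\infty r\,h(r)\,e^{-zr}dr$. On this ansatz, Baxter's
two factorized relations reduce to closed forms: the hard-core condition
$h(r) = -1$ inside the core becomes a residual spanned by
$\{1, r, e^{-zr}\}$ (collocated at six interior points), the Yukawa tail
gives one amplitude equation, and $G$ is closed by a panelized
Gauss–Legendre quadrature of $S(q)-1$ in $q$-space. The
5-equation system is solved by a compact Levenberg–Marquardt (pure R by
design: it runs inside outer `minpack.lm` fits, whose C callback is not
reentrant). $S(q) = 1/|\hat Q(q)|^2$ is then closed-form — manifestly
non-negative, tending to 1 at large $q$.

Correctness rests on two independent oracles, both in the test suite:

* at zero coupling the system must collapse to Baxter's hard-sphere
  coefficients, i.e. the Percus–Yevick closed form — observed agreement is
  at machine precision (well inside the 1e-6 contract);
* at finite coupling it must agree with a from-scratch Picard iteration of
  the Ornstein–Zernike equation under the MSA closure on an 8192-point
  radial grid (41 hard-core diameters, contact-node averaging) — agreement
  is ~2e-5, inside the 2e-3 contract.

When the plain MSA yields an unphysical negative contact correlation
$g(\sigma^+) < 0$ (dilute, strongly charged, weakly screened fluids), the
standard rescaling is applied: the core is inflated at fixed number density
and fixed physical potential ($\eta^* = \eta s^3$, $k^* = ks$,
$\gamma^* = \gamma/s$) and $s$ is found by bracketed root search on
$g(\sigma^{*+}) = 0$ to 1e-10. The contact value itself is closed-form:
continuity of $h - c$ across the core gives
$g(1^+) = c(1^+) - c(1^-)$ with $c(1^-)$ from the factorization.

One parameterization note: the volume-fraction parameter $\phi$ follows the
standard convention of this structure-factor family — it is the packing
fraction of the $\sigma$-spheres, with number density $n = 6\phi/\pi\sigma^3$
— while the concentration bookkeeping uses the partial specific volume,
$c = \phi/\upsilon$ with $\upsilon = 0.75$ ml/g. For Hb these two roles of
$\phi$ are not exactly reconcilable (the dry-volume density at
$c = \phi/\upsilon$ differs from the packing density at the fitted 23.6 Å
core); the package keeps both conventions explicitly, which places the
physiological interaction peak near 0.12 Å⁻¹ on synthetic curves — the
broad neighbourhood of the reported ~0.1 Å⁻¹ peak.

### Fitting

`fit_sans` performs bounded weighted (1/σ²) least squares over
$\{I_1, d, I_2, \gamma e^{-k}, R_\mathrm{eff}, \phi\}$ with five jittered
multi-starts, because the $I_1$/$I_2$ trade-off is shallow; inner MSA solves
warm-start from the previous coefficients. $R_\mathrm{eff}$ can be fixed
(the treatment used for the human samples, where it is poorly determined);
the returned condition number of the scaled Jacobian makes the
identifiability of the remaining parameters checkable. The fit is
noise-level self-consistent: at 3% peak noise, 25-seed recovery of $\phi$ is
within 5% RMS with $R_\mathrm{eff}$ fixed. Freeing $R_\mathrm{eff}$ roughly
triples the $\phi$ spread through the $\gamma$–$R_\mathrm{eff}$–$\phi$
degeneracy; that is a property of the model, not the optimizer, and is why
the fixed-radius path exists.

Kinetic series are fitted per time point with shared fixed parameters;
$\langle C\rangle$ is the unweighted time mean by default (error-weighted
optional), and a linear trend in $c(t)$ significant at the 5% level raises
the drift flag that catches lysis-like steps.

## QENS: two Lorentzians under the resolution

For a protein undergoing simultaneous internal motion and global diffusion,
the measured dynamic structure factor is modelled as

$$S_\mathrm{tot}(q,\omega) = A_0(q)\,L_{\Gamma_G}(\omega) +
  (1-A_0(q))\,L_{\Gamma_G+\Gamma_I}(\omega),$$

unit-area Lorentzians with HWHM in µeV, plus a linear background, all
convolved with the measured resolution function. The elastic line never
appears as a bare delta: in solution the global width $\Gamma_G > 0$
broadens it, and the constraint $\Gamma_I \ge 0$ orders the components,
removing label switching by construction. Convolution evaluates the model
on a 4× oversampled grid padded by 12 resolution widths, convolves with the
spline-resampled unit-area kernel (FFT), and resamples; against an
independent Voigt quadrature oracle this is accurate to ~2e-5 relative.
Backgrounds are linear in $\omega$ (unconstrained sign) and commute with the
symmetric unit-area kernel, so they are added after convolution.

Derived quantities:

* $D_\mathrm{eff}$ from the error-weighted, origin-anchored line
  $\Gamma_G = \hbar D_\mathrm{eff} q^2$ (an intercept option exists for
  diagnostics); $\hbar = 6.582119569\times 10^{-10}$ µeV s, and
  $10^{-7}$ cm²/s $= 10^9$ Å²/s. The apparent coefficient contains
  rotational diffusion; for spherical particles
  $D_\mathrm{trans} = D_\mathrm{eff}/1.27$ (named, overridable constant).
* the internal width is flat in $q^2$ for confined motion — a regression
  p-value reports flatness — and its weighted mean gives
  $\tau = \hbar/\langle\Gamma\rangle$ in ps.
* the EISF is fitted with Gaussian confinement plus an immobile fraction,
  $A_0(q) = (1-p)e^{-\langle x^2\rangle q^2} + p$, bounded
  $\langle x^2\rangle \ge 0$, $p \in [0,1]$; a flat EISF flags
  $\langle x^2\rangle$ as unidentifiable rather than returning an arbitrary
  value. The sphere-confinement equivalence $\langle x^2\rangle = r^2/5$ is
  provided for comparison with diffusion-in-a-sphere analyses.

Buffer spectra subtract with a configurable scale (default 1; the weighting
the facility applied is unstated) and quadrature-combined uncertainties;
negative bins are kept and flagged, never clipped.

## Crowding inversion

Concentrated hard-particle suspensions follow a Mooney-type viscosity law,
$\eta(c)/\eta_0 = \exp\!\big([\eta]c/(1-(k/v)[\eta]c)\big)$, with intrinsic
viscosity $[\eta]$ and self-crowding ratio $k/v$; self-diffusion slows as
$D(c) = D_0\,\eta_0/\eta(c)$. Solving for $c$:

$$c = \frac{\ln(D_0/D)}{\ln(D_0/D)\,(k/v)\,[\eta] + [\eta]}.$$

Defaults are the measured Hb pair $[\eta] = 2.94\times10^{-3}$ l/g and
$k/v = 0.52$ (the hydrodynamic-model alternative $[\eta] =
3.60\times10^{-3}$ l/g is deliberately not substituted: the two parameters
are strongly coupled, so mixing a theoretical $[\eta]$ with the measured
$k/v$ would be inconsistent), with $D_0 = 46.8\times10^{-8}$ cm²/s at 288 K
and $63.4\times10^{-8}$ at 298 K. Concentrations are handled in g/l
(numerically mg/ml); the law has a pole at
$c_\mathrm{max} = 1/((k/v)[\eta]) \approx 654$ mg/ml which error messages
name explicitly. The forward/inverse pair is consistent to 1e-10 over
50–500 mg/ml. Volume bookkeeping is purely proportional
($V_\mathrm{new}/V_\mathrm{ref} = c_\mathrm{ref}/c_\mathrm{new}$ at fixed
molecule count); only per-pair ratios are reported, since any cross-sample
averaging convention would be arbitrary. The hydrodynamic function
$H = D/D_0$ can be compared with the colloidal hard-sphere short-time
prediction $H = 1 - 1.831\phi$.

## Synthetic data: what it emulates, what it does not

The generators are pure functions of (truth, seed), with one named
substream per component (signal, buffer, per-q spectra) so adding a
component never shifts another draw. They emulate: log-spaced Bonse–Hart
grids (2e-5–2e-3 Å⁻¹) with multiplicative 2% noise and optional slit
smearing; SANS grids (0.01–0.45 Å⁻¹) with counting-statistics noise scaled
to 3% relative error at the interaction peak; and backscattering spectra on
the 0.34–1.92 Å⁻¹, ±31 µeV (0.2 µeV bins) grid — or the restricted ±20 µeV,
0.3 µeV variant — with a 1.0 µeV FWHM Gaussian resolution and Poisson
counts set so the elastic-peak relative error is ~2%, emulating overnight
runs. Recorded noise levels are honest: the generating model's reduced
$\chi^2$ against its own noisy output is 1.0 ± 0.15 across seeds.

They do **not** emulate: rocking-curve reduction or absolute calibration,
wavelength-spread smearing, multiple scattering, detector-angle geometry,
atomic-detail form factors (the sphere stands in for the protein envelope),
attractive Hb–Hb interactions, or the high-q deviations of real structure
factors from the screened-hard-sphere model. Passing recovery tests
therefore establishes the correctness and statistical calibration of the
estimators under the stated models — not that those models exhaust the
physics of real RBC data.

## Problem sizes and reproducibility

The test suite and the analysis scripts use 120-point curves, 8–10 spectra
of ~310 bins per QENS sample, 25-seed recovery studies for the SANS and
QENS estimators, 50-seed noise-calibration and 100-seed coverage checks —
sizes chosen so the statistical contracts (RMS errors, 2σ recovery rates,
coverage bands) are measured rather than asserted while the whole suite
stays desk-scale. All randomness flows through explicit integer seeds; the
acceptance script (`scripts/acceptance.R`) recomputes the four diffusion-to-
concentration inversions from scratch at any seed, and the full-chain
report is byte-identical under a repeated (config, seed) pair.

## Known limitations

* The MSA/RMSA route covers repulsive Yukawa interactions only; attractive
  contributions (suggested by the high-q deviation flag the SANS fit
  records) are out of scope.
* USANS cell volumes from packed suspensions are systematically low (by
  about 5× for the shrunken-cell state); the package reports the naive
  value and the caveat, no correction.
* The joint SANS parameter space is ill-conditioned when $R_\mathrm{eff}$
  is free at realistic noise; fix it (as done for the human samples) when
  absolute volume fractions matter.
* Per-q QENS fits are independent; a global-in-q fit with shared
  $D_\mathrm{eff}$ would propagate information across detectors but is off
  by default to match the per-q analysis convention.
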