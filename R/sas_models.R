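#' Parameters of the correlation-peak ("Butler empirical") USANS model
#'
#' @param I0 peak intensity scale (> 0); the model attains exactly `I0` at
#'   the correlation peak q* = 2 pi / xi.
#' @param alpha dimensionless scaling parameter in (0, 1); the high-q plateau
#'   of the model is `I0 * alpha`.
#' @param xi correlation length. Any length unit; must be reciprocal to the
#'   unit of q passed to [butler_empirical()] (micron curves fitted on 1/A
#'   grids use xi in angstrom internally).
#' @param d power-law coefficient, in \[1, 4.5\].
#' @return A `butler_params` list.
#' @export
butler_params <- function(I0, alpha, xi, d) {
  if (!is.finite(I0) || I0 <= 0) stopf("I0 must be > 0")
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1)
    stopf("alpha must lie strictly inside (0, 1)")
  if (!is.finite(xi) || xi <= 0) stopf("xi must be > 0")
  if (!is.finite(d) || d < 1 || d > 4.5) stopf("d must lie in [1, 4.5]")
  structure(list(I0 = I0, alpha = alpha, xi = xi, d = d),
            class = "butler_params")
}

#' Correlation-peak USANS model
#'
#' Empirical intensity model for curves with a single correlation peak
#' centred at q* = 2 pi / xi and power-law decay with exponent d at high q:
#' \deqn{I(q) = I_0 \frac{\alpha/(1-\alpha) + 2 x^{-d}}{1/(1-\alpha) + x^{-2d}},
#'   \quad x = q\xi/2\pi.}
#' At x = 1 the value is exactly I0; as q grows the model tends to I0 alpha.
#'
#' @param q momentum transfer, must be positive; reciprocal unit of `p$xi`.
#' @param p a [butler_params()].
#' @return Intensity vector.
#' @export
butler_empirical <- function(q, p) {
  stopifnot(inherits(p, "butler_params"))
  if (any(!is.finite(q)) || any(q <= 0)) stopf("q must be positive")
  x <- q * p$xi / (2 * pi)
  xd <- x^(-p$d)
  p$I0 * (p$alpha / (1 - p$alpha) + 2 * xd) / (1 / (1 - p$alpha) + xd^2)
}

#' Parameters of the generalized Guinier-Porod model
#'
#' Globular (dimensionality s = 0) variant: a Guinier regime
#' `scale * exp(-q^2 Rg^2 / 3)` joined to a Porod power law `~ q^-d` at the
#' crossover q1 = sqrt(3 d / 2) / Rg, with the power-law prefactor chosen so
#' that value and first derivative are continuous at q1.
#'
#' @param scale forward-scattering intensity (combined I0 G scale), > 0.
#' @param Rg radius of gyration (> 0); unit reciprocal to the q unit.
#' @param d Porod exponent, > 0.
#' @return A `guinier_porod_params` list with the derived crossover `q1`.
#' @export
guinier_porod_params <- function(scale, Rg, d) {
  if (!is.finite(scale) || scale <= 0) stopf("scale must be > 0")
  if (!is.finite(Rg) || Rg <= 0) stopf("Rg must be > 0")
  if (!is.finite(d) || d <= 0) stopf("d must be > 0")
  q1 <- sqrt(3 * d / 2) / Rg
  structure(list(scale = scale, Rg = Rg, d = d, q1 = q1),
            class = "guinier_porod_params")
}

#' Generalized Guinier-Porod intensity
#'
#' @param q momentum transfer, >= 0, reciprocal unit of `p$Rg`.
#' @param p a [guinier_porod_params()].
#' @return Intensity vector; continuous with continuous first derivative at
#'   the crossover `p$q1`.
#' @export
guinier_porod <- function(q, p) {
  stopifnot(inherits(p, "guinier_porod_params"))
  if (any(!is.finite(q)) || any(q < 0)) stopf("q must be >= 0")
  D <- p$scale * exp(-p$d / 2) * p$q1^p$d
  ifelse(q <= p$q1,
         p$scale * exp(-q^2 * p$Rg^2 / 3),
         D * q^(-p$d))
}

#' Normalized sphere form factor
#'
#' Squared Rayleigh amplitude of a homogeneous sphere,
#' \deqn{F(q) = \left[\frac{3(\sin qR - qR\cos qR)}{(qR)^3}\right]^2,}
#' normalized so that F(0) = 1. Used as the single-particle scattering
#' signature standing in for a tabulated protein form factor.
#'
#' @param q momentum transfer, reciprocal unit of `R`.
#' @param R sphere radius, > 0.
#' @return F(q) in \[0, 1\].
#' @export
sphere_form_factor <- function(q, R) {
  if (!is.finite(R) || R <= 0) stopf("R must be > 0")
  x <- q * R
  # below x ~ 0.05 the direct formula loses ~8 digits to cancellation in
  # sin(x) - x cos(x); the 3-term series is exact to ~1e-13 there
  amp <- ifelse(abs(x) < 0.05,
                1 - x^2 / 10 + x^4 / 280,
                3 * (sin(x) - x * cos(x)) / x^3)
  amp^2
}

#' Debye screening length from ionic strength
#'
#' Electrostatic screening length in water at 293 K,
#' kappa^-1 = 0.304 / sqrt(I) nanometre, returned in angstrom.
#'
#' @param ionic_strength molar ionic strength, > 0.
#' @return Debye length in angstrom.
#' @export
#' @examples
#' debye_length(0.15)  # 7.85 A
debye_length <- function(ionic_strength) {
  if (any(!is.finite(ionic_strength)) || any(ionic_strength <= 0))
    stopf("ionic strength must be > 0 (molar)")
  3.04 / sqrt(ionic_strength)
}

#' Charged-hard-sphere interaction state
#'
#' Describes the screened Coulomb (Yukawa) repulsion between protein
#' macro-ions: beta U(x) = gamma exp(-k x) / x for x = r/sigma > 1, with
#' contact potential gamma exp(-k) in units of kB T, dimensionless screening
#' k = sigma/kappa^-1, hard-core diameter sigma = 2 R_eff and volume
#' fraction phi.
#'
#' @param contact_potential contact value of the screened Coulomb repulsion,
#'   units of kB T, >= 0.
#' @param R_eff effective hard-core radius, angstrom (sigma = 2 R_eff).
#' @param phi hard-core volume fraction, in \[0, 0.74).
#' @param kappa_inv Debye screening length, angstrom. Defaults to
#'   `debye_length(ionic_strength)`.
#' @param ionic_strength molar ionic strength used when `kappa_inv` is not
#'   given (default 0.15 M, physiological saline).
#' @param T temperature, kelvin.
#' @param epsilon solvent dielectric constant (default 80, water near 293 K).
#' @return A `yukawa_interaction` list with fields `contact_potential`, `k`,
#'   `sigma_hc`, `phi`, `kappa_inv`, `T`, `epsilon`.
#' @export
yukawa_interaction <- function(contact_potential, R_eff, phi,
                               kappa_inv = NULL, ionic_strength = 0.15,
                               T = 293, epsilon = 80) {
  if (!is.finite(contact_potential) || contact_potential < 0)
    stopf("contact_potential must be >= 0")
  if (!is.finite(R_eff) || R_eff <= 0) stopf("R_eff must be > 0")
  if (!is.finite(phi) || phi < 0 || phi >= 0.74)
    stopf("phi must lie in [0, 0.74)")
  if (is.null(kappa_inv)) kappa_inv <- debye_length(ionic_strength)
  if (!is.finite(kappa_inv) || kappa_inv <= 0) stopf("kappa_inv must be > 0")
  sigma_hc <- 2 * R_eff
  structure(list(contact_potential = contact_potential,
                 k = sigma_hc / kappa_inv,
                 sigma_hc = sigma_hc, phi = phi, kappa_inv = kappa_inv,
                 T = T, epsilon = epsilon),
            class = "yukawa_interaction")
}

#' Effective macro-ion charge from the contact potential
#'
#' Inverts the screened Coulomb contact potential to the effective absolute
#' surface charge per macro-ion,
#' \deqn{Z = (2+k)\,\sqrt{\pi \varepsilon \varepsilon_0 \sigma\, U_c}/e,}
#' where U_c is the contact potential in joule, sigma the hard-core diameter
#' and k the dimensionless screening.
#'
#' @param y a [yukawa_interaction()].
#' @param const physical constants, see [physical_constants()].
#' @return Effective charge Z in elementary charges (>= 0).
#' @export
#' @examples
#' y <- yukawa_interaction(2.5, R_eff = 23.6, phi = 0.256, kappa_inv = 7.8)
#' charge_from_contact_potential(y)  # about 16 e
charge_from_contact_potential <- function(y, const = physical_constants()) {
  stopifnot(inherits(y, "yukawa_interaction"))
  U <- y$contact_potential * const$kB_J_K * y$T        # joule
  sigma_m <- y$sigma_hc * 1e-10
  (2 + y$k) * sqrt(pi * y$epsilon * const$eps0_F_m * sigma_m * U) / const$e_C
}

#' Composite SANS intensity model
#'
#' Forward model for a reduced SANS curve from a concentrated protein
#' suspension: a low-q power law for forward scattering plus a particle term
#' modulated by interparticle correlations,
#' \deqn{I(q) = I_1 q^{-d} + I_2 F(q) S(q).}
#'
#' @param q momentum transfer; must be nonzero when d > 0.
#' @param powerlaw list with `I1` (amplitude, >= 0) and `d` (exponent).
#' @param I2 form-factor scale.
#' @param F form factor values on `q`, normalized to F(0) = 1.
#' @param S structure factor values on `q`.
#' @return Intensity vector.
#' @export
composite_sans_intensity <- function(q, powerlaw, I2, F, S) {
  if (powerlaw$d > 0 && any(q == 0)) stopf("q = 0 invalid for a q^-d power law")
  powerlaw$I1 * q^(-powerlaw$d) + I2 * F * S
}
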