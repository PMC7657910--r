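# Closed-form crowded-solution relations for haemoglobin: concentration-
# dependent viscosity and self-diffusion of a concentrated protein solution
# (a Mooney-type hard-particle law), the inversion from a measured diffusion
# coefficient to protein concentration, and the hydrodynamic function.
# Concentrations are handled in g/l, numerically identical to mg/ml.

#' Crowding parameters for haemoglobin
#'
#' Intrinsic viscosity and self-crowding ratio entering the concentrated-
#' solution viscosity law, plus the dilute-limit diffusion coefficient.
#' Defaults are the neutron-spin-echo-derived haemoglobin values
#' (\[eta\] = 2.94e-3 l/g, k/v = 0.52); D0 defaults to the hydrodynamic-model
#' value at 288 K.
#'
#' @param intrinsic_viscosity intrinsic viscosity \[eta\], litres per gram.
#' @param k_over_v self-crowding factor divided by the Einstein coefficient,
#'   dimensionless (0.4 for ideal spheres at infinite dilution).
#' @param D0 dilute-limit diffusion coefficient, cm^2/s.
#' @param T_K temperature at which `D0` applies, kelvin.
#' @return A `crowding_params` list.
#' @export
crowding_params <- function(intrinsic_viscosity = 2.94e-3, k_over_v = 0.52,
                            D0 = 46.8e-8, T_K = 288) {
  if (intrinsic_viscosity <= 0 || k_over_v <= 0 || D0 <= 0)
    stopf("crowding parameters must be positive")
  structure(list(intrinsic_viscosity = intrinsic_viscosity,
                 k_over_v = k_over_v, D0 = D0, T_K = T_K),
            class = "crowding_params")
}

.c_max <- function(p) 1 / (p$k_over_v * p$intrinsic_viscosity)

#' Relative viscosity of a crowded protein solution
#'
#' \deqn{\eta(c)/\eta_0 = \exp\!\left(\frac{[\eta] c}{1 - (k/v) [\eta] c}\right)}
#' with a pole at c_max = 1 / ((k/v) \[eta\]) (about 654 mg/ml at the
#' haemoglobin defaults).
#'
#' @param c concentration, mg/ml (= g/l), below the pole.
#' @param p a [crowding_params()].
#' @return eta(c)/eta0, dimensionless.
#' @export
relative_viscosity <- function(c, p = crowding_params()) {
  stopifnot(inherits(p, "crowding_params"))
  cm <- .c_max(p)
  if (any(!is.finite(c)) || any(c < 0)) stopf("c must be >= 0")
  if (any(c >= cm))
    stopf("concentration %.4g mg/ml at or beyond the viscosity pole c_max = %.4g mg/ml",
          max(c), cm)
  x <- p$intrinsic_viscosity * c
  exp(x / (1 - p$k_over_v * x))
}

#' Self-diffusion coefficient at concentration
#'
#' D(c) = D0 / (eta(c)/eta0), the crowded-solution slow-down of protein
#' self-diffusion.
#'
#' @inheritParams relative_viscosity
#' @return D(c) in cm^2/s.
#' @export
diffusion_at_concentration <- function(c, p = crowding_params()) {
  p$D0 / relative_viscosity(c, p)
}

#' Invert a measured diffusion coefficient to protein concentration
#'
#' Solves the crowded-solution diffusion law for concentration:
#' \deqn{c = \frac{\ln(D_0/D)}{\ln(D_0/D)\,(k/v)\,[\eta] + [\eta]}.}
#' The measured apparent coefficient is first divided by `rotation_factor`
#' (1.27 for spherical particles) to remove the rotational contribution
#' contained in a quasi-elastic line width.
#'
#' @param D_measured_eff apparent diffusion coefficient from QENS, cm^2/s.
#' @param p a [crowding_params()] (supplies D0 and the viscosity law).
#' @param rotation_factor ratio of apparent to centre-of-mass diffusion
#'   (default 1.27, spherical particles; set to 1 for a coefficient that is
#'   already translational).
#' @return Concentration in mg/ml.
#' @export
#' @examples
#' concentration_from_diffusion(10.0e-8, crowding_params(D0 = 46.8e-8))  # ~315
concentration_from_diffusion <- function(D_measured_eff, p = crowding_params(),
                                         rotation_factor = physical_constants()$rotation_factor) {
  stopifnot(inherits(p, "crowding_params"))
  if (any(!is.finite(D_measured_eff)) || any(D_measured_eff <= 0))
    stopf("D_measured_eff must be > 0")
  D <- D_measured_eff / rotation_factor
  if (any(D > p$D0))
    stopf("rotation-corrected D = %.4g cm^2/s exceeds D0 = %.4g cm^2/s (would imply negative concentration)",
          max(D), p$D0)
  L <- log(p$D0 / D)
  L / (L * p$k_over_v * p$intrinsic_viscosity + p$intrinsic_viscosity)
}

#' Hydrodynamic function
#'
#' H(c) = D(c)/D0, the crowding-induced slow-down of self-diffusion relative
#' to infinite dilution.
#'
#' @param D diffusion coefficient at concentration, cm^2/s.
#' @param D0 dilute-limit diffusion coefficient, cm^2/s.
#' @return H, dimensionless.
#' @export
hydrodynamic_function <- function(D, D0) {
  if (any(D <= 0) || any(D0 <= 0)) stopf("D and D0 must be > 0")
  D / D0
}

#' Hard-sphere short-time hydrodynamic function
#'
#' Leading-order colloidal hard-sphere prediction H = 1 - 1.831 phi for the
#' short-time self-diffusion slow-down at volume fraction phi.
#'
#' @param phi volume fraction in \[0, 1/1.831\].
#' @return H, dimensionless, >= 0.
#' @export
hard_sphere_H <- function(phi) {
  if (any(!is.finite(phi)) || any(phi < 0) || any(phi > 1 / 1.831))
    stopf("phi must lie in [0, %.4g] for a non-negative hard-sphere H", 1 / 1.831)
  1 - 1.831 * phi
}

#' Fractional cell-volume change from two concentrations
#'
#' With a fixed number of haemoglobin molecules per cell, concentration is
#' inversely proportional to cell volume, so the fractional volume change of
#' a state with concentration `c_new` relative to the reference `c_ref` is
#' c_ref/c_new - 1 (positive = expansion).
#'
#' @param c_ref reference-state concentration, mg/ml.
#' @param c_new perturbed-state concentration, mg/ml.
#' @return Fractional volume change.
#' @export
volume_change <- function(c_ref, c_new) {
  if (any(c_ref <= 0) || any(c_new <= 0)) stopf("concentrations must be > 0")
  c_ref / c_new - 1
}

#' Expected haemoglobin concentration after full cell lysis
#'
#' Diluting the intracellular content of packed cells at haematocrit `hct`
#' into the full suspension volume gives hct * c_cell.
#'
#' @param haematocrit volume fraction of cells in the suspension, (0, 1\].
#' @param c_cell intracellular concentration, mg/ml.
#' @return Expected lysate concentration, mg/ml.
#' @export
expected_lysate_concentration <- function(haematocrit, c_cell) {
  if (any(haematocrit <= 0) || any(haematocrit > 1))
    stopf("haematocrit must lie in (0, 1]")
  haematocrit * c_cell
}
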