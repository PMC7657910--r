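#' Physical constants used throughout the package
#'
#' Returns the fixed physical constants used by the scattering and crowding
#' calculations. Values follow the 2019 SI redefinition (CODATA 2018).
#'
#' @return A named list with components:
#' \describe{
#'   \item{hbar_eV_s}{reduced Planck constant, eV s.}
#'   \item{hbar_ueV_s}{reduced Planck constant, micro-eV s (used for
#'     converting quasi-elastic line widths to diffusion coefficients).}
#'   \item{hbar_ueV_ps}{reduced Planck constant, micro-eV ps (used for
#'     correlation times).}
#'   \item{kB_J_K}{Boltzmann constant, J/K.}
#'   \item{e_C}{elementary charge, C.}
#'   \item{eps0_F_m}{vacuum permittivity, F/m.}
#'   \item{upsilon_ml_g}{partial specific volume of haemoglobin, ml/g.}
#'   \item{rotation_factor}{ratio of the apparent QENS diffusion coefficient
#'     to pure centre-of-mass self-diffusion for uncorrelated rotational and
#'     translational diffusion of a spherical particle.}
#' }
#' @export
#' @examples
#' physical_constants()$hbar_ueV_ps  # 658.2119569
physical_constants <- function() {
  list(
    hbar_eV_s   = 6.582119569e-16,
    hbar_ueV_s  = 6.582119569e-10,
    hbar_ueV_ps = 658.2119569,
    kB_J_K      = 1.380649e-23,
    e_C         = 1.602176634e-19,
    eps0_F_m    = 8.8541878128e-12,
    upsilon_ml_g = 0.75,
    rotation_factor = 1.27
  )
}

# internal shorthand
.const <- physical_constants()

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

#' @noRd
trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

# Gauss-Legendre nodes/weights on [-1, 1] via Golub-Welsch
#' @noRd
gauss_legendre <- function(n) {
  if (n == 1) return(list(x = 0, w = 2))
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(x = e$values[ord], w = 2 * e$vectors[1, ord]^2)
}
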