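# Slit smearing and iterative desmearing for Bonse-Hart (USANS) curves.
#
# The infinite-slit forward operator with sharp cutoff dq_v is
#   I_s(q) = (1/dq_v) int_0^dq_v I(sqrt(q^2 + u^2)) du,
# evaluated by fixed-order Gauss-Legendre quadrature. Smearing a measured
# curve requires intensities slightly beyond its q range; a power law fitted
# to the high-q tail provides the extrapolation.

# interpolator for a measured curve: log-log spline inside the range,
# fitted q^-d power law beyond it
.curve_interpolator <- function(curve, tail_points = 10) {
  q <- curve$q; I <- curve$I
  if (any(I <= 0))
    stopf("curve interpolation requires positive intensities")
  lq <- log(q); lI <- log(I)
  n <- length(q)
  tp <- max(3, min(tail_points, n))
  tail_fit <- stats::lm.fit(cbind(1, lq[(n - tp + 1):n]), lI[(n - tp + 1):n])
  tail_d <- -tail_fit$coefficients[2]
  tail_A <- exp(tail_fit$coefficients[1])
  sp <- stats::splinefun(lq, lI, method = "natural")
  function(qq) {
    out <- numeric(length(qq))
    inside <- qq <= q[n]
    out[inside] <- exp(sp(log(qq[inside])))
    out[!inside] <- tail_A * qq[!inside]^(-tail_d)
    out
  }
}

#' Slit-smear a point-resolved scattering curve
#'
#' Applies the infinite-slit smearing kernel with sharp vertical cutoff
#' `dq_v` to a point-resolved curve or model function, emulating Bonse-Hart
#' camera optics.
#'
#' @param curve a point-resolved [sas_curve()], or a function `I(q)` (in
#'   which case `q_grid` must be supplied).
#' @param dq_v vertical slit half-width, same reciprocal unit as q.
#' @param q_grid evaluation grid when `curve` is a function.
#' @param n_quad Gauss-Legendre order for the kernel integral.
#' @param tail_points number of trailing points used for the power-law tail
#'   extrapolation when smearing a measured curve.
#' @return A slit-smeared [sas_curve()] (`smeared = TRUE`, `dq_v` recorded).
#' @export
slit_smear <- function(curve, dq_v, q_grid = NULL, n_quad = 64,
                       tail_points = 10) {
  if (!is.finite(dq_v) || dq_v <= 0) stopf("dq_v must be > 0")
  if (is.function(curve)) {
    if (is.null(q_grid)) stopf("q_grid required when smearing a model function")
    fI <- curve
    q <- q_grid
    sig <- rep(0, length(q))
  } else {
    stopifnot(inherits(curve, "sas_curve"))
    if (curve$smeared) stopf("curve is already slit-smeared")
    fI <- .curve_interpolator(curve, tail_points)
    q <- curve$q
    sig <- curve$sigma
  }
  gl <- gauss_legendre(n_quad)
  u <- dq_v / 2 * (gl$x + 1)
  w <- gl$w / 2                      # weights for the mean over (0, dq_v)
  Is <- vapply(q, function(qq) sum(w * fI(sqrt(qq^2 + u^2))), numeric(1))
  out <- sas_curve(q, Is, sig, smeared = TRUE, dq_v = dq_v,
                   units = if (is.function(curve)) "1/A" else curve$units)
  out
}

#' Desmear a slit-smeared curve (Lake's iterative algorithm)
#'
#' Multiplicative fixed-point iteration
#' `I_{n+1}(q) = I_n(q) * I_meas(q) / Smear(I_n)(q)`, started from the
#' measured curve and stopped when the reduced chi-square between the
#' re-smeared iterate and the measurement falls below `chi2_tol`, or after
#' `max_iter` iterations (in which case the best iterate is returned with a
#' warning and `converged = FALSE`).
#'
#' @param curve a slit-smeared [sas_curve()] with `dq_v` set (or `dq_v`
#'   passed explicitly).
#' @param dq_v slit half-width; defaults to the curve's metadata.
#' @param max_iter maximum number of Lake iterations.
#' @param chi2_tol reduced chi-square stopping threshold.
#' @param pseudo_sigma_frac relative uncertainty assumed when the curve
#'   carries no sigma column (noiseless model curves), used only to form the
#'   convergence statistic.
#' @param clip_negative clip negative intermediate intensities to a small
#'   positive floor (required by the multiplicative update).
#' @return A point-resolved [sas_curve()] with attributes `iterations`,
#'   `chi2_red` and `converged`.
#' @export
lake_desmear <- function(curve, dq_v = NULL, max_iter = 200, chi2_tol = 1.05,
                         pseudo_sigma_frac = 5e-4, clip_negative = TRUE) {
  stopifnot(inherits(curve, "sas_curve"))
  if (!curve$smeared) stopf("lake_desmear expects a slit-smeared curve")
  dq_v <- dq_v %||% curve$dq_v
  if (is.null(dq_v) || !is.finite(dq_v) || dq_v <= 0)
    stopf("slit half-width dq_v unavailable")
  Imeas <- curve$I
  sig <- curve$sigma
  if (all(sig == 0)) sig <- pmax(abs(Imeas) * pseudo_sigma_frac, 1e-300)
  cur <- Imeas
  if (clip_negative) cur <- pmax(cur, 1e-12 * max(abs(Imeas)))
  chi2 <- Inf
  it <- 0L
  smear_vec <- function(I) {
    cv <- sas_curve(curve$q, I, units = curve$units)
    slit_smear(cv, dq_v)$I
  }
  repeat {
    it <- it + 1L
    sm <- smear_vec(cur)
    chi2 <- mean(((sm - Imeas) / sig)^2)
    if (chi2 < chi2_tol || it >= max_iter) break
    cur <- cur * Imeas / sm
    if (clip_negative) cur <- pmax(cur, 1e-12 * max(abs(Imeas)))
  }
  converged <- chi2 < chi2_tol
  if (!converged)
    warnf("Lake desmearing stopped at chi2_red = %.3g after %d iterations", chi2, it)
  out <- sas_curve(curve$q, cur, curve$sigma, smeared = FALSE,
                   units = curve$units)
  attr(out, "iterations") <- it
  attr(out, "chi2_red") <- chi2
  attr(out, "converged") <- converged
  out
}
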