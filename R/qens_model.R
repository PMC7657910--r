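# QENS spectral model: internal protein motion convolved with global
# diffusion gives a two-Lorentzian dynamic structure factor
#   S_total(q, w) = A0(q) L(G_G) + (1 - A0(q)) L(G_G + G_I),
# each L a unit-area Lorentzian in energy transfer (HWHM in ueV), plus a
# linear background. Fitted models are numerically convolved with the
# measured instrumental resolution function.

#' QENS spectrum container
#'
#' S(q, omega) for a single scattering vector on a fixed energy-transfer
#' grid, with uncertainties and a companion resolution spectrum measured on
#' a vanadium-like standard. The resolution is normalized to unit area on
#' its grid at construction.
#'
#' @param q scattering vector, 1/A.
#' @param omega energy-transfer grid, ueV; strictly increasing, spanning an
#'   approximately symmetric window.
#' @param S measured intensity per omega bin.
#' @param sigma 1-sigma uncertainties on `S`.
#' @param resolution resolution spectrum on the same grid (vector), or a
#'   list `list(omega=, R=)` on its own grid.
#' @return A `qens_spectrum` object.
#' @export
qens_spectrum <- function(q, omega, S, sigma, resolution) {
  omega <- as.numeric(omega)
  if (any(diff(omega) <= 0)) stopf("omega must be strictly increasing")
  if (length(S) != length(omega) || length(sigma) != length(omega))
    stopf("S/sigma length mismatch with omega")
  if (any(!is.finite(S))) stopf("S must be finite")
  if (any(sigma < 0)) stopf("sigma must be >= 0")
  if (is.list(resolution)) {
    r_om <- as.numeric(resolution$omega); r_S <- as.numeric(resolution$R)
  } else {
    r_om <- omega; r_S <- as.numeric(resolution)
  }
  if (length(r_S) != length(r_om)) stopf("resolution grid mismatch")
  area <- trapz(r_om, r_S)
  if (!is.finite(area) || area <= 0) stopf("resolution must have positive area")
  structure(list(q = q, omega = omega, S = S, sigma = sigma,
                 res_omega = r_om, res = r_S / area,
                 negative_bins = any(S < 0)),
            class = "qens_spectrum")
}

#' @export
print.qens_spectrum <- function(x, ...) {
  cat(sprintf("<qens_spectrum> q = %.3g 1/A, %d bins, omega in [%.3g, %.3g] ueV\n",
              x$q, length(x$omega), min(x$omega), max(x$omega)))
  invisible(x)
}

# unit-area Lorentzian of HWHM Gamma (ueV) on energy grid omega (ueV)
.lorentzian <- function(omega, Gamma) {
  Gamma / (pi * (Gamma^2 + omega^2))
}

#' Two-Lorentzian QENS model (unconvolved)
#'
#' Evaluates
#' `scale * (A0 L(Gamma_G) + (1 - A0) L(Gamma_G + Gamma_I)) + bkg_a + bkg_b * omega`
#' with unit-area Lorentzians of the given half-widths at half-maximum. The
#' narrow width carries global protein diffusion; the broad width adds the
#' internal relaxation rate.
#'
#' @param omega energy transfer, ueV.
#' @param params list with `A0` in \[0,1\], `Gamma_G` >= 0 and `Gamma_I` >= 0
#'   (ueV), `scale`, and optional `bkg_a`, `bkg_b` (linear background).
#' @return Intensity on `omega`.
#' @export
model_total_sqw <- function(omega, params) {
  p <- params
  if (p$A0 < 0 || p$A0 > 1) stopf("A0 must lie in [0, 1]")
  if (p$Gamma_G < 0 || p$Gamma_I < 0) stopf("line widths must be >= 0")
  if (p$Gamma_G == 0) stopf("unconvolved model requires Gamma_G > 0 (elastic line is a delta)")
  a <- p$bkg_a %||% 0
  b <- p$bkg_b %||% 0
  p$scale * (p$A0 * .lorentzian(omega, p$Gamma_G) +
               (1 - p$A0) * .lorentzian(omega, p$Gamma_G + p$Gamma_I)) +
    a + b * omega
}

#' Convolve a spectral model with the instrumental resolution
#'
#' Evaluates `model` on an internally oversampled energy grid extending
#' beyond the data window by at least `pad_widths` resolution widths,
#' convolves it with the unit-area resolution lineshape (trapezoid-weighted
#' discrete convolution) and resamples onto `omega_out`. A linear background
#' is invariant under a symmetric unit-area kernel, so backgrounds may be
#' added before or after convolution interchangeably.
#'
#' @param model function of omega, or a list of model values already on the
#'   fine grid returned by a previous call.
#' @param resolution list `list(omega=, R=)` (any normalization; re-normalized
#'   to unit area internally), e.g. the `res_omega`/`res` fields of a
#'   [qens_spectrum()].
#' @param omega_out output (data) grid, ueV.
#' @param oversample fine-grid refinement factor relative to the output bin.
#' @param pad_widths window extension in units of the resolution FWHM.
#' @return Convolved model on `omega_out`.
#' @export
convolve_resolution <- function(model, resolution, omega_out, oversample = 4,
                                pad_widths = 12) {
  r_om <- resolution$omega; rS <- resolution$R %||% resolution$res
  area <- trapz(r_om, rS)
  rS <- rS / area
  # FWHM estimate of the resolution for padding
  half <- max(rS) / 2
  above <- which(rS >= half)
  fwhm <- max(r_om[max(above)] - r_om[min(above)], diff(range(r_om)) / 20)
  h <- min(diff(omega_out)) / oversample
  pad <- pad_widths * fwhm
  fine <- seq(min(omega_out) - pad, max(omega_out) + pad, by = h)
  m <- if (is.function(model)) model(fine) else model
  if (length(m) != length(fine)) stopf("model values do not match the fine grid")
  # resolution on a symmetric fine grid (zero outside its support)
  rmax_half <- max(abs(r_om))
  nk <- floor(rmax_half / h)
  kg <- (-nk:nk) * h
  kern <- stats::spline(r_om, rS, xout = kg)$y
  kern[kg < min(r_om) | kg > max(r_om)] <- 0
  kern <- pmax(kern, 0)                   # guard against spline undershoot
  kern <- kern / (sum(kern) * h)          # discrete unit area
  cm <- stats::convolve(m, rev(kern), type = "open") * h
  # "open" convolution has length n + 2*nk - ... alignment: index shift nk
  cm <- cm[(nk + 1):(nk + length(fine))]
  stats::spline(fine, cm, xout = omega_out)$y
}

#' Subtract a scaled buffer spectrum
#'
#' S_out = S_sample - scale * S_buffer on identical grids; uncertainties add
#' in quadrature. Negative bins are retained (flagged, not clipped).
#'
#' @param sample a [qens_spectrum()].
#' @param buffer a [qens_spectrum()] on the same omega grid.
#' @param scale buffer scale factor (transmission/volume-fraction weighting;
#'   default 1).
#' @return A [qens_spectrum()] with the buffer removed.
#' @export
subtract_buffer <- function(sample, buffer, scale = 1) {
  stopifnot(inherits(sample, "qens_spectrum"), inherits(buffer, "qens_spectrum"))
  if (length(sample$omega) != length(buffer$omega) ||
      max(abs(sample$omega - buffer$omega)) > 1e-9)
    stopf("sample and buffer energy grids differ")
  out <- qens_spectrum(sample$q, sample$omega,
                       sample$S - scale * buffer$S,
                       sqrt(sample$sigma^2 + scale^2 * buffer$sigma^2),
                       list(omega = sample$res_omega, R = sample$res))
  out
}
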