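# Per-q QENS fitting and the derived dynamical quantities: global diffusion
# coefficient from the narrow-width dispersion Gamma_G = hbar D q^2, internal
# correlation time tau = hbar / <Gamma_I>, and the Gaussian-confinement EISF.

#' Fit a QENS spectrum (per q) with the resolution-convolved model
#'
#' Bounded weighted least squares of the convolved two-Lorentzian model (see
#' [model_total_sqw()] and [convolve_resolution()]) against a measured
#' spectrum, including a linear background. The constraint Gamma_I >= 0
#' orders the two Lorentzians by construction (the broad one is narrow +
#' internal), removing the label-switching ambiguity.
#'
#' @param spectrum a [qens_spectrum()] (>= 50 energy bins).
#' @param init optional named starting values
#'   (`A0, Gamma_G, Gamma_I, scale, bkg_a, bkg_b`).
#' @param oversample,pad_widths convolution controls, see
#'   [convolve_resolution()].
#' @return A `per_q_fit` list: `q`, `par` (named estimates), `se`
#'   (1-sigma uncertainties), `chi2_red`, `converged`.
#' @export
fit_spectrum <- function(spectrum, init = NULL, oversample = 4,
                         pad_widths = 12) {
  stopifnot(inherits(spectrum, "qens_spectrum"))
  om <- spectrum$omega
  if (length(om) < 50) stopf("need at least 50 energy bins")
  S <- spectrum$S
  sig <- spectrum$sigma
  w <- if (all(sig == 0)) rep(1, length(S)) else 1 / pmax(sig, 1e-300)
  resolution <- list(omega = spectrum$res_omega, R = spectrum$res)
  # precompute the fine grid/kernel once per spectrum by closing over
  # convolve_resolution's internals via a model function
  area0 <- trapz(om, S)
  st <- list(A0 = 0.7, Gamma_G = 0.5, Gamma_I = 3, scale = max(area0, 1e-12),
             bkg_a = max(min(S), 0), bkg_b = 0)
  if (!is.null(init)) for (nm in intersect(names(init), names(st))) st[[nm]] <- init[[nm]]
  lower <- c(A0 = 0, Gamma_G = 1e-4, Gamma_I = 0, scale = 1e-12,
             bkg_a = -Inf, bkg_b = -Inf)
  upper <- c(A0 = 1, Gamma_G = 50, Gamma_I = 500, scale = Inf,
             bkg_a = Inf, bkg_b = Inf)
  fn <- function(p) {
    mod <- function(x) {
      p <- as.list(p)
      p$scale * (p$A0 * .lorentzian(x, p$Gamma_G) +
                   (1 - p$A0) * .lorentzian(x, p$Gamma_G + p$Gamma_I))
    }
    conv <- convolve_resolution(mod, resolution, om, oversample, pad_widths)
    (S - (conv + p[["bkg_a"]] + p[["bkg_b"]] * om)) * w
  }
  run_lm <- function(start) {
    minpack.lm::nls.lm(par = start, fn = fn, lower = lower, upper = upper,
                       control = minpack.lm::nls.lm.control(maxiter = 300))
  }
  fit <- run_lm(unlist(st))
  if (!is.null(init)) {
    # label-switching guard: also try the start with the narrow/broad roles
    # of the two widths exchanged and keep the better optimum
    st2 <- st
    st2$Gamma_G <- min(st$Gamma_G, st$Gamma_I)
    st2$Gamma_I <- abs(st$Gamma_I - st$Gamma_G)
    fit2 <- run_lm(unlist(st2))
    if (fit2$deviance < fit$deviance) fit <- fit2
  }
  converged <- !(fit$info %in% c(0, 9)) && all(is.finite(fit$par))
  res <- fn(fit$par)
  dof <- max(length(S) - length(fit$par), 1)
  chi2_red <- sum(res^2) / dof
  cv <- tryCatch(chi2_red * solve(fit$hessian), error = function(e) NULL)
  se <- if (is.null(cv)) rep(NA_real_, length(fit$par)) else sqrt(pmax(diag(cv), 0))
  names(se) <- names(fit$par)
  structure(list(q = spectrum$q, par = as.list(fit$par), se = as.list(se),
                 chi2_red = chi2_red, converged = converged),
            class = "per_q_fit")
}

#' Fit all spectra of a q series
#'
#' Independent per-q fits (see [fit_spectrum()]); non-converged q values are
#' flagged and excluded from downstream summaries.
#'
#' @param spectra list of [qens_spectrum()] objects.
#' @param ... passed to [fit_spectrum()].
#' @return List of `per_q_fit` objects with attribute `failed_q`.
#' @export
fit_spectra <- function(spectra, ...) {
  fits <- lapply(spectra, function(sp) {
    tryCatch(fit_spectrum(sp, ...), error = function(e) {
      structure(list(q = sp$q, par = NULL, se = NULL, chi2_red = NA_real_,
                     converged = FALSE, error = conditionMessage(e)),
                class = "per_q_fit")
    })
  })
  attr(fits, "failed_q") <- vapply(fits[!vapply(fits, `[[`, TRUE, "converged")],
                                   `[[`, numeric(1), "q")
  fits
}

#' Global diffusion coefficient from the narrow-width dispersion
#'
#' Error-weighted straight-line fit through the origin of Gamma_G versus
#' q^2; the slope is hbar D_eff, converted to cm^2/s. The apparent
#' coefficient D_eff contains rotational and translational diffusion; the
#' translational part is D_eff / 1.27 for spherical particles.
#'
#' @param Gamma_G narrow half-widths at half-maximum, ueV (>= 4 values).
#' @param q scattering vectors, 1/A.
#' @param se optional 1-sigma uncertainties on `Gamma_G` (equal weights if
#'   absent or zero).
#' @param T_K sample temperature, kelvin (recorded).
#' @param rotation_factor apparent-to-translational ratio (default 1.27).
#' @param intercept include a free intercept (diagnostic option; default
#'   FALSE, the dispersion law passes through the origin).
#' @return A `diffusion_result` list: `D_eff` and `D_trans` (cm^2/s), their
#'   standard errors, `slope` (ueV A^2), `T_K`, `chi2_red`.
#' @export
fit_global_diffusion <- function(Gamma_G, q, se = NULL, T_K = 288,
                                 rotation_factor = physical_constants()$rotation_factor,
                                 intercept = FALSE) {
  ok <- is.finite(Gamma_G) & is.finite(q)
  use_w <- !is.null(se) && any(is.finite(se) & se > 0)
  if (use_w) ok <- ok & is.finite(se) & se > 0
  Gamma_G <- Gamma_G[ok]; q <- q[ok]
  if (!is.null(se)) se <- se[ok]
  if (length(Gamma_G) < 4) stopf("need at least 4 usable q points")
  w <- if (use_w) 1 / se^2 else rep(1, length(q))
  x <- q^2
  if (intercept) {
    fit <- stats::lm(Gamma_G ~ x, weights = w)
    slope <- stats::coef(fit)[["x"]]
    slope_se <- summary(fit)$coefficients["x", "Std. Error"]
    dof <- length(x) - 2
  } else {
    slope <- sum(w * Gamma_G * x) / sum(w * x^2)
    slope_se <- sqrt(1 / sum(w * x^2))
    dof <- length(x) - 1
  }
  hbar <- physical_constants()$hbar_ueV_s
  D_A2s <- slope / hbar                     # A^2/s
  D_eff <- D_A2s * 1e-16                    # cm^2/s
  resid <- Gamma_G - slope * x
  chi2_red <- sum(w * resid^2) / max(dof, 1)
  if (!use_w) slope_se <- slope_se * sqrt(chi2_red)
  structure(list(D_eff = D_eff, D_eff_se = slope_se / hbar * 1e-16,
                 D_trans = D_eff / rotation_factor,
                 rotation_factor = rotation_factor,
                 slope_ueV_A2 = slope, T_K = T_K, chi2_red = chi2_red,
                 n_points = length(x)),
            class = "diffusion_result")
}

#' Internal correlation time from the internal line widths
#'
#' The internal width Gamma_I(q) of localized motion is flat in q^2 within
#' error; its error-weighted mean <Gamma> converts to a correlation time
#' tau = hbar / <Gamma> in picoseconds. A regression of Gamma_I on q^2 is
#' performed first and its p-value reported as the flatness diagnostic.
#'
#' @param Gamma_I internal half-widths, ueV (at least one finite value).
#' @param q scattering vectors, 1/A (needed for the flatness check).
#' @param se optional 1-sigma uncertainties on `Gamma_I`.
#' @return An `internal_dynamics_result` list: `Gamma_mean` (ueV), `tau_ps`,
#'   `Gamma_mean_se`, `tau_ps_se`, `flat_p_value`.
#' @export
correlation_time <- function(Gamma_I, q = NULL, se = NULL) {
  ok <- is.finite(Gamma_I)
  use_w <- !is.null(se) && any(ok & is.finite(se) & se > 0)
  if (use_w) ok <- ok & is.finite(se) & se > 0
  if (!any(ok)) stopf("no finite internal widths")
  g <- Gamma_I[ok]
  w <- if (use_w) 1 / se[ok]^2 else rep(1, length(g))
  gm <- sum(w * g) / sum(w)
  gm_se <- sqrt(1 / sum(w))
  flat_p <- NA_real_
  if (!is.null(q) && sum(ok) >= 3) {
    x <- q[ok]^2
    fit <- stats::lm(g ~ x, weights = w)
    flat_p <- suppressWarnings(summary(fit)$coefficients["x", "Pr(>|t|)"])
  }
  hbar_ps <- physical_constants()$hbar_ueV_ps
  structure(list(Gamma_mean = gm, Gamma_mean_se = gm_se,
                 tau_ps = hbar_ps / gm,
                 tau_ps_se = hbar_ps / gm^2 * gm_se,
                 flat_p_value = flat_p),
            class = "internal_dynamics_result")
}

#' Gaussian-confinement EISF fit
#'
#' Weighted fit of the elastic incoherent structure factor of localized
#' motion with Gaussian statistics plus an immobile fraction,
#' \deqn{A_0(q) = (1-p)\,e^{-\langle x^2\rangle q^2} + p,}
#' with bounds <x^2> >= 0 and p in \[0, 1\].
#'
#' @param A0 EISF values in \[0, 1\] (>= 4 q points).
#' @param q scattering vectors, 1/A.
#' @param se optional 1-sigma uncertainties on `A0`.
#' @return List with `x2` (mean-square displacement, A^2), `p_immobile`,
#'   their standard errors, `chi2_red`, and a `degenerate` flag raised when
#'   the EISF is flat and <x^2> is unidentifiable.
#' @export
fit_eisf <- function(A0, q, se = NULL) {
  ok <- is.finite(A0) & is.finite(q)
  A0 <- A0[ok]; q <- q[ok]
  if (!is.null(se)) se <- se[ok]
  if (length(A0) < 4) stopf("need at least 4 q points")
  if (any(A0 < -0.05) || any(A0 > 1.05)) stopf("A0 must lie in [0, 1]")
  w <- if (is.null(se) || all(se == 0)) rep(1, length(A0)) else 1 / pmax(se, 1e-12)
  fn <- function(p) (A0 - ((1 - p[2]) * exp(-p[1] * q^2) + p[2])) * w
  # initial values from a log-linear fit of A0 - min(A0)
  p0 <- c(x2 = 0.5, p = max(min(A0) - 0.05, 0))
  fit <- minpack.lm::nls.lm(par = p0, fn = fn, lower = c(0, 0), upper = c(50, 1),
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  res <- fn(fit$par)
  dof <- max(length(A0) - 2, 1)
  chi2_red <- sum(res^2) / dof
  cv <- tryCatch(chi2_red * solve(fit$hessian), error = function(e) NULL)
  se_out <- if (is.null(cv)) c(NA_real_, NA_real_) else sqrt(pmax(diag(cv), 0))
  spread <- diff(range(A0))
  degenerate <- is.null(cv) || spread < 3 * stats::median(if (is.null(se)) 0 else se) ||
    (!is.null(cv) && se_out[1] > 10 * max(fit$par[1], 0.1))
  list(x2 = fit$par[[1]], p_immobile = fit$par[[2]],
       x2_se = se_out[1], p_se = se_out[2],
       chi2_red = chi2_red, degenerate = isTRUE(degenerate))
}

#' Mean-square displacement of a sphere-confined walker in the Gaussian model
#'
#' Diffusion confined to a sphere of radius r corresponds to a Gaussian-
#' confinement mean-square displacement <x^2> = r^2 / 5.
#'
#' @param r sphere radius, angstrom (>= 0).
#' @return <x^2> in A^2.
#' @export
sphere_to_gaussian_msd <- function(r) {
  if (any(r < 0)) stopf("r must be >= 0")
  r^2 / 5
}
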