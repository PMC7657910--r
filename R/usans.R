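# USANS morphology fits: correlation-peak (rouleaux) and generalized
# Guinier-Porod (shrunken spherical cells) models, with derived morphology
# quantities. Curves carry q in 1/A; correlation lengths and radii of
# gyration are reported in micrometres (1 um = 1e4 A), cell volumes in
# femtolitres (1 um^3 = 1 fl).

.UM_PER_A <- 1e-4

#' Effective sphere radius from a Guinier radius
#'
#' For a homogeneous sphere Rg^2 = (3/5) R^2, so R = sqrt(5/3) Rg.
#'
#' @param Rg radius of gyration (> 0), any length unit.
#' @return Sphere radius in the same unit.
#' @export
sphere_radius_from_rg <- function(Rg) {
  if (any(!is.finite(Rg)) || any(Rg <= 0)) stopf("Rg must be > 0")
  sqrt(5 / 3) * Rg
}

#' Sphere volume in femtolitres
#'
#' @param R sphere radius in micrometres.
#' @return Volume 4 pi R^3 / 3 in femtolitres (um^3 = fl).
#' @export
sphere_volume <- function(R) {
  if (any(!is.finite(R)) || any(R <= 0)) stopf("R must be > 0")
  4 * pi * R^3 / 3
}

# weighted residual helper shared by the USANS fits
.wres <- function(obs, model, sigma) {
  w <- if (all(sigma == 0)) rep(1, length(obs)) else 1 / pmax(sigma, 1e-300)
  (obs - model) * w
}

.aicc <- function(rss, n, k) {
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / max(n - k - 1, 1)
}

#' Fit a USANS curve with a morphology model
#'
#' Weighted (1/sigma^2) bounded least squares of either the correlation-peak
#' model ([butler_empirical()]) or the generalized Guinier-Porod model
#' ([guinier_porod()]) to a de-smeared USANS curve, with derived morphology
#' quantities: correlation length xi and peak position q* = 2 pi / xi for
#' the peak model; effective sphere radius sqrt(5/3) Rg and cell volume
#' 4 pi R^3/3 for the Guinier-Porod model.
#'
#' @param curve a point-resolved [sas_curve()] with q in 1/A (at least 10
#'   points spanning the peak or the Guinier knee).
#' @param model `"butler"` (correlation peak) or `"gp"` (Guinier-Porod).
#' @param init optional named list of starting values (`I0, alpha, xi_um, d`
#'   or `scale, Rg_um, d`); data-driven defaults otherwise (xi from the
#'   intensity argmax, Rg from a Guinier line on the lowest q decade).
#' @param bounds optional named list of length-2 vectors overriding the
#'   default parameter bounds.
#' @return A `usans_result` list: `model`, `params` (estimates with 1-sigma
#'   uncertainties, lengths in micrometres), derived fields (`xi`, `q_star`
#'   in reciprocal micrometres, or `R_eff_sphere` in um and `V_cell` in fl),
#'   `chi2_red`, `aicc` and a `peak_in_range` flag for the peak model.
#' @export
fit_usans <- function(curve, model = c("butler", "gp"), init = NULL,
                      bounds = NULL) {
  stopifnot(inherits(curve, "sas_curve"))
  model <- match.arg(model)
  if (curve$smeared)
    stopf("fit_usans expects a de-smeared curve (see lake_desmear)")
  q <- curve$q; I <- curve$I; sig <- curve$sigma
  if (length(q) < 10) stopf("need at least 10 points")
  if (model == "butler") {
    ipk <- which.max(I)
    xi0 <- 2 * pi / q[ipk]                       # A
    alpha0 <- min(max(I[length(I)] / I[ipk], 1e-3), 0.9)
    start <- list(I0 = I[ipk], alpha = alpha0, xi = xi0, d = 3.5)
    if (!is.null(init)) {
      init$xi <- if (!is.null(init$xi_um)) init$xi_um / .UM_PER_A else init$xi
      for (nm in intersect(names(init), names(start))) start[[nm]] <- init[[nm]]
    }
    lower <- c(I0 = 1e-12, alpha = 1e-6, xi = xi0 / 50, d = 1)
    upper <- c(I0 = Inf, alpha = 1 - 1e-6, xi = xi0 * 50, d = 4.5)
    fn <- function(p) {
      bp <- butler_params(p[1], p[2], p[3], p[4])
      .wres(I, butler_empirical(q, bp), sig)
    }
    par0 <- unlist(start)
  } else {
    nlow <- max(5L, sum(q <= min(q) * 10))       # lowest decade
    gfit <- stats::lm.fit(cbind(1, q[1:nlow]^2), log(pmax(I[1:nlow], 1e-300)))
    Rg0 <- sqrt(max(-3 * unname(gfit$coefficients[2]), 1e4))
    scale0 <- exp(unname(gfit$coefficients[1]))
    nl <- length(q)
    hi <- max(3L, floor(nl / 4))
    pfit <- stats::lm.fit(cbind(1, log(q[(nl - hi + 1):nl])),
                          log(pmax(I[(nl - hi + 1):nl], 1e-300)))
    d0 <- min(max(-unname(pfit$coefficients[2]), 1), 4.4)
    start <- list(scale = scale0, Rg = Rg0, d = d0)
    if (!is.null(init)) {
      init$Rg <- if (!is.null(init$Rg_um)) init$Rg_um / .UM_PER_A else init$Rg
      for (nm in intersect(names(init), names(start))) start[[nm]] <- init[[nm]]
    }
    lower <- c(scale = 1e-12, Rg = Rg0 / 100, d = 0.5)
    upper <- c(scale = Inf, Rg = Rg0 * 100, d = 10)
    fn <- function(p) {
      gp <- guinier_porod_params(p[1], p[2], p[3])
      .wres(I, guinier_porod(q, gp), sig)
    }
    par0 <- unlist(start)
  }
  if (!is.null(bounds)) {
    for (nm in names(bounds)) {
      lower[nm] <- bounds[[nm]][1]; upper[nm] <- bounds[[nm]][2]
    }
  }
  fit <- minpack.lm::nls.lm(par = par0, fn = fn, lower = lower, upper = upper,
                            control = minpack.lm::nls.lm.control(maxiter = 500))
  if (fit$info %in% c(0, 9))
    stopf("USANS fit did not converge (info = %d): %s", fit$info, fit$message)
  p <- fit$par
  res <- fn(p)
  npar <- length(p)
  dof <- max(length(q) - npar, 1)
  chi2_red <- sum(res^2) / dof
  # covariance-based 1-sigma uncertainties (scaled by sqrt(chi2_red) when
  # the curve carries real uncertainties)
  cv <- tryCatch(chi2_red * solve(fit$hessian), error = function(e) NULL)
  se <- if (is.null(cv)) rep(NA_real_, npar) else sqrt(pmax(diag(cv), 0))
  names(se) <- names(p)
  out <- list(model = model, chi2_red = chi2_red,
              aicc = .aicc(sum(res^2), length(q), npar),
              converged = TRUE)
  if (model == "butler") {
    xi_um <- p[["xi"]] * .UM_PER_A
    out$params <- list(I0 = p[["I0"]], alpha = p[["alpha"]], xi_um = xi_um,
                       d = p[["d"]])
    out$se <- list(I0 = se[["I0"]], alpha = se[["alpha"]],
                   xi_um = se[["xi"]] * .UM_PER_A, d = se[["d"]])
    out$xi <- xi_um
    out$q_star <- 2 * pi / xi_um                     # 1/um
    out$peak_in_range <- {
      qs_A <- 2 * pi / p[["xi"]]
      qs_A >= min(q) && qs_A <= max(q)
    }
    if (!out$peak_in_range)
      warnf("fitted correlation peak lies outside the measured q range")
  } else {
    Rg_um <- p[["Rg"]] * .UM_PER_A
    R_um <- sphere_radius_from_rg(Rg_um)
    out$params <- list(scale = p[["scale"]], Rg_um = Rg_um, d = p[["d"]])
    out$se <- list(scale = se[["scale"]], Rg_um = se[["Rg"]] * .UM_PER_A,
                   d = se[["d"]])
    out$R_eff_sphere <- R_um
    out$V_cell <- sphere_volume(R_um)
  }
  class(out) <- "usans_result"
  out
}

#' @export
print.usans_result <- function(x, ...) {
  if (x$model == "butler") {
    cat(sprintf("USANS correlation-peak fit: xi = %.3f um (q* = %.3f 1/um), d = %.2f, chi2_red = %.3g\n",
                x$xi, x$q_star, x$params$d, x$chi2_red))
  } else {
    cat(sprintf("USANS Guinier-Porod fit: Rg = %.3f um -> R = %.3f um, V = %.1f fl, d = %.2f, chi2_red = %.3g\n",
                x$params$Rg_um, x$R_eff_sphere, x$V_cell, x$params$d, x$chi2_red))
  }
  invisible(x)
}
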