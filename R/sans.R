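# SANS pipeline: composite-model fits of protein-suspension curves, the
# structure-factor extraction, conversion of volume fraction to protein
# concentration, and kinetic (time-series) fitting.

#' Form factor specification
#'
#' Either an analytic sphere (`sphere_form_factor(q, R)`) or a tabulated
#' normalized form factor interpolated cubically.
#'
#' @param spec `list(type = "sphere", R = <radius in A>)`, or
#'   `list(type = "table", q = <1/A>, F = <normalized>)`, or a
#'   [sas_curve()] holding the tabulated F(q).
#' @return A function F(q) normalized to F(0) = 1.
#' @export
form_factor_function <- function(spec) {
  if (inherits(spec, "sas_curve")) spec <- list(type = "table", q = spec$q, F = spec$I)
  if (identical(spec$type, "sphere")) {
    R <- spec$R
    if (!is.finite(R) || R <= 0) stopf("sphere form factor needs R > 0")
    return(function(q) sphere_form_factor(q, R))
  }
  if (identical(spec$type, "table")) {
    F0 <- spec$F[which.min(spec$q)]
    if (abs(F0 - 1) > 0.05)
      warnf("tabulated form factor not normalized at low q (F = %.3g); rescaling", F0)
    sp <- stats::splinefun(spec$q, spec$F / F0, method = "natural")
    return(function(q) pmax(sp(q), 0))
  }
  stopf("unknown form factor spec")
}

#' Extract an experimental structure factor from a SANS curve
#'
#' Subtracts the fitted power-law forward scattering and divides by the
#' scaled form factor:
#' `S_exp(q) = (I(q) - I1 q^-d) / (I2 F(q))`, with first-order error
#' propagation. The range is truncated (with a warning) before the first
#' form-factor zero, where the division is ill-posed.
#'
#' @param curve a [sas_curve()].
#' @param I1,d power-law amplitude and exponent.
#' @param I2 form-factor scale.
#' @param ff form factor: function of q or a spec for
#'   [form_factor_function()].
#' @param ff_floor smallest usable F(q) value (range truncation threshold).
#' @return A [sas_curve()] holding S_exp(q) with propagated uncertainties;
#'   attribute `truncated` reports whether the range was cut.
#' @export
extract_structure_factor <- function(curve, I1, d, I2, ff, ff_floor = 1e-3) {
  stopifnot(inherits(curve, "sas_curve"))
  Ffun <- if (is.function(ff)) ff else form_factor_function(ff)
  Fv <- Ffun(curve$q)
  bad <- which(Fv < ff_floor)
  keep <- seq_along(curve$q)
  truncated <- FALSE
  if (length(bad)) {
    keep <- seq_len(min(bad) - 1)
    truncated <- TRUE
    warnf("form factor falls below %.1e at q = %.4g; truncating the extraction range",
          ff_floor, curve$q[min(bad)])
    if (length(keep) < 2) stopf("no usable extraction range before the form-factor zero")
  }
  q <- curve$q[keep]
  S <- (curve$I[keep] - I1 * q^(-d)) / (I2 * Fv[keep])
  sig <- curve$sigma[keep] / (I2 * Fv[keep])
  out <- sas_curve(q, S, sig, units = curve$units)
  attr(out, "truncated") <- truncated
  out
}

#' Intracellular concentration from volume fraction
#'
#' c = phi / upsilon with the protein partial specific volume
#' upsilon = 0.75 ml/g, returned in mg/ml.
#'
#' @param phi volume fraction in \[0, 1).
#' @param upsilon partial specific volume, ml/g.
#' @return Concentration in mg/ml.
#' @export
#' @examples
#' concentration_from_phi(0.256)  # 341 mg/ml
concentration_from_phi <- function(phi, upsilon = physical_constants()$upsilon_ml_g) {
  if (any(phi < 0) || any(phi >= 1)) stopf("phi must lie in [0, 1)")
  phi / upsilon * 1000
}

#' Joint fit of the composite SANS model
#'
#' Bounded weighted least squares of
#' `I(q) = I1 q^-d + I2 F(q) S(q)` with the screened-Coulomb RMSA structure
#' factor (see [rmsa_structure_factor()]) over the parameters
#' `I1, d, I2, contact_potential, R_eff, phi` (R_eff optionally fixed), with
#' the Debye length held at the value set by the configured ionic strength.
#' Multi-start (jittered initializations) guards against the shallow
#' I1/I2 trade-off; RMSA coefficient solves are warm-started inside the
#' optimization.
#'
#' @param curve a [sas_curve()] covering the interaction peak
#'   (roughly 0.02-0.4 1/A for haemoglobin).
#' @param ff form factor (function or spec, see [form_factor_function()]).
#' @param init named list of starting values (defaults provided).
#' @param fix_reff fix R_eff at this value (angstrom) instead of fitting it.
#' @param ionic_strength molar ionic strength fixing the Debye length.
#' @param T_K,epsilon temperature and solvent dielectric constant (for the
#'   derived charge).
#' @param n_starts number of jittered multi-start initializations.
#' @param jitter_sd relative log-normal jitter applied to the starts.
#' @param cond_cap condition-number cap for the identifiability diagnostic.
#' @return A `sans_fit_result`: `par` (I1, d, I2, contact_potential, R_eff,
#'   phi), `se`, derived `Z` (elementary charges) and `c_mg_ml`, `yukawa`
#'   (the fitted [yukawa_interaction()]), `chi2_red`, `condition_number`,
#'   flags (`converged`, `phi_at_bound`, `high_q_deviation`).
#' @export
fit_sans <- function(curve, ff, init = NULL, fix_reff = NULL,
                     ionic_strength = 0.15, T_K = 293, epsilon = 80,
                     n_starts = 5, jitter_sd = 0.15, cond_cap = 1e8) {
  stopifnot(inherits(curve, "sas_curve"))
  Ffun <- if (is.function(ff)) ff else form_factor_function(ff)
  q <- curve$q; I <- curve$I; sig <- curve$sigma
  w <- if (all(sig == 0)) rep(1, length(I)) else 1 / pmax(sig, 1e-300)
  kappa_inv <- debye_length(ionic_strength)
  Fv <- Ffun(q)

  free_reff <- is.null(fix_reff)
  p_names <- c("I1", "d", "I2", "contact_potential",
               if (free_reff) "R_eff", "phi")
  st <- list(I1 = max(I[1] * q[1]^2.2, 1e-8), d = 2.2,
             I2 = max(I) / 1.3, contact_potential = 2,
             R_eff = if (free_reff) 23.5 else fix_reff, phi = 0.25)
  if (!is.null(init)) for (nm in intersect(names(init), names(st))) st[[nm]] <- init[[nm]]
  lower <- c(I1 = 0, d = 1, I2 = 1e-12, contact_potential = 0,
             R_eff = 15, phi = 0.02)[p_names]
  upper <- c(I1 = Inf, d = 4, I2 = Inf, contact_potential = 30,
             R_eff = 35, phi = 0.6)[p_names]

  warm <- new.env(parent = emptyenv())
  model_fn <- function(pv) {
    pl <- as.list(pv)
    if (!free_reff) pl$R_eff <- fix_reff
    y <- yukawa_interaction(pl$contact_potential, pl$R_eff, pl$phi,
                            kappa_inv = kappa_inv, T = T_K, epsilon = epsilon)
    det <- tryCatch(
      rmsa_structure_factor(q, y, return_details = TRUE, init = warm$coef),
      error = function(e) NULL)
    if (is.null(det)) {
      det <- rmsa_structure_factor(q, y, return_details = TRUE)
    }
    if (!isTRUE(det$rescaled)) warm$coef <- det$coef
    pl$I1 * q^(-pl$d) + pl$I2 * Fv * det$S
  }
  fn <- function(pv) (I - model_fn(pv)) * w

  base <- unlist(st[p_names])
  best <- NULL
  set_jitter <- function(k) {
    if (k == 1) return(base)
    # deterministic jitter stream: repeated fits of the same curve explore
    # the same starts regardless of the ambient RNG state
    jit <- .with_substream(971, sprintf("sans_start_%02d", k),
                           stats::rnorm(length(base), 0, jitter_sd))
    pmin(pmax(base * exp(jit), lower + 1e-9), upper - 1e-9)
  }
  for (k in seq_len(n_starts)) {
    p0 <- set_jitter(k)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0, fn = fn, lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-15, ptol = 1e-15)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) stopf("SANS fit failed for all starts")
  pv <- best$par
  res <- fn(pv)
  dof <- max(length(q) - length(pv), 1)
  chi2_red <- sum(res^2) / dof
  cv <- tryCatch(chi2_red * solve(best$hessian), error = function(e) NULL)
  se <- if (is.null(cv)) rep(NA_real_, length(pv)) else sqrt(pmax(diag(cv), 0))
  names(se) <- names(pv)
  # identifiability: condition number of the column-scaled Jacobian
  J <- .num_jacobian(fn, pv, lower, upper)
  Js <- sweep(J, 2, pmax(abs(pv), 1e-12), "*")
  cond <- tryCatch(kappa(Js, exact = TRUE), error = function(e) Inf)

  pl <- as.list(pv)
  if (!free_reff) { pl$R_eff <- fix_reff; se <- c(se, R_eff = 0) }
  y <- yukawa_interaction(pl$contact_potential, pl$R_eff, pl$phi,
                          kappa_inv = kappa_inv, T = T_K, epsilon = epsilon)
  # high-q deviation flag: weighted residuals beyond the S(q) peak
  det <- rmsa_structure_factor(q, y, return_details = TRUE)
  ipk <- which.max(det$S)
  high <- seq_along(q) > ipk
  dev_high <- if (any(high)) sqrt(mean(res[high]^2)) else NA_real_
  phi_at_bound <- pl$phi <= lower[["phi"]] + 1e-6 || pl$phi >= upper[["phi"]] - 1e-6
  structure(list(
    par = pl, se = as.list(se),
    Z = charge_from_contact_potential(y),
    c_mg_ml = concentration_from_phi(pl$phi),
    yukawa = y, chi2_red = chi2_red,
    condition_number = cond, cond_ok = cond < cond_cap,
    high_q_rms = dev_high,
    converged = !(best$info %in% c(0, 9)),
    phi_at_bound = phi_at_bound,
    rescaled = det$rescaled),
    class = "sans_fit_result")
}

#' @export
print.sans_fit_result <- function(x, ...) {
  cat(sprintf(paste0("SANS charged-hard-sphere fit: contact = %.2f kBT, Z = %.1f e, ",
                     "R_eff = %.1f A, phi = %.3f -> c = %.0f mg/ml (chi2_red = %.3g)\n"),
              x$par$contact_potential, x$Z, x$par$R_eff, x$par$phi, x$c_mg_ml,
              x$chi2_red))
  invisible(x)
}

# forward-difference Jacobian respecting bounds
.num_jacobian <- function(fn, p, lower, upper, eps = 1e-6) {
  f0 <- fn(p)
  J <- matrix(0, length(f0), length(p))
  for (j in seq_along(p)) {
    h <- eps * max(abs(p[j]), 1e-8)
    pj <- p; pj[j] <- min(p[j] + h, upper[j])
    if (pj[j] == p[j]) pj[j] <- max(p[j] - h, lower[j])
    J[, j] <- (fn(pj) - f0) / (pj[j] - p[j])
  }
  J
}

#' Locate a curve's peak position by local quadratic interpolation
#'
#' Fits a parabola to the points around the discrete argmax and returns the
#' vertex abscissa -- a noise-robust peak locator for broad interaction
#' peaks (the raw argmax of a noisy curve wanders by several grid steps).
#'
#' @param curve a [sas_curve()] (or any list with `q` and `I`).
#' @param halfwidth number of grid points on each side of the argmax used
#'   in the quadratic fit.
#' @return Peak position in the curve's q units.
#' @export
peak_position <- function(curve, halfwidth = 7) {
  q <- curve$q; I <- curve$I
  i0 <- which.max(I)
  idx <- max(1, i0 - halfwidth):min(length(q), i0 + halfwidth)
  co <- stats::lm.fit(cbind(1, q[idx], q[idx]^2), I[idx])$coefficients
  if (!is.finite(co[3]) || co[3] >= 0) return(q[i0])
  vert <- -co[2] / (2 * co[3])
  if (vert < min(q[idx]) || vert > max(q[idx])) q[i0] else unname(vert)
}

#' Fit a kinetic SANS time series
#'
#' Per-time-point composite fits (see [fit_sans()]) with shared fixed
#' parameters, returning the concentration trace c(t), its time average
#' <C>, and a drift flag based on the significance of a linear trend.
#'
#' @param curves list of [sas_curve()] objects.
#' @param times incubation times, hours, same length as `curves`, increasing.
#' @param ff form factor (shared).
#' @param weighted_mean use error-weighted instead of unweighted averaging
#'   of c(t).
#' @param drift_level significance level for the linear-trend drift flag.
#' @param ... passed to [fit_sans()] (e.g. `fix_reff`).
#' @return A `kinetic_series` list: `times`, `results`, `c_t`, `c_mean`,
#'   `drift` (logical), `drift_p`, `failed` (time indices that failed).
#' @export
fit_kinetic_series <- function(curves, times, ff, weighted_mean = FALSE,
                               drift_level = 0.05, ...) {
  if (length(curves) != length(times)) stopf("curves/times length mismatch")
  if (length(curves) < 2) stopf("need at least 2 time points")
  if (any(diff(times) <= 0)) stopf("times must be increasing")
  results <- vector("list", length(curves))
  for (i in seq_along(curves)) {
    results[[i]] <- tryCatch(fit_sans(curves[[i]], ff, ...),
                             error = function(e) NULL)
  }
  failed <- which(vapply(results, is.null, TRUE))
  okidx <- setdiff(seq_along(results), failed)
  c_t <- rep(NA_real_, length(times))
  c_se <- rep(NA_real_, length(times))
  for (i in okidx) {
    c_t[i] <- results[[i]]$c_mg_ml
    c_se[i] <- 1000 / physical_constants()$upsilon_ml_g *
      (results[[i]]$se$phi %||% NA_real_)
  }
  if (weighted_mean && all(is.finite(c_se[okidx])) && all(c_se[okidx] > 0)) {
    wts <- 1 / c_se[okidx]^2
    c_mean <- sum(wts * c_t[okidx]) / sum(wts)
  } else c_mean <- mean(c_t[okidx])
  drift_p <- NA_real_
  drift <- FALSE
  if (length(okidx) >= 3) {
    fit <- stats::lm(c_t[okidx] ~ times[okidx])
    drift_p <- suppressWarnings(summary(fit)$coefficients[2, "Pr(>|t|)"])
    drift <- is.finite(drift_p) && drift_p < drift_level
  }
  structure(list(times = times, results = results, c_t = c_t, c_se = c_se,
                 c_mean = c_mean, drift = drift, drift_p = drift_p,
                 failed = failed),
            class = "kinetic_series")
}
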