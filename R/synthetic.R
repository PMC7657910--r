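# Seeded synthetic-data generators emulating the instrument grids and
# counting statistics of the three techniques: Bonse-Hart USANS curves
# (correlation peak or micrometre Guinier regime), SANS curves with an
# interaction peak near 0.1 1/A over a power-law background, and
# backscattering QENS spectra (q = 0.34-1.92 1/A, ~ueV energy window,
# 1.0 ueV FWHM Gaussian resolution) with Poisson counting noise.
# Every generator is a pure function of (truth, seed); each dataset
# component (signal, buffer, resolution) draws from its own named
# substream so adding one component never shifts another.

.component_seed <- function(seed, component) {
  s <- as.numeric(seed) %% 2147480009
  ci <- utf8ToInt(component)
  h <- sum(ci * seq_along(ci))              # position-weighted, order matters
  as.integer((s * 7919 + h * 104729) %% 2147480009)
}

.with_substream <- function(seed, component, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(.component_seed(seed, component))
  force(expr)
}

.logspace <- function(lo, hi, n) exp(seq(log(lo), log(hi), length.out = n))

#' Generate a synthetic USANS curve
#'
#' Evaluates a correlation-peak or Guinier-Porod truth model on a
#' logarithmic USANS grid, optionally slit-smears it, and adds
#' multiplicative Gaussian noise of the stated fraction; the sigma column is
#' the generating standard deviation.
#'
#' @param truth list: `model = "butler"` with `I0, alpha, xi_um, d`, or
#'   `model = "gp"` with `scale, Rg_um, d`.
#' @param q_grid momentum-transfer grid, 1/A (default 120 points, 2e-5 to
#'   2e-3, log-spaced).
#' @param smear slit-smear the curve (flag)?
#' @param dq_v slit half-width used when smearing (default 5e-5 1/A).
#' @param noise_frac relative Gaussian noise level (0 = noiseless).
#' @param seed integer seed.
#' @return List with `curve` (a [sas_curve()]) and `truth` (the ground-truth
#'   record including grid, noise and seed).
#' @export
make_usans <- function(truth, q_grid = .logspace(2e-5, 2e-3, 120),
                       smear = FALSE, dq_v = 5e-5, noise_frac = 0.02,
                       seed = 1) {
  model <- match.arg(truth$model, c("butler", "gp"))
  if (model == "butler") {
    p <- butler_params(truth$I0, truth$alpha, truth$xi_um * 1e4, truth$d)
    fI <- function(q) butler_empirical(q, p)
  } else {
    p <- guinier_porod_params(truth$scale, truth$Rg_um * 1e4, truth$d)
    fI <- function(q) guinier_porod(q, p)
  }
  if (smear) {
    cv <- slit_smear(fI, dq_v, q_grid = q_grid)
    I_model <- cv$I
  } else I_model <- fI(q_grid)
  sig <- noise_frac * I_model
  I_obs <- if (noise_frac > 0)
    .with_substream(seed, "signal", I_model * (1 + noise_frac * stats::rnorm(length(q_grid))))
  else I_model
  curve <- sas_curve(q_grid, I_obs, sig, smeared = smear,
                     dq_v = if (smear) dq_v else NULL)
  list(curve = curve,
       truth = list(generator = "make_usans", model = model, params = truth,
                    smear = smear, dq_v = dq_v, noise_frac = noise_frac,
                    seed = seed, q_range = range(q_grid), n = length(q_grid)))
}

#' Generate a synthetic SANS curve
#'
#' Forward composite model (power law + form factor times RMSA structure
#' factor) with counting-statistics noise: sigma proportional to sqrt(I),
#' scaled so the relative error at the interaction peak equals
#' `rel_err_peak`.
#'
#' @param truth list with `I1`, `d`, `I2`, `yukawa` (a
#'   [yukawa_interaction()]) and optional `ff`
#'   (default 23.6 A sphere, the scale of the fitted effective Hb radius).
#' @param q_grid 1/A (default 120 points, 0.01-0.45, log-spaced).
#' @param rel_err_peak relative 1-sigma counting error at the peak
#'   (0 = noiseless).
#' @param seed integer seed.
#' @return List with `curve`, `S_true` (generating structure factor) and
#'   `truth`.
#' @export
make_sans <- function(truth, q_grid = .logspace(0.01, 0.45, 120),
                      rel_err_peak = 0.03, seed = 1) {
  y <- truth$yukawa
  stopifnot(inherits(y, "yukawa_interaction"))
  ff <- truth$ff %||% list(type = "sphere", R = 23.6)
  Ffun <- form_factor_function(ff)
  S <- rmsa_structure_factor(q_grid, y)
  I_model <- composite_sans_intensity(q_grid, list(I1 = truth$I1, d = truth$d),
                                      truth$I2, Ffun(q_grid), S)
  if (rel_err_peak > 0) {
    Ipk <- max(I_model)
    sig <- rel_err_peak * sqrt(Ipk * pmax(I_model, 0))
    I_obs <- .with_substream(seed, "signal",
                             I_model + sig * stats::rnorm(length(q_grid)))
  } else { sig <- rep(0, length(q_grid)); I_obs <- I_model }
  curve <- sas_curve(q_grid, I_obs, sig)
  list(curve = curve, S_true = S,
       truth = list(generator = "make_sans", params = truth,
                    rel_err_peak = rel_err_peak, seed = seed,
                    q_range = range(q_grid), n = length(q_grid)))
}

#' Generate a kinetic series of synthetic SANS curves
#'
#' Shares all truth parameters across time points except the volume
#' fraction, which follows `phi_fun(t)` (constant by default, or a step
#' change emulating the onset of cell lysis).
#'
#' @param truth as in [make_sans()]; `truth$yukawa$phi` is the baseline.
#' @param times incubation times, hours.
#' @param phi_fun optional function of time returning the volume fraction.
#' @param step optional list `list(t = <hours>, dphi = <change>)` applied on
#'   top of the baseline from time `t` onwards.
#' @param rel_err_peak,seed as in [make_sans()].
#' @return List with `curves`, `times`, `truth`.
#' @export
make_sans_kinetic <- function(truth, times, phi_fun = NULL, step = NULL,
                              rel_err_peak = 0.03, seed = 1) {
  base_phi <- truth$yukawa$phi
  pf <- phi_fun %||% function(t) {
    base_phi + if (!is.null(step) && t >= step$t) step$dphi else 0
  }
  curves <- vector("list", length(times))
  for (i in seq_along(times)) {
    tr <- truth
    tr$yukawa <- yukawa_interaction(truth$yukawa$contact_potential,
                                    truth$yukawa$sigma_hc / 2, pf(times[i]),
                                    kappa_inv = truth$yukawa$kappa_inv,
                                    T = truth$yukawa$T,
                                    epsilon = truth$yukawa$epsilon)
    curves[[i]] <- make_sans(tr, rel_err_peak = rel_err_peak,
                             seed = .component_seed(seed, sprintf("t%02d", i)))$curve
  }
  list(curves = curves, times = times,
       truth = list(generator = "make_sans_kinetic", params = truth,
                    times = times, step = step, rel_err_peak = rel_err_peak,
                    seed = seed))
}

#' Generate a set of synthetic QENS spectra
#'
#' Per-q resolution-convolved two-Lorentzian spectra with ground truth:
#' global widths Gamma_G = hbar D_eff q^2, a Gaussian-confinement EISF
#' A0(q) = (1-p) exp(-x2 q^2) + p, a flat internal width Gamma_I, linear
#' background, Gaussian resolution of the stated FWHM, and Poisson noise at
#' a count level set by the relative error at the elastic peak
#' (default ~2%, emulating overnight backscattering runs).
#'
#' @param truth list: `D_eff` (cm^2/s), `x2` (A^2), `p` (immobile fraction),
#'   `Gamma_I` (ueV), optional `bkg_frac` (flat background as a fraction of
#'   the peak, default 0.005) and `buffer_frac` (flat buffer component
#'   added to the sample, default 0).
#' @param q scattering vectors, 1/A (default: 10 detectors, 0.34-1.92).
#' @param window energy window, ueV (default c(-31, 31)).
#' @param step energy bin, ueV (default 0.2).
#' @param res_fwhm resolution FWHM, ueV (default 1.0).
#' @param counts_peak expected counts in the elastic-peak bin (default 2500,
#'   i.e. ~2% relative error; 0 = noiseless).
#' @param seed integer seed.
#' @return List with `spectra` (list of [qens_spectrum()]), `buffer` (list
#'   or NULL), and `truth` (including the per-q generating `A0` and
#'   `Gamma_G`).
#' @export
make_qens <- function(truth, q = seq(0.34, 1.92, length.out = 10),
                      window = c(-31, 31), step = 0.2, res_fwhm = 1.0,
                      counts_peak = 2500, seed = 1) {
  omega <- seq(window[1], window[2], by = step)
  sd_res <- res_fwhm / (2 * sqrt(2 * log(2)))
  res_shape <- exp(-omega^2 / (2 * sd_res^2))
  res <- list(omega = omega, R = res_shape / trapz(omega, res_shape))
  hbar <- physical_constants()$hbar_ueV_s
  A0q <- (1 - truth$p) * exp(-truth$x2 * q^2) + truth$p
  GGq <- hbar * truth$D_eff * 1e16 * q^2
  bkg_frac <- truth$bkg_frac %||% 0.005
  buffer_frac <- truth$buffer_frac %||% 0
  spectra <- vector("list", length(q))
  buffers <- if (buffer_frac > 0) vector("list", length(q)) else NULL
  for (i in seq_along(q)) {
    mod <- function(x) {
      A0q[i] * .lorentzian(x, GGq[i]) +
        (1 - A0q[i]) * .lorentzian(x, GGq[i] + truth$Gamma_I)
    }
    sig_shape <- convolve_resolution(mod, res, omega)
    # scale to counts: elastic-peak bin of the signal = counts_peak
    peak <- max(sig_shape)
    fac <- if (counts_peak > 0) counts_peak / peak else 1 / peak
    signal <- sig_shape * fac
    bkg <- bkg_frac * max(signal)
    # unscaled flat buffer model; the sample receives buffer_frac of it, so
    # subtract_buffer(sample, buffer, scale = buffer_frac) removes it
    buf_level <- 0.2 * max(signal)
    expect <- signal + bkg + buffer_frac * buf_level
    if (counts_peak > 0) {
      counts <- .with_substream(seed, sprintf("signal_q%02d", i),
                                stats::rpois(length(omega), expect))
      Sv <- counts
      sg <- sqrt(pmax(expect, 1))
    } else { Sv <- expect; sg <- rep(0, length(omega)) }
    spectra[[i]] <- qens_spectrum(q[i], omega, Sv, sg, res)
    if (buffer_frac > 0) {
      bexp <- rep(buf_level, length(omega))
      if (counts_peak > 0) {
        bcounts <- .with_substream(seed, sprintf("buffer_q%02d", i),
                                   stats::rpois(length(omega), bexp))
        buffers[[i]] <- qens_spectrum(q[i], omega, bcounts,
                                      sqrt(pmax(bexp, 1)), res)
      } else buffers[[i]] <- qens_spectrum(q[i], omega, bexp,
                                           rep(0, length(omega)), res)
    }
  }
  list(spectra = spectra, buffer = buffers,
       truth = list(generator = "make_qens", params = truth, q = q,
                    A0 = A0q, Gamma_G = GGq, window = window, step = step,
                    res_fwhm = res_fwhm, counts_peak = counts_peak,
                    seed = seed))
}
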