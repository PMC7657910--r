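# Mean spherical approximation for the hard-core one-Yukawa fluid, solved by
# Baxter's Wiener-Hopf factorization. The factor function
#   Q_in(r) = (a/2)(r^2-1) + b(r-1) + c1 (e^{-zr} - e^{-z}) + d1 e^{-z},  r < 1
#   Q_out(r) = d1 e^{-zr},                                               r > 1
# (hard-core diameter sigma = 1, z = kappa*sigma) carries five scalar
# unknowns (a, b, c1, d1 and the Laplace moment G = int r h(r) e^{-zr} dr).
# Baxter's two factorized Ornstein-Zernike relations reduce, on this ansatz,
# to closed-form expressions; the core condition h(r) = -1 for r < 1 is
# enforced at collocation points (the residual lies in span{1, r, e^{-zr}},
# so any three interior points determine it), the Yukawa tail fixes the
# amplitude equation, and G is closed by a q-space quadrature of S(q)-1.
# At zero coupling the system reduces exactly to Baxter's hard-sphere
# coefficients, i.e. the Percus-Yevick solution.

#' Percus-Yevick hard-sphere structure factor (closed form)
#'
#' Analytic structure factor of the pure hard-sphere fluid in the
#' Percus-Yevick approximation (Wertheim/Thiele solution). Serves as the
#' zero-coupling limit of the screened-Coulomb structure factor and as an
#' independent oracle in tests.
#'
#' @param q momentum transfer, reciprocal unit of `sigma`.
#' @param phi hard-sphere volume fraction in \[0, 0.74).
#' @param sigma hard-core diameter (default 1: q is then q*sigma).
#' @return S(q) vector.
#' @export
py_hard_sphere_sq <- function(q, phi, sigma = 1) {
  if (!is.finite(phi) || phi < 0 || phi >= 0.74) stopf("phi must lie in [0, 0.74)")
  if (phi == 0) return(rep(1, length(q)))
  x <- q * sigma
  eta <- phi
  A <- (1 + 2 * eta)^2 / (1 - eta)^4
  B <- -6 * eta * (1 + eta / 2)^2 / (1 - eta)^4
  C <- eta * A / 2
  small <- x < 0.05
  rc <- numeric(length(x))
  if (any(!small)) {
    xs <- x[!small]
    f1 <- (sin(xs) - xs * cos(xs)) / xs^3
    f2 <- (2 * xs * sin(xs) - (xs^2 - 2) * cos(xs) - 2) / xs^4
    f3 <- ((4 * xs^3 - 24 * xs) * sin(xs) - (xs^4 - 12 * xs^2 + 24) * cos(xs) + 24) / xs^6
    rc[!small] <- -24 * eta * (A * f1 + B * f2 + C * f3)
  }
  if (any(small)) {
    # series of the integrals int_0^1 t^(n+2) sinc(xt) dt for x -> 0
    xs <- x[small]
    f1 <- 1 / 3 - xs^2 / 30 + xs^4 / 840
    f2 <- 1 / 4 - xs^2 / 36 + xs^4 / 960
    f3 <- 1 / 6 - xs^2 / 48 + xs^4 / 1200
    rc[small] <- -24 * eta * (A * f1 + B * f2 + C * f3)
  }
  1 / (1 - rc)
}

# q-space Gauss-Legendre quadrature reused across solves (panelized so that
# the oscillations of S(q)-1, period 2*pi in q*sigma, are well resolved)
.msa_quad_cache <- new.env(parent = emptyenv())
.msa_quad <- function(qmax = 600, npanel = 120, nnode = 8) {
  key <- sprintf("%g_%d_%d", qmax, npanel, nnode)
  if (!is.null(.msa_quad_cache[[key]])) return(.msa_quad_cache[[key]])
  gl <- gauss_legendre(nnode)
  edges <- seq(0, qmax, length.out = npanel + 1)
  lo <- edges[-length(edges)]; hi <- edges[-1]
  q <- as.vector(outer(gl$x, (hi - lo) / 2) + rep((hi + lo) / 2, each = nnode))
  w <- as.vector(outer(gl$w, (hi - lo) / 2))
  .msa_quad_cache[[key]] <- list(q = q, w = w)
  .msa_quad_cache[[key]]
}

# S(q*sigma) from the factor-function coefficients; x is dimensionless q*sigma
.msa_sq_from_coef <- function(x, coef, eta, z) {
  a <- coef[1]; b <- coef[2]; c1 <- coef[3]; d1 <- coef[4]
  ez <- exp(-z)
  w <- 1i * x
  ew <- exp(w)
  P0 <- (ew - 1) / w
  P1 <- (ew * (w - 1) + 1) / w^2
  P2 <- (ew * (w^2 - 2 * w + 2) - 2) / w^3
  Pz <- (exp(w - z) - 1) / (w - z)
  Qf <- 1 - 12 * eta * ((a / 2) * (P2 - P0) + b * (P1 - P0) +
                          c1 * (Pz - ez * P0) + d1 * ez * P0 +
                          d1 * exp(w - z) / (z - w))
  1 / (Re(Qf)^2 + Im(Qf)^2)
}

.msa_residuals <- function(u, eta, z, gamma, rcoll, quad) {
  a <- u[1]; b <- u[2]; c1 <- u[3]; d1 <- u[4]; G <- u[5]
  ez <- exp(-z)
  E0 <- (1 - ez) / z
  E1 <- (1 - (1 + z) * ez) / z^2
  E2 <- (2 - (z^2 + 2 * z + 2) * ez) / z^3
  M0 <- -a / 3 - b / 2 + c1 * (E0 - ez) + d1 * ez
  M1 <- -a / 8 - b / 6 + c1 * (E1 - ez / 2) + d1 * ez / 2
  r <- rcoll
  Qp <- a * r + b - z * c1 * exp(-z * r)
  Jr <- ez * ((r - 1) * (1 - exp(-z * r)) / z - (1 - (1 + z * r) * exp(-z * r)) / z^2)
  res_core <- r - Qp + 12 * eta * (-(r * M0 - M1) - d1 * Jr -
                                     d1 * exp(-z * r) * (G + E1))
  Qhz <- (a / 2) * (E2 - E0) + b * (E1 - E0) +
    c1 * ((1 - exp(-2 * z)) / (2 * z) - ez * E0) +
    d1 * ez * E0 + d1 * exp(-2 * z) / (2 * z)
  res_amp <- gamma + z * d1 * (1 - 12 * eta * Qhz)
  S <- .msa_sq_from_coef(quad$q, u, eta, z)
  Gnum <- sum(quad$w * (S - 1) * quad$q^2 / (quad$q^2 + z^2)) / (12 * pi * eta)
  c(res_core, res_amp, G - Gnum)
}

# contact value g(sigma+) from the solved coefficients: the indirect
# correlation h - c is continuous across contact, so
# g(1+) = c(1+) - c(1-) with c(1-) from Baxter's first relation.
.msa_contact_g <- function(coef, eta, z, contact) {
  a <- coef[1]; b <- coef[2]; c1 <- coef[3]; d1 <- coef[4]
  ez <- exp(-z)
  E0 <- (1 - ez) / z
  E1 <- (1 - (1 + z) * ez) / z^2
  E2 <- (2 - (z^2 + 2 * z + 2) * ez) / z^3
  Qhz <- (a / 2) * (E2 - E0) + b * (E1 - E0) +
    c1 * ((1 - exp(-2 * z)) / (2 * z) - ez * E0) +
    d1 * ez * E0 + d1 * exp(-2 * z) / (2 * z)
  c_in1 <- -(a + b - z * c1 * ez) - 12 * eta * z * d1 * ez * Qhz
  -contact - c_in1
}

# Compact Levenberg-Marquardt for the coefficient system. Self-contained on
# purpose: the MSA solve runs inside other minpack.lm fits, whose C callback
# is not reentrant, so the inner solver must be pure R.
.lm_solve <- function(fn, par, maxit = 200, ftol = 1e-28, lambda0 = 1e-3) {
  p <- par
  f <- fn(p)
  cost <- sum(f^2)
  lambda <- lambda0
  npar <- length(p)
  for (it in seq_len(maxit)) {
    J <- matrix(0, length(f), npar)
    for (j in seq_len(npar)) {
      h <- 1e-7 * max(abs(p[j]), 1e-6)
      pj <- p; pj[j] <- pj[j] + h
      J[, j] <- (fn(pj) - f) / h
    }
    g <- crossprod(J, f)
    A <- crossprod(J)
    dA <- diag(A)
    improved <- FALSE
    for (tries in 1:25) {
      step <- tryCatch(solve(A + lambda * diag(pmax(dA, 1e-300), npar), -g),
                       error = function(e) NULL)
      if (!is.null(step)) {
        pn <- p + as.vector(step)
        fnew <- fn(pn)
        if (all(is.finite(fnew)) && sum(fnew^2) < cost) {
          p <- pn; f <- fnew; cost <- sum(f^2)
          lambda <- max(lambda / 4, 1e-12)
          improved <- TRUE
          break
        }
      }
      lambda <- lambda * 8
    }
    if (!improved || cost < ftol) break
  }
  list(par = p, cost = cost, iterations = it)
}

# Solve the MSA coefficient system for (eta, z, contact potential).
# Returns coefficients, contact value of g, and diagnostics.
.msa_solve <- function(eta, z, contact, init = NULL, quad = .msa_quad()) {
  gamma <- contact * exp(z)
  aHS <- (1 + 2 * eta) / (1 - eta)^2
  bHS <- -3 * eta / (2 * (1 - eta)^2)
  if (is.null(init)) {
    ez <- exp(-z)
    E0 <- (1 - ez) / z
    E1 <- (1 - (1 + z) * ez) / z^2
    E2 <- (2 - (z^2 + 2 * z + 2) * ez) / z^3
    QhzHS <- (aHS / 2) * (E2 - E0) + bHS * (E1 - E0)
    d10 <- -gamma / (z * (1 - 12 * eta * QhzHS))
    SPY <- py_hard_sphere_sq(quad$q, eta)
    G0 <- sum(quad$w * (SPY - 1) * quad$q^2 / (quad$q^2 + z^2)) / (12 * pi * eta)
    init <- c(aHS, bHS, d10, d10, G0)
  }
  rcoll <- seq(0.1, 0.95, length.out = 6)
  fit <- .lm_solve(function(u) .msa_residuals(u, eta, z, gamma, rcoll, quad),
                   init)
  resid <- .msa_residuals(fit$par, eta, z, gamma, rcoll, quad)
  rnorm <- sqrt(sum(resid^2))
  if (!is.finite(rnorm) || rnorm > 1e-6)
    stopf(paste0("MSA coefficient solve did not converge ",
                 "(eta = %.4g, k = %.4g, contact = %.4g kBT; residual %.3g)"),
          eta, z, contact, rnorm)
  list(coef = fit$par, eta = eta, z = z, contact = contact,
       g_contact = .msa_contact_g(fit$par, eta, z, contact),
       resid_norm = rnorm)
}

#' Rescaled mean spherical approximation (RMSA) structure factor
#'
#' Structure factor of charged hard spheres interacting through a screened
#' Coulomb (Yukawa) repulsion, in the mean spherical approximation. When the
#' plain MSA yields an unphysical negative pair correlation at contact, the
#' hard core is inflated at fixed number density (and fixed physical
#' potential) until g(sigma+) = 0 before evaluating S(q) -- the standard
#' rescaling construction for weakly coupled macro-ion fluids.
#'
#' @param q_grid momentum transfer values, positive; reciprocal angstrom when
#'   `y$sigma_hc` is in angstrom.
#' @param y a [yukawa_interaction()] describing the macro-ion fluid.
#' @param return_details if `TRUE`, return a list with the solution
#'   diagnostics (`rescaled`, scaling factor `s`, contact value, coefficients)
#'   alongside `S`.
#' @param init optional warm-start coefficient vector from a previous solve
#'   at nearby parameters (used heavily inside fits).
#' @return `S(q)` evaluated on `q_grid` (or a detail list). S is
#'   non-negative by construction and tends to 1 at large q.
#' @export
#' @examples
#' y <- yukawa_interaction(2.5, R_eff = 23.6, phi = 0.256, kappa_inv = 7.8)
#' S <- rmsa_structure_factor(seq(0.02, 0.4, by = 0.01), y)
rmsa_structure_factor <- function(q_grid, y, return_details = FALSE,
                                  init = NULL) {
  stopifnot(inherits(y, "yukawa_interaction"))
  if (any(!is.finite(q_grid)) || any(q_grid <= 0)) stopf("q_grid must be positive")
  eta <- y$phi
  if (eta < 1e-10) {
    S <- rep(1, length(q_grid))
    if (return_details) return(list(S = S, rescaled = FALSE, s = 1,
                                    g_contact = NA_real_, coef = NULL))
    return(S)
  }
  z <- y$k
  contact <- y$contact_potential
  sol <- .msa_solve(eta, z, contact, init = init)
  s <- 1
  rescaled <- FALSE
  if (sol$g_contact < 0) {
    rescaled <- TRUE
    # inflate the core: s > 1, eta* = eta s^3, k* = k s, and the physical
    # potential unchanged => contact* = (contact / s) exp(-z (s - 1))
    smax <- (0.72 / eta)^(1 / 3)
    if (smax <= 1) stopf("rescaling impossible: packing fraction too high")
    gfun <- function(s) {
      .msa_solve(eta * s^3, z * s, (contact / s) * exp(-z * (s - 1)))$g_contact
    }
    g_hi <- gfun(smax)
    if (g_hi < 0)
      stopf("RMSA rescaling root search failed: g(sigma+) = %.4g still negative at maximal inflation s = %.4g",
            g_hi, smax)
    root <- stats::uniroot(gfun, c(1, smax), tol = 1e-10)
    s <- root$root
    sol <- .msa_solve(eta * s^3, z * s, (contact / s) * exp(-z * (s - 1)))
  }
  S <- .msa_sq_from_coef(q_grid * y$sigma_hc * s, sol$coef, sol$eta, sol$z)
  if (return_details)
    return(list(S = S, rescaled = rescaled, s = s,
                g_contact = sol$g_contact, coef = sol$coef,
                eta_solved = sol$eta, z_solved = sol$z))
  S
}

#' Ornstein-Zernike MSA oracle (iterative solver)
#'
#' Brute-force verification oracle for [rmsa_structure_factor()]: solves the
#' Ornstein-Zernike equation with the MSA closure (c(r) = -beta U(r) outside
#' the hard core, g(r) = 0 inside) by Picard iteration with mixing on a fine
#' radial grid, using fast sine transforms. Used in tests; algorithmically
#' independent of the factorization route.
#'
#' @param y a [yukawa_interaction()].
#' @param q_grid optional physical q grid (reciprocal angstrom) on which to
#'   interpolate the result.
#' @param dr radial step in units of the hard-core diameter.
#' @param n number of radial points (grid extent n * dr, >= 40 diameters).
#' @param mix Picard mixing parameter in (0, 1\].
#' @param tol convergence tolerance on the indirect correlation function.
#' @param maxit maximum number of iterations.
#' @return List with `q` (dimensionless q*sigma), `S`, iteration count, and
#'   (when `q_grid` is supplied) `S_interp` on the physical grid.
#' @export
oz_msa_oracle <- function(y, q_grid = NULL, dr = 0.005, n = 8192,
                          mix = 0.25, tol = 1e-11, maxit = 8000) {
  stopifnot(inherits(y, "yukawa_interaction"))
  eta <- y$phi
  z <- y$k
  if (n * dr < 40) stopf("radial grid must span at least 40 hard-core diameters")
  gamma <- y$contact_potential * exp(z)
  r <- (1:n) * dr
  rho <- 6 * eta / pi
  rmax <- (n + 1) * dr
  qk <- (1:n) * pi / rmax
  u_tail <- gamma * exp(-z * r) / r
  core <- r < 1 - 1e-12
  at_b <- abs(r - 1) < 1e-12
  fst <- function(f) {            # sum-based DST-I via FFT of odd extension
    yv <- c(0, f, 0, -rev(f))
    -Im(stats::fft(yv))[2:(n + 1)] / 2
  }
  gam <- numeric(n)
  delta <- Inf
  for (it in seq_len(maxit)) {
    cr <- ifelse(core, -1 - gam, -u_tail)
    if (any(at_b)) cr[at_b] <- 0.5 * ((-1 - gam[at_b]) + (-u_tail[at_b]))
    chat <- 4 * pi / qk * fst(r * cr) * dr
    gamhat <- rho * chat^2 / (1 - rho * chat)
    gam_new <- fst(qk * gamhat) * (pi / rmax) / (2 * pi^2 * r)
    delta <- max(abs(gam_new - gam))
    gam <- mix * gam_new + (1 - mix) * gam
    if (delta < tol) break
  }
  if (delta >= tol)
    stopf("OZ-MSA oracle did not converge: delta = %.3g after %d iterations (eta = %.3g, k = %.3g)",
          delta, maxit, eta, z)
  cr <- ifelse(core, -1 - gam, -u_tail)
  if (any(at_b)) cr[at_b] <- 0.5 * ((-1 - gam[at_b]) + (-u_tail[at_b]))
  chat <- 4 * pi / qk * fst(r * cr) * dr
  S <- 1 / (1 - rho * chat)
  out <- list(q = qk, S = S, iters = it, delta = delta)
  if (!is.null(q_grid)) {
    x <- q_grid * y$sigma_hc
    if (any(x > max(qk))) stopf("q_grid extends beyond the oracle's q range")
    out$S_interp <- stats::spline(qk, S, xout = x)$y
  }
  out
}
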