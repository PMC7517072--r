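#' Planar double-layer scenario
#'
#' Describes the 1D (planar) domain of the fourth-order Poisson-Bikerman
#' solve: a charged wall at `x = 0` in contact with an electrolyte, far
#' field at `x = L`.
#'
#' @param L domain length, Angstrom.
#' @param n number of grid nodes.
#' @param sigma surface charge density at the wall, e per square Angstrom.
#' @param eps_s relative permittivity of the solvent.
#' @param lc correlation length, Angstrom (0 disables ion-ion/ion-water
#'   correlations).
#' @param V applied far-field offset, kBT/e (the far boundary is held at 0;
#'   `V` shifts the wall-side Dirichlet value in transport solves).
#' @return object of class `pnpb_domain`.
#' @export
domain_spec <- function(L = 40, n = 801, sigma = 0, eps_s = 78.45,
                        lc = 0, V = 0) {
  stopifnot(is.finite(sigma), eps_s > 0, lc >= 0, L > 0, n >= 11)
  structure(list(L = L, n = as.integer(n), sigma = sigma, eps_s = eps_s,
                 lc = lc, V = V),
            class = "pnpb_domain")
}

#' Nonlinear solver configuration
#'
#' Controls the relaxed Newton iteration with steric and correlation
#' continuation used by [solve_equilibrium()] and [solve_pnpb_steady()].
#'
#' @param tol nonlinear tolerance on the max-norm potential update, kBT/e.
#' @param omega_4pbik relaxation weight on the old iterate in the
#'   electrostatic loop (in (0, 1); smaller is more aggressive).
#' @param omega_pnpb relaxation weight in the outer transport loop.
#' @param steric_steps number of continuation steps ramping particle
#'   volumes from 0 to their physical values.
#' @param corr_steps number of continuation steps ramping the correlation
#'   length from 0 to `lc`.
#' @param dV voltage ramp increment for transport solves, kBT/e.
#' @param max_iter maximum Newton iterations per continuation stage.
#' @param newton one of "lagged" (void-fraction response frozen in the
#'   charge-density derivative) or "full" (includes the implicit steric
#'   response).
#' @return object of class `pnpb_solver_config`.
#' @export
solver_config <- function(tol = 1e-6, omega_4pbik = 0.5, omega_pnpb = 0.5,
                          steric_steps = 10, corr_steps = 5, dV = 0.5,
                          max_iter = 400,
                          newton = c("lagged", "full")) {
  stopifnot(tol > 0, omega_4pbik > 0, omega_4pbik < 1,
            omega_pnpb > 0, omega_pnpb < 1,
            steric_steps >= 1, corr_steps >= 1, max_iter >= 1)
  structure(list(tol = tol, omega_4pbik = omega_4pbik,
                 omega_pnpb = omega_pnpb, steric_steps = steric_steps,
                 corr_steps = corr_steps, dV = dV, max_iter = max_iter,
                 newton = match.arg(newton)),
            class = "pnpb_solver_config")
}

## Solve (lc2 D2 - 1) Psi = rho with dPsi/dn = 0 at the wall, Psi = 0 far.
## lc2 = 0 reduces to Psi = -rho.
solve_aux_field <- function(rho, h, lc2) {
  n <- length(rho)
  if (lc2 == 0) return(-rho)
  lower <- rep(lc2 / h^2, n - 1)
  upper <- rep(lc2 / h^2, n - 1)
  diag0 <- rep(-2 * lc2 / h^2 - 1, n)
  b <- rho
  diag0[1] <- -2 * lc2 / h^2 - 1; upper[1] <- 2 * lc2 / h^2  # ghost Neumann
  diag0[n] <- 1; lower[n - 1] <- 0; b[n] <- 0
  tridiag_solve(lower, diag0, upper, b)
}

## One relaxed-Newton stage at fixed continuation parameters.
## Reduced equations on phi (kBT/e):
##   (lc2 D2 - 1) Psi = rho_r,  D2 phi = Psi,
##   rho_r = 4 pi lB sum_i z_i C_i,  C from the self-consistent Fermi state.
## Wall BC: phi'(0) = -4 pi lB sigma, Psi'(0) = 0; far field phi = Psi = 0.
edl_stage <- function(u, comp, fourpilB, sigma, h, lc2, steric_scale,
                      cfg, exponent = "volume_ratio") {
  n <- length(u)
  res_hist <- numeric(0)
  for (it in seq_len(cfg$max_iter)) {
    fs <- fermi_state(u, comp, steric_scale = steric_scale,
                      exponent = exponent)
    rho <- fourpilB * charge_density(fs$C, comp)
    ## Newton derivative m = -d(rho)/d(phi) >= 0
    zz <- comp$z
    m <- fourpilB * as.vector(fs$C %*% zz^2)
    if (cfg$newton == "full" && steric_scale > 0) {
      vt <- steric_scale * comp$v
      p <- if (exponent == "uniform") as.numeric(vt > 0) else vt / comp$v0
      num <- as.vector(fs$C %*% (vt * zz))
      den <- fs$Gamma + as.vector(fs$C %*% (vt * p))
      dS <- num / den                      # d S / d phi per node
      m <- m - fourpilB * as.vector(fs$C %*% (zz * p)) * dS
    }
    Psi <- solve_aux_field(rho, h, lc2)
    ## (-D2 + m) u_new = -Psi + m u_old; Neumann wall, Dirichlet far field
    lower <- rep(-1 / h^2, n - 1)
    upper <- rep(-1 / h^2, n - 1)
    diag0 <- 2 / h^2 + m
    b <- -Psi + m * u
    upper[1] <- -2 / h^2
    b[1] <- b[1] + 2 * fourpilB * sigma / h
    diag0[n] <- 1; lower[n - 1] <- 0; b[n] <- 0
    unew <- tridiag_solve(lower, diag0, upper, b)
    step <- unew - u
    err <- max(abs(step))
    if (!is.finite(err))
      stop("equilibrium stage diverged (non-finite update); residual ",
           "history tail ",
           paste(signif(utils::tail(res_hist, 5), 3), collapse = ", "),
           call. = FALSE)
    ## trust-region cap: Boltzmann factors overflow for wild Newton steps
    if (err > 5) step <- step * (5 / err)
    res_hist <- c(res_hist, err)
    u <- u + (1 - cfg$omega_4pbik) * step
    if (err < cfg$tol) return(list(u = u, iterations = it, err = err,
                                   residuals = res_hist, converged = TRUE))
  }
  list(u = u, iterations = cfg$max_iter, err = err, residuals = res_hist,
       converged = FALSE)
}

#' Solve the equilibrium planar double layer
#'
#' Self-consistent solution of the fourth-order Poisson-Bikerman
#' electrostatics in a planar half-space: the fourth-order equation is
#' decomposed into two second-order equations (an auxiliary density-like
#' field and the Poisson equation), the saturating Fermi closure couples
#' the concentrations to the potential through the steric potential, and
#' the nonlinear system is solved by relaxed Newton iteration with
#' continuation in the steric switch and the correlation length.
#'
#' @param domain a `pnpb_domain` (surface charge, permittivity, correlation
#'   length, extent).
#' @param comp a `pnpb_composition`.
#' @param config a `pnpb_solver_config`.
#' @param steric_exponent passed to [fermi_state()]: `"volume_ratio"` for
#'   the size-weighted steric energies (the default closure) or
#'   `"uniform"` for the identical-steric-energy Bikerman closure.
#' @return object of class `pnpb_field_state`: list with grid `x`, reduced
#'   potential `phi` (kBT/e), auxiliary field `Psi`, concentration matrix
#'   `C` (A^-3), void fraction `Gamma`, steric potential `S`, charge
#'   density `rho` (e A^-3), plus `lB`, convergence diagnostics and the
#'   inputs.
#' @export
solve_equilibrium <- function(domain, comp,
                              config = solver_config(),
                              steric_exponent = c("volume_ratio",
                                                  "uniform")) {
  steric_exponent <- match.arg(steric_exponent)
  lB <- bjerrum_length(domain$eps_s, comp$T)
  fourpilB <- 4 * pi * lB
  n <- domain$n
  h <- domain$L / (n - 1)
  x <- seq(0, domain$L, length.out = n)
  u <- numeric(n)
  stage_err <- numeric(0)

  ## steric continuation at lc = 0
  any_steric <- any(comp$v > 0)
  lam_seq <- if (any_steric)
    seq(0, 1, length.out = config$steric_steps + 1)[-1] else 1
  for (lam in lam_seq) {
    st <- edl_stage(u, comp, fourpilB, domain$sigma, h, 0, lam, config,
                    steric_exponent)
    u <- st$u
    stage_err <- c(stage_err, st$err)
  }
  ## correlation continuation
  if (domain$lc > 0) {
    for (fr in seq(0, 1, length.out = config$corr_steps + 1)[-1]) {
      st <- edl_stage(u, comp, fourpilB, domain$sigma, h,
                      (fr * domain$lc)^2, 1, config, steric_exponent)
      u <- st$u
      stage_err <- c(stage_err, st$err)
    }
  }
  ## final polish at the physical parameters
  st <- edl_stage(u, comp, fourpilB, domain$sigma, h, domain$lc^2, 1,
                  config, steric_exponent)
  if (!st$converged)
    stop("equilibrium solve did not converge: final max-norm update ",
         format(st$err), "; residual history tail ",
         paste(signif(utils::tail(st$residuals, 5), 3), collapse = ", "),
         call. = FALSE)
  u <- st$u
  fs <- fermi_state(u, comp, exponent = steric_exponent)
  rho <- charge_density(fs$C, comp)
  Psi <- solve_aux_field(fourpilB * rho, h, domain$lc^2)
  structure(list(
    x = x, phi = u, Psi = Psi, C = fs$C, Gamma = fs$Gamma, S = fs$S,
    rho = rho, lB = lB, domain = domain, composition = comp,
    steric_exponent = steric_exponent,
    iterations = st$iterations, err = st$err, stage_err = stage_err,
    residuals = st$residuals
  ), class = "pnpb_field_state")
}

#' @export
print.pnpb_field_state <- function(x, ...) {
  cat(sprintf(
    "Planar 4PBik field state: n=%d, L=%.1f A, sigma=%.4g e/A^2, lc=%.3g A\n",
    length(x$x), x$domain$L, x$domain$sigma, x$domain$lc))
  cat(sprintf("  phi(0) = %.4f kBT/e, min phi = %.4f at x = %.2f A\n",
              x$phi[1], min(x$phi), x$x[which.min(x$phi)]))
  cat(sprintf("  converged with max update %.3g after %d final iterations\n",
              x$err, x$iterations))
  invisible(x)
}

## interior/one-sided finite-difference derivative of a nodal field
fd_derivative <- function(y, h) {
  n <- length(y)
  d <- numeric(n)
  d[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / (2 * h)
  d[1] <- (-3 * y[1] + 4 * y[2] - y[3]) / (2 * h)
  d[n] <- (3 * y[n] - 4 * y[n - 1] + y[n - 2]) / (2 * h)
  d
}

#' Polarization field of the solved double layer
#'
#' `P = eps_s lc^2 (phi'')' - (eps_w - 1) eps0 phi'` evaluated by repeated
#' central differencing (one-sided at the boundaries). Reported in reduced
#' units of `eps0 kBT/(e Angstrom)`, i.e. the returned value is `P/eps0`
#' with the potential in kBT/e. With `lc = 0` this reduces to the standard
#' linear-dielectric polarization `(eps_w - 1) E`.
#'
#' @param state a `pnpb_field_state`.
#' @param lc correlation length (defaults to the one used in the solve).
#' @return vector of reduced polarization values.
#' @export
polarization_field <- function(state, lc = state$domain$lc) {
  h <- state$x[2] - state$x[1]
  eps_w <- state$domain$eps_s
  d1 <- fd_derivative(state$phi, h)
  if (lc == 0) return(-(eps_w - 1) * d1)
  d2 <- fd_derivative(d1, h)
  d3 <- fd_derivative(d2, h)
  eps_w * lc^2 * d3 - (eps_w - 1) * d1
}

#' Effective (output) permittivity profile
#'
#' The fourth-order operator makes the dielectric response an output: with
#' `phit = phi - lc^2 phi''` the displacement potential, the pointwise
#' ratio `eps_hat = eps_s * phit' / phi'` defines a dielectric function of
#' position and composition. Nodes where `|phi'|` falls below `threshold`
#' times its maximum are masked (`NA`) to avoid 0/0.
#'
#' @param state a `pnpb_field_state`.
#' @param lc correlation length (defaults to the one used in the solve).
#' @param threshold relative gradient cutoff for masking.
#' @return vector of effective permittivities (NA where masked).
#' @export
effective_permittivity <- function(state, lc = state$domain$lc,
                                   threshold = 1e-6) {
  h <- state$x[2] - state$x[1]
  eps_w <- state$domain$eps_s
  d1 <- fd_derivative(state$phi, h)
  if (lc == 0) {
    out <- rep(eps_w, length(d1))
    out[abs(d1) < threshold * max(abs(d1))] <- NA_real_
    return(out)
  }
  d2 <- fd_derivative(d1, h)
  phit <- state$phi - lc^2 * d2
  dt1 <- fd_derivative(phit, h)
  out <- eps_w * dt1 / d1
  out[abs(d1) < threshold * max(abs(d1))] <- NA_real_
  out
}

#' Closed-form Gouy-Chapman potential for a 1:1 electrolyte
#'
#' Classical point-ion Poisson-Boltzmann solution of the charged planar
#' wall: `phi(x) = 4 artanh(tanh(phi0/4) exp(-x/lD))` with the contact
#' value from the Grahame relation
#' `sinh(phi0/2) = 2 pi lB sigma lD` (reduced units).
#'
#' @param x positions, Angstrom.
#' @param sigma surface charge density, e/A^2.
#' @param conc_M bulk salt concentration (each species), mol/L.
#' @param eps_s solvent permittivity.
#' @param T temperature, K.
#' @return potential in kBT/e.
#' @export
gouy_chapman_potential <- function(x, sigma, conc_M, eps_s = 78.45,
                                   T = 298.15) {
  lB <- bjerrum_length(eps_s, T)
  c0 <- molar_to_number(conc_M)
  lD <- 1 / sqrt(8 * pi * lB * c0)
  phi0 <- 2 * asinh(2 * pi * lB * sigma * lD)
  4 * atanh(tanh(phi0 / 4) * exp(-x / lD))
}

#' Net screening charge balance of a converged state
#'
#' Integrated ionic charge per unit area plus the surface charge; zero for
#' a perfectly screened double layer.
#'
#' @param state a `pnpb_field_state`.
#' @return residual charge in e/A^2.
#' @export
charge_balance <- function(state) {
  h <- state$x[2] - state$x[1]
  q <- sum((state$rho[-1] + state$rho[-length(state$rho)]) / 2) * h
  q + state$domain$sigma
}
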