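#' Transport specification
#'
#' Per-species diffusion coefficients and reservoir boundary data for the
#' steady-state Nernst-Planck-Bikerman solve. Time carries an arbitrary
#' unit chosen by the diffusion coefficients (A^2 per unit time); fluxes
#' and currents are reported in the matching reduced units.
#'
#' @param D named numeric vector of diffusion coefficients (A^2/time), one
#'   per species of the composition (water last).
#' @param left_M,right_M reservoir concentrations at `x = 0` and `x = L`
#'   in mol/L (length K+1; water typically at its bulk value on both
#'   sides).
#' @param V applied voltage, kBT/e, imposed as `phi(0) = V`, `phi(L) = 0`.
#' @param theta pore diffusion reduction factor in `(0, 1]`, applied
#'   multiplicatively over `pore_range`.
#' @param pore_range optional `c(xmin, xmax)` over which `theta` applies.
#' @return object of class `pnpb_transport`.
#' @export
transport_spec <- function(D, left_M, right_M, V = 0, theta = 1,
                           pore_range = NULL) {
  stopifnot(all(D > 0), theta > 0, theta <= 1,
            all(left_M >= 0), all(right_M >= 0))
  structure(list(D = D, left_M = left_M, right_M = right_M, V = V,
                 theta = theta, pore_range = pore_range),
            class = "pnpb_transport")
}

#' Bernoulli function of exponential fitting
#'
#' `B(t) = t / (exp(t) - 1)`, evaluated by its Taylor series
#' `1 - t/2 + t^2/12 - t^4/720` for `|t| < 1e-4` and through `expm1`
#' otherwise; `B(0) = 1` and `B(t) - B(-t) = -t`.
#'
#' @param t numeric vector.
#' @return `B(t)`, same shape as `t`.
#' @export
bernoulli <- function(t) {
  out <- numeric(length(t))
  small <- abs(t) < 1e-4
  ts <- t[small]
  out[small] <- 1 - ts / 2 + ts^2 / 12 - ts^4 / 720
  tb <- t[!small]
  out[!small] <- tb / expm1(tb)
  dim(out) <- dim(t)
  out
}

#' Scharfetter-Gummel edge flux
#'
#' Exponential-fitting flux across one edge:
#' `J = -(D/h) [B(-t) C_right - B(t) C_left]` with
#' `t = beta dphi - dS` the total (electric plus steric) reduced potential
#' drop over the edge. Exact for constant field and steric gradient on the
#' edge; a single edge spanning the domain reproduces the
#' Goldman-Hodgkin-Katz flux.
#'
#' @param C_left,C_right node concentrations, A^-3.
#' @param t_edge reduced potential drop across the edge.
#' @param D diffusion coefficient, A^2/time.
#' @param h edge length, Angstrom.
#' @return flux in A^-2 / time (positive toward increasing x).
#' @export
sg_flux <- function(C_left, C_right, t_edge, D, h) {
  -(D / h) * (bernoulli(-t_edge) * C_right - bernoulli(t_edge) * C_left)
}

#' Goldman-Hodgkin-Katz constant-field flux
#'
#' Closed-form flux through a region of length `L` with a linear potential
#' profile: the integral of the drift-diffusion equation at constant field.
#' Written here independently of the edge discretization for use as a
#' cross-check; algebraically identical to [sg_flux()] applied to the whole
#' region as a single edge.
#'
#' @param C_left,C_right boundary concentrations, A^-3.
#' @param t total reduced potential drop `beta * V` over the region.
#' @param D diffusion coefficient.
#' @param L region length, Angstrom.
#' @return flux in A^-2 / time.
#' @export
ghk_flux <- function(C_left, C_right, t, D, L) {
  if (abs(t) < 1e-12) return(-D * (C_right - C_left) / L)
  (D / L) * t * (C_left - C_right * exp(t)) / (exp(t) - 1)
}

#' Stability margin of the naive finite-difference NP discretization
#'
#' The primitive central scheme produces negative concentrations when
#' `|-beta dphi + dS| > 2` on an edge; the Scharfetter-Gummel scheme is
#' unconditionally positive. This diagnostic reports the margin.
#'
#' @param dphi edge potential differences, kBT/e.
#' @param dS edge steric potential differences.
#' @param beta species valence.
#' @return list with `margin = |-beta dphi + dS|` and logical `ok`
#'   (margin <= 2).
#' @export
stability_margin <- function(dphi, dS, beta) {
  m <- abs(-beta * dphi + dS)
  list(margin = m, ok = m <= 2)
}

#' Assemble the Scharfetter-Gummel system for one species
#'
#' Tridiagonal system for the steady-state Nernst-Planck-Bikerman equation
#' `-dJ/dx = 0` with
#' `J_{i+1/2} = -(D/h)[B(-t_i) C_{i+1} - B(t_i) C_i]`,
#' `t_i = beta dphi_i - (v/v0) dS_i`. Row coefficients are
#' `b_{i-1} = -B(t_{i-1})`, `b_i = B(-t_{i-1}) + B(t_i)`,
#' `b_{i+1} = -B(-t_i)`. Dirichlet concentration rows at the reservoir
#' ends.
#'
#' @param phi nodal reduced potential.
#' @param S nodal steric potential.
#' @param beta species valence (0 for water).
#' @param steric_weight `v_i/v0` for the species.
#' @param D edge diffusion coefficients (scalar or length n-1).
#' @param h grid spacing.
#' @param C_left,C_right Dirichlet boundary concentrations, A^-3.
#' @return list with tridiagonal bands `lower`, `diag`, `upper`, rhs `b`
#'   and the edge drops `t_edge`.
#' @export
assemble_npb <- function(phi, S, beta, steric_weight, D, h,
                         C_left, C_right) {
  n <- length(phi)
  t_edge <- beta * diff(phi) - steric_weight * diff(S)
  D <- rep_len(D, n - 1)
  Bm <- bernoulli(-t_edge)   # weights C_{i+1}
  Bp <- bernoulli(t_edge)    # weights C_i
  ## interior row i: D_{i-1}(B(-t_{i-1}) C_i - ... ) structure
  lower <- -D[-(n - 1)] * Bp[-(n - 1)]           # coefficient on C_{i-1}
  upper <- -D[-1] * Bm[-1]                       # coefficient on C_{i+1}
  diag0 <- c(1, D[-(n - 1)] * Bm[-(n - 1)] + D[-1] * Bp[-1], 1)
  lower <- c(lower, 0)
  upper <- c(0, upper)
  b <- numeric(n); b[1] <- C_left; b[n] <- C_right
  list(lower = lower, diag = diag0, upper = upper, b = b, t_edge = t_edge)
}

#' Solve the linear Nernst-Planck system for one species
#'
#' @inheritParams assemble_npb
#' @return nodal concentrations, A^-3.
#' @export
solve_np <- function(phi, S, beta, steric_weight, D, h, C_left, C_right) {
  sys <- assemble_npb(phi, S, beta, steric_weight, D, h, C_left, C_right)
  tridiag_solve(sys$lower, sys$diag, sys$upper, sys$b)
}

## per-species edge fluxes for a concentration profile
edge_fluxes <- function(C, t_edge, D, h) {
  n <- length(C)
  D <- rep_len(D, n - 1)
  -(D / h) * (bernoulli(-t_edge) * C[-1] - bernoulli(t_edge) * C[-n])
}

#' Steady-state Poisson-Nernst-Planck-Bikerman solve
#'
#' Gummel-type outer iteration coupling the Scharfetter-Gummel
#' Nernst-Planck solves for every species (water included, driven only by
#' the steric potential) to the decomposed fourth-order Poisson-Bikerman
#' electrostatics. The applied voltage is reached through a ramp of
#' increments `config$dV`; within each ramp step, NP solves alternate with
#' the two electrostatic solves under relaxation `config$omega_pnpb` until
#' the max-norm potential update falls below `config$tol`.
#'
#' @param domain a `pnpb_domain`; `domain$sigma` is ignored (both ends are
#'   reservoirs at Dirichlet potential).
#' @param comp a `pnpb_composition`; its bulk concentrations define the
#'   steric reference state.
#' @param transport a `pnpb_transport`.
#' @param config a `pnpb_solver_config`.
#' @return list with `state` (a `pnpb_field_state`-like list including
#'   `phi`, `C`, `Gamma`, `S`) and `flux` (class `pnpb_flux`: per-species
#'   edge flux matrix `J`, species means `J_mean`, total current density
#'   `I`, spatial relative variation `J_variation`, and SG stability
#'   margins).
#' @export
solve_pnpb_steady <- function(domain, comp, transport,
                              config = solver_config()) {
  n <- domain$n
  h <- domain$L / (n - 1)
  x <- seq(0, domain$L, length.out = n)
  lB <- bjerrum_length(domain$eps_s, comp$T)
  fourpilB <- 4 * pi * lB
  K1 <- comp$K + 1
  CL <- molar_to_number(transport$left_M)
  CR <- molar_to_number(transport$right_M)
  stopifnot(length(CL) == K1, length(CR) == K1)
  Dedge <- matrix(rep(transport$D, each = n - 1), n - 1, K1)
  if (!is.null(transport$pore_range)) {
    xm <- (x[-1] + x[-n]) / 2
    inpore <- xm >= transport$pore_range[1] & xm <= transport$pore_range[2]
    Dedge[inpore, ] <- Dedge[inpore, ] * transport$theta
  }
  p <- if (comp$v0 > 0) comp$v / comp$v0 else rep(0, K1)

  ## initial state: linear potential at V = 0, bulk-interpolated C
  phi <- numeric(n)
  C <- sapply(seq_len(K1), function(i) seq(CL[i], CR[i], length.out = n))
  Vtargets <- if (transport$V == 0) 0 else
    seq(0, transport$V, by = sign(transport$V) * min(config$dV,
                                                     abs(transport$V)))
  if (utils::tail(Vtargets, 1) != transport$V)
    Vtargets <- c(Vtargets, transport$V)

  for (V in Vtargets) {
    for (it in seq_len(config$max_iter)) {
      Gamma <- 1 - as.vector(C %*% comp$v)
      Gamma <- pmax(Gamma, 1e-12)
      S <- log(Gamma / comp$Gamma_B)
      ## NP solves, species by species
      for (i in seq_len(K1)) {
        C[, i] <- solve_np(phi, S, comp$z[i], p[i], Dedge[, i], h,
                           CL[i], CR[i])
      }
      Gamma <- pmax(1 - as.vector(C %*% comp$v), 1e-12)
      S <- log(Gamma / comp$Gamma_B)
      rho <- fourpilB * charge_density(C, comp)
      m <- fourpilB * as.vector(C %*% comp$z^2)
      Psi <- solve_aux_field_dirichlet(rho, h, domain$lc^2)
      ## (-D2 + m) phi_new = -Psi + m phi_old, Dirichlet V / 0
      lower <- rep(-1 / h^2, n - 1); upper <- rep(-1 / h^2, n - 1)
      diag0 <- 2 / h^2 + m
      b <- -Psi + m * phi
      diag0[1] <- 1; upper[1] <- 0; b[1] <- V
      diag0[n] <- 1; lower[n - 1] <- 0; b[n] <- 0
      phinew <- tridiag_solve(lower, diag0, upper, b)
      err <- max(abs(phinew - phi))
      phi <- config$omega_pnpb * phi + (1 - config$omega_pnpb) * phinew
      if (err < config$tol) break
    }
    if (err >= config$tol)
      stop("transport solve did not converge at V = ", V,
           ": max-norm potential update ", format(err), call. = FALSE)
  }

  ## final NP solve at the converged fields so that the reported fluxes
  ## are exactly divergence-free for the (phi, S) they are computed with
  Gamma <- pmax(1 - as.vector(C %*% comp$v), 1e-12)
  S <- log(Gamma / comp$Gamma_B)
  for (i in seq_len(K1))
    C[, i] <- solve_np(phi, S, comp$z[i], p[i], Dedge[, i], h, CL[i], CR[i])
  J <- sapply(seq_len(K1), function(i) {
    t_edge <- comp$z[i] * diff(phi) - p[i] * diff(S)
    edge_fluxes(C[, i], t_edge, Dedge[, i], h)
  })
  colnames(J) <- comp$name
  S_used <- S
  Gamma <- pmax(1 - as.vector(C %*% comp$v), 1e-12)
  S <- log(Gamma / comp$Gamma_B)
  Jm <- colMeans(J)
  Jvar <- apply(J, 2, function(j)
    if (max(abs(j)) > 0) (max(j) - min(j)) / max(abs(j)) else 0)
  zion <- comp$z; zion[K1] <- 0
  I <- sum(zion * Jm)
  margins <- sapply(seq_len(K1), function(i)
    max(stability_margin(diff(phi), p[i] * diff(S), comp$z[i])$margin))
  state <- list(x = x, phi = phi, C = C, Gamma = Gamma, S = S,
                rho = charge_density(C, comp), lB = lB, domain = domain,
                composition = comp)
  flux <- structure(list(J = J, J_mean = Jm, J_variation = Jvar, I = I,
                         max_margin = margins), class = "pnpb_flux")
  list(state = state, flux = flux)
}

## Dirichlet-Dirichlet variant of the auxiliary-field solve (Psi = 0 at
## both reservoirs; reservoirs are charge-neutral far fields).
solve_aux_field_dirichlet <- function(rho, h, lc2) {
  n <- length(rho)
  if (lc2 == 0) return(-rho)
  lower <- rep(lc2 / h^2, n - 1)
  upper <- rep(lc2 / h^2, n - 1)
  diag0 <- rep(-2 * lc2 / h^2 - 1, n)
  b <- rho
  diag0[1] <- 1; upper[1] <- 0; b[1] <- 0
  diag0[n] <- 1; lower[n - 1] <- 0; b[n] <- 0
  tridiag_solve(lower, diag0, upper, b)
}

#' @export
print.pnpb_flux <- function(x, ...) {
  cat("Steady-state NPB fluxes (reduced units)\n")
  df <- data.frame(species = names(x$J_mean), J = x$J_mean,
                   rel_variation = x$J_variation,
                   max_SG_margin = x$max_margin)
  print(df, row.names = FALSE)
  cat(sprintf("total current density I = %.6g e/(A^2 time)\n", x$I))
  invisible(x)
}
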