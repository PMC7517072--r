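#' Hydration specification of a single ion
#'
#' Collects the single-ion parameters of the generalized Debye-Hueckel
#' model: the (Pauling) ionic radius, the experimental Born cavity radius at
#' infinite dilution, the water coordination number of the hydration shell,
#' and the three Born-radius scaling parameters that absorb the
#' concentration dependence of the solvation energy.
#'
#' @param name ion name, e.g. "Cl-".
#' @param z integer valence.
#' @param a_A Pauling radius in Angstrom.
#' @param R0_A experimental Born radius at infinite dilution, Angstrom.
#' @param O_w water coordination (occupancy) number of the hydration shell.
#' @param alpha numeric length-3: Born-scaling parameters (dimensionless).
#' @param eps_ion dielectric constant inside the ionic cavity.
#' @return object of class `pnpb_hydration`.
#' @export
hydration_spec <- function(name, z, a_A, R0_A, O_w = 18,
                           alpha = c(0, 0, 0), eps_ion = 1) {
  stopifnot(R0_A > 0, O_w >= 0, length(alpha) == 3, a_A >= 0)
  structure(list(name = name, z = as.integer(z), a = a_A, R0 = R0_A,
                 O_w = O_w, alpha = as.numeric(alpha), eps_ion = eps_ion),
            class = "pnpb_hydration")
}

#' Steric linearization factor Lambda of a binary electrolyte
#'
#' First-order (in the electric potential) response of the charge density
#' including the steric potential:
#' `Lambda = C1 (v1 - v2)^2 / {Gamma_B [v0 + v1^2 C1 + v2^2 C2 + v3^2 C3]}`
#' with species 1 = cation, 2 = anion, 3 = water. It vanishes when cation
#' and anion have equal volumes and in the point-particle limit.
#'
#' @param comp a `pnpb_composition` with exactly two ionic species (cation
#'   first) plus water.
#' @return dimensionless Lambda.
#' @export
lambda_factor <- function(comp) {
  if (comp$K != 2)
    stop("Lambda is defined for a binary electrolyte (2 ionic species + water)")
  v <- comp$v; C <- comp$C_bulk
  if (comp$z[1] <= 0) stop("first species must be the cation")
  if (v[1] == v[2]) return(0)   # equal volumes (incl. point particles)
  C[1] * (v[1] - v[2])^2 /
    (comp$Gamma_B * (comp$v0 + sum(v^2 * C)))
}

#' Screening lengths of the generalized Debye-Hueckel model
#'
#' Computes the Bjerrum length, the classical Debye length, the steric
#' linearization factor `Lambda`, the generalized Debye length
#' `lD4 = [eps_s kBT / (C1 ((1 - Lambda) q1^2 - q1 q2))]^(1/2)` (expressed
#' through the Bjerrum length in reduced units) and the density-density
#' correlation length `lc = sqrt(lB lD / 48)`.
#'
#' @param comp binary `pnpb_composition` (cation, anion, water).
#' @param eps_w relative permittivity of the solvent.
#' @return list with `lB`, `lD`, `Lambda`, `lD4`, `lc` (Angstrom).
#' @export
screening_lengths <- function(comp, eps_w = 78.45) {
  lB <- bjerrum_length(eps_w, comp$T)
  lD <- debye_length(comp, eps_w)
  Lam <- lambda_factor(comp)
  z1 <- comp$z[1]; z2 <- comp$z[2]; C1 <- comp$C_bulk[1]
  denom <- C1 * ((1 - Lam) * z1^2 - z1 * z2)
  if (is.finite(lD) && denom <= 0)
    stop("infeasible parameters: nonpositive argument for the generalized ",
         "Debye length")
  lD4 <- if (C1 == 0) Inf else 1 / sqrt(4 * pi * lB * denom)
  lc <- if (is.finite(lD)) sqrt(lB * lD / 48) else Inf
  list(lB = lB, lD = lD, Lambda = Lam, lD4 = lD4, lc = lc)
}

#' Spectral roots of the linearized fourth-order operator
#'
#' The linearized fourth-order Poisson-Bikerman operator factorizes into two
#' exponential screening modes with inverse lengths
#' `lambda_{1,2} = sqrt((1 -/+ sqrt(1 - 4 lc^2/lD4^2)) / (2 lc^2))`.
#' They satisfy the Vieta identities
#' `lambda1^2 + lambda2^2 = 1/lc^2` and
#' `lambda1^2 lambda2^2 = 1/(lc^2 lD4^2)`. In the limit `lc -> 0` the slow
#' root tends to the inverse generalized Debye length and the fast root to
#' infinity (flagged via `lc_zero`).
#'
#' @param lc correlation length, Angstrom (>= 0).
#' @param lD4 generalized Debye length, Angstrom (> 0).
#' @return list with `lambda1 <= lambda2` (1/Angstrom) and flag `lc_zero`.
#' @export
spectral_roots <- function(lc, lD4) {
  stopifnot(lc >= 0, lD4 > 0)
  if (lc == 0)
    return(list(lambda1 = 1 / lD4, lambda2 = Inf, lc_zero = TRUE))
  disc <- 1 - 4 * lc^2 / lD4^2
  if (disc < 0)
    stop("complex spectral roots: 4 lc^2 > lD4^2 is outside the validated ",
         "regime of the closed-form model", call. = FALSE)
  ## cancellation-free form of (1 - sqrt(disc))/(2 lc^2)
  l1sq <- 2 / (lD4^2 * (1 + sqrt(disc)))
  l2sq <- (1 + sqrt(disc)) / (2 * lc^2)
  list(lambda1 = sqrt(l1sq), lambda2 = sqrt(l2sq), lc_zero = FALSE)
}

#' Correlation geometry factor Theta
#'
#' `Theta = (lambda1^2 - lambda2^2) /
#'   [lambda1^2 (lambda2 Rsh + 1) - lambda2^2 (lambda1 Rsh + 1)]`,
#' algebraically equal to `(l1 + l2) / (l1 l2 Rsh + l1 + l2)`, which is the
#' form used for coalescing roots (`lambda1 = lambda2`) and for the
#' `lambda2 -> Inf` limit `1 / (1 + lambda1 Rsh)`. Tends to 1 at infinite
#' dilution.
#'
#' @param lambda1,lambda2 spectral roots, 1/Angstrom (real, >= 0).
#' @param Rsh hydration-shell outer radius, Angstrom.
#' @return dimensionless Theta.
#' @export
theta_factor <- function(lambda1, lambda2, Rsh) {
  stopifnot(lambda1 >= 0, lambda2 >= 0, Rsh >= 0)
  if (is.infinite(lambda2)) return(1 / (1 + lambda1 * Rsh))
  den <- lambda1 * lambda2 * Rsh + lambda1 + lambda2
  if (den == 0) stop("degenerate geometry: zero denominator in Theta")
  (lambda1 + lambda2) / den
}

#' Hydration-shell volume and radius from the steric condition
#'
#' The shell volume `Vsh` around an ion holding `O_w` water molecules is
#' fixed by equating the two expressions for the shell steric potential,
#' `ln[(Vsh - vw O_w)/(Vsh Gamma_B)] = (v0/vw) ln[O_w/(Vsh Cw^B)]`,
#' solved by bracketed root finding. The outer shell radius follows from
#' `Vsh = (4 pi/3)(Rsh^3 - a_i^3)` with `a_i` the Pauling radius.
#'
#' @param spec a `pnpb_hydration` (for `O_w` and the Pauling radius).
#' @param comp a `pnpb_composition` providing `v0`, `Gamma_B` and the bulk
#'   water concentration (water is the last species).
#' @return list with `V_sh` (A^3) and `R_sh` (A).
#' @export
shell_radius <- function(spec, comp) {
  if (spec$O_w <= 0) stop("shell equation requires O_w > 0")
  vw <- comp$v[comp$K + 1]
  Cw <- comp$C_bulk[comp$K + 1]
  if (vw <= 0 || Cw <= 0) stop("composition must contain finite-size water")
  resid <- function(V)
    log((V - vw * spec$O_w) / (V * comp$Gamma_B)) -
      (comp$v0 / vw) * log(spec$O_w / (V * Cw))
  lo <- vw * spec$O_w * (1 + 1e-9)
  hi <- vw * spec$O_w * 1e4
  flo <- resid(lo); fhi <- resid(hi)
  if (!is.finite(flo) || !is.finite(fhi) || flo * fhi > 0)
    stop("no solution: shell steric equation has no sign change in the ",
         "bracket (over-packed shell?)", call. = FALSE)
  V <- stats::uniroot(resid, c(lo, hi), tol = 1e-13)$root
  if (V <= vw * spec$O_w)
    stop("over-packed shell: v_w O_w >= V_sh at the root")
  R <- (3 * V / (4 * pi) + spec$a^3)^(1 / 3)
  list(V_sh = V, R_sh = R)
}

#' Concentration-dependent Born radius
#'
#' `R_Born = theta R0` with
#' `theta = 1 + alpha1 sqrt(Cb) + alpha2 Cb + alpha3 Cb^(3/2)` and `Cb` the
#' dimensionless bulk concentration of the ion (numerically its molarity).
#'
#' @param spec a `pnpb_hydration`.
#' @param conc_M bulk concentration of the ion in mol/L (>= 0).
#' @return Born radius in Angstrom.
#' @export
born_radius <- function(spec, conc_M) {
  stopifnot(conc_M >= 0)
  cb <- conc_M
  th <- 1 + spec$alpha[1] * sqrt(cb) + spec$alpha[2] * cb +
    spec$alpha[3] * cb^1.5
  if (any(th <= 0))
    stop("invalid parameters: Born scaling theta <= 0")
  th * spec$R0
}

#' Generalized Debye-Hueckel summary for one ion in one solution
#'
#' Assembles all scalars of the closed-form model: screening lengths,
#' spectral roots, `Theta`, Born and shell radii, the excess chemical
#' potential and the activity coefficient.
#'
#' @param spec a `pnpb_hydration` for the ion of interest.
#' @param comp binary `pnpb_composition` containing that ion.
#' @param eps_w solvent dielectric constant.
#' @return object of class `pnpb_gdh`: list with `lB`, `lD`, `Lambda`,
#'   `lD4`, `lc`, `lambda1`, `lambda2`, `Theta`, `R_Born`, `R_sh`, `V_sh`,
#'   `mu_ex` (kBT) and `ln_gamma`.
#' @export
gdh <- function(spec, comp, eps_w = 78.45) {
  sl <- screening_lengths(comp, eps_w)
  sh <- shell_radius(spec, comp)
  conc <- comp$conc_M[match(spec$name, comp$name)]
  if (is.na(conc)) {
    ## ion not named in the composition: use the matching-valence species
    idx <- which(comp$z == spec$z)[1]
    if (is.na(idx)) stop("ion ", spec$name, " not found in composition")
    conc <- comp$conc_M[idx]
  }
  RB <- born_radius(spec, conc)
  if (is.finite(sl$lD4)) {
    ro <- spectral_roots(sl$lc, sl$lD4)
    Th <- theta_factor(ro$lambda1, ro$lambda2, sh$R_sh)
  } else {
    ro <- list(lambda1 = 0, lambda2 = Inf)
    Th <- 1
  }
  lng <- 0.5 * spec$z^2 * sl$lB *
    (1 / RB - 1 / spec$R0 + (Th - 1) / sh$R_sh)
  structure(list(
    ion = spec$name, lB = sl$lB, lD = sl$lD, Lambda = sl$Lambda,
    lD4 = sl$lD4, lc = sl$lc, lambda1 = ro$lambda1, lambda2 = ro$lambda2,
    Theta = Th, R_Born = RB, R0 = spec$R0, R_sh = sh$R_sh, V_sh = sh$V_sh,
    mu_ex = lng, ln_gamma = lng
  ), class = "pnpb_gdh")
}

#' @export
print.pnpb_gdh <- function(x, ...) {
  cat(sprintf(
    "Generalized Debye-Hueckel result for %s\n  lB=%.4f  lD=%.4f  lD4=%.4f  lc=%.4f A\n  Lambda=%.3e  lambda1=%.5f  lambda2=%.5f 1/A  Theta=%.6f\n  R_Born=%.4f  R_sh=%.4f A  ln gamma=%.6f\n",
    x$ion, x$lB, x$lD, x$lD4, x$lc, x$Lambda, x$lambda1, x$lambda2,
    x$Theta, x$R_Born, x$R_sh, x$ln_gamma))
  invisible(x)
}

#' Reaction potential around a solvated ion
#'
#' Three-branch closed-form reaction potential of the linearized
#' fourth-order model, in reduced units (kBT/e):
#' constant inside the ionic cavity (`r < R_Born`), Coulombic across the
#' hydration shell, and a two-mode screened Coulomb decay in the solvent
#' (`r > R_sh`). Continuous across both interfaces.
#'
#' @param r radial distance(s) from the ion center, Angstrom (>= 0).
#' @param g a `pnpb_gdh` result.
#' @param z ion valence (defaults to sign/magnitude implied by `g` if
#'   computed via [gdh()]; must be supplied when `g` is hand-built).
#' @return potential in kBT/e, same length as `r`.
#' @export
reaction_potential <- function(r, g, z) {
  stopifnot(all(r >= 0))
  l1 <- g$lambda1; l2 <- g$lambda2; Rs <- g$R_sh
  q <- z * g$lB
  core <- q * (1 / g$R_Born + (g$Theta - 1) / Rs)
  shell <- function(rr) q * (1 / rr + (g$Theta - 1) / Rs)
  solv <- function(rr) {
    if (is.infinite(l2)) {
      ## lc -> 0 limit: single screened mode
      q / rr * exp(-l1 * (rr - Rs)) / (1 + l1 * Rs)
    } else {
      den <- l1^2 * (l2 * Rs + 1) - l2^2 * (l1 * Rs + 1)
      q / rr * (l1^2 * exp(-l2 * (rr - Rs)) - l2^2 * exp(-l1 * (rr - Rs))) / den
    }
  }
  out <- numeric(length(r))
  inside <- r < g$R_Born
  mid <- !inside & r < Rs
  far <- !inside & !mid
  out[inside] <- core
  out[mid] <- shell(r[mid])
  out[far] <- solv(r[far])
  out
}

#' Single-ion activity coefficient
#'
#' Three modes:
#' \describe{
#'   \item{generalized}{closed-form model:
#'     `ln gamma = (z^2 lB / 2) [1/R_Born - 1/R0 + (Theta - 1)/R_sh]`.}
#'   \item{classical_DH}{the 1923 Debye-Hueckel form
#'     `ln gamma = -(z^2 lB / 2) / (lD (1 + R/lD))` with `R` the distance of
#'     closest approach (here the hydration-shell radius unless overridden).}
#'   \item{extended_DHB}{the 1925 Hueckel extension
#'     `ln gamma = -(z^2 lB / 2) / (lD (1 + eta0 sqrt(I))) + eta1 I` with
#'     ionic strength `I = 0.5 sum C_i z_i^2` in mol/L.}
#' }
#'
#' @param spec a `pnpb_hydration`.
#' @param comp binary `pnpb_composition`.
#' @param mode one of "generalized", "classical_DH", "extended_DHB".
#' @param eps_w solvent dielectric constant.
#' @param R_closest distance of closest approach for the classical mode
#'   (Angstrom); defaults to the hydration-shell radius.
#' @param eta for `extended_DHB`: numeric `c(eta0, eta1)`.
#' @return `ln gamma` (dimensionless).
#' @export
activity_coefficient <- function(spec, comp,
                                 mode = c("generalized", "classical_DH",
                                          "extended_DHB"),
                                 eps_w = 78.45, R_closest = NULL,
                                 eta = c(0, 0)) {
  mode <- match.arg(mode)
  lB <- bjerrum_length(eps_w, comp$T)
  lD <- debye_length(comp, eps_w)
  if (mode == "generalized") {
    g <- gdh(spec, comp, eps_w)
    if (g$R_sh <= 0) stop("generalized mode requires R_sh > 0")
    return(g$ln_gamma)
  }
  if (mode == "classical_DH") {
    if (is.null(R_closest)) R_closest <- shell_radius(spec, comp)$R_sh
    if (!is.finite(lD)) return(0)
    return(-0.5 * spec$z^2 * lB / (lD * (1 + R_closest / lD)))
  }
  ## extended_DHB
  ionic <- comp$z != 0
  I <- 0.5 * sum(comp$conc_M[ionic] * comp$z[ionic]^2)
  if (!is.finite(lD)) return(eta[2] * I)
  -0.5 * spec$z^2 * lB / (lD * (1 + eta[1] * sqrt(I))) + eta[2] * I
}

#' Excess chemical potential of a single ion
#'
#' `mu_ex = (z/2) [phi(0) - phi0(0)]` in kBT, with `phi` the reaction
#' potential of the solution and `phi0` its infinite-dilution limit
#' `z lB / R0`. Shares the closed-form code path with
#' [activity_coefficient()], so `mu_ex = ln gamma` identically.
#'
#' @param spec a `pnpb_hydration`.
#' @param comp binary `pnpb_composition`.
#' @param eps_w solvent dielectric constant.
#' @return excess chemical potential in kBT.
#' @export
excess_chemical_potential <- function(spec, comp, eps_w = 78.45) {
  g <- gdh(spec, comp, eps_w)
  phi0_center <- spec$z * g$lB / spec$R0
  0.5 * spec$z * (reaction_potential(0, g, spec$z) - phi0_center)
}

#' Fit Born-scaling parameters to activity data
#'
#' Least-squares estimation of the three Born-scaling parameters from a
#' table of (concentration, measured activity coefficient) pairs for one
#' ion in a binary salt, using Levenberg-Marquardt on the residuals
#' `ln gamma_model - ln gamma_data`.
#'
#' @param data data.frame with columns `conc_M` and `gamma` (> 0).
#' @param spec a `pnpb_hydration` for the ion (its `alpha` is ignored).
#' @param comp_fun function(conc_M) returning the `pnpb_composition` of the
#'   salt solution at that concentration; see [binary_salt()].
#' @param eps_w solvent dielectric constant.
#' @param start starting values for the three parameters.
#' @return list with `alpha` (length 3), `residual_norm` and the `nls.lm`
#'   convergence `info`.
#' @export
fit_activity_parameters <- function(data, spec, comp_fun, eps_w = 78.45,
                                    start = c(0, 0, 0)) {
  stopifnot(is.data.frame(data), all(c("conc_M", "gamma") %in% names(data)))
  if (nrow(data) < 3)
    stop("under-determined fit: need at least 3 data points for 3 parameters")
  if (any(data$gamma <= 0)) stop("activity coefficients must be positive")
  lg_obs <- log(data$gamma)
  comps <- lapply(data$conc_M, comp_fun)
  model <- function(alpha) {
    sp <- spec; sp$alpha <- alpha
    vapply(seq_len(nrow(data)), function(i)
      activity_coefficient(sp, comps[[i]], "generalized", eps_w),
      numeric(1))
  }
  res <- minpack.lm::nls.lm(par = start,
                            fn = function(p) model(p) - lg_obs,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200, ftol = 1e-15, ptol = 1e-15))
  list(alpha = unname(res$par),
       residual_norm = sqrt(sum(res$fvec^2)),
       info = res$info)
}

#' Composition builder for a binary salt at variable concentration
#'
#' Returns a function mapping salt molarity to a `pnpb_composition`, for
#' use with [fit_activity_parameters()] and activity scans.
#'
#' @param cation,anion names of the two ions.
#' @param z numeric length-2 valences (cation positive).
#' @param radius_A numeric length-2 Pauling radii.
#' @param nu numeric length-2 stoichiometric numbers (e.g. `c(1, 2)` for
#'   CaCl2); defaults to the electroneutral pair for the given valences.
#' @param water_radius_A,water_conc_M,T water and temperature parameters.
#' @return function(conc_M) -> `pnpb_composition`.
#' @export
binary_salt <- function(cation, anion, z, radius_A,
                        nu = c(abs(z[2]), abs(z[1])),
                        water_radius_A = 1.4, water_conc_M = 55.5,
                        T = 298.15) {
  force(nu)
  function(conc_M) {
    electrolyte(name = c(cation, anion), z = z, radius_A = radius_A,
                conc_M = conc_M * nu,
                water_radius_A = water_radius_A,
                water_conc_M = water_conc_M, T = T)
  }
}
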