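#' Electrolyte composition with finite-size ions, water and voids
#'
#' Builds the composition object used throughout the package. Every species
#' (ions and water) carries a valence, a radius and a bulk concentration; the
#' per-species volume `v_i = 4 pi a_i^3 / 3`, the average particle volume
#' `v0 = sum(v_i)/(K+1)` and the bulk void volume fraction
#' `Gamma_B = 1 - sum(v_i C_i^B)` are derived. Water must be the last species
#' and have valence zero; whatever volume is not occupied by ions or water is
#' interstitial void, and `Gamma_B > 0` is required for the composition to be
#' physically realizable.
#'
#' @param species a data.frame with columns `name`, `z` (integer valence),
#'   `radius_A` (Angstrom, >= 0) and `conc_M` (mol/L, >= 0). The last row must
#'   be water (`z = 0`). A radius of zero puts that species in the
#'   point-particle limit: it occupies no volume and does not enter the void
#'   fraction.
#' @param T absolute temperature in kelvin.
#' @return an object of class `pnpb_composition` with elements `name`, `z`,
#'   `a`, `v` (A^3), `conc_M`, `C_bulk` (A^-3), `K` (number of ionic
#'   species), `v0` (A^3), `Gamma_B` and `T`.
#' @examples
#' comp <- make_composition(data.frame(
#'   name = c("Na+", "Cl-", "H2O"),
#'   z = c(1, -1, 0),
#'   radius_A = c(0.95, 1.81, 1.4),
#'   conc_M = c(0.1, 0.1, 55.5)))
#' comp$Gamma_B
#' @export
make_composition <- function(species, T = 298.15) {
  required <- c("name", "z", "radius_A", "conc_M")
  if (!is.data.frame(species) || !all(required %in% names(species)))
    stop("`species` must be a data.frame with columns ",
         paste(required, collapse = ", "))
  K1 <- nrow(species)
  if (K1 < 1)
    stop("need at least water (and usually ionic species)")
  z <- as.numeric(species$z)
  a <- as.numeric(species$radius_A)
  conc_M <- as.numeric(species$conc_M)
  if (z[K1] != 0)
    stop("water (valence 0) must be the last species")
  if (any(a < 0)) stop("radii must be >= 0")
  if (any(conc_M < 0)) stop("concentrations must be >= 0")
  if (any(z[-K1] != round(z[-K1])))
    stop("ionic valences must be integers")

  C_bulk <- molar_to_number(conc_M)
  ionic <- seq_len(K1 - 1)
  net <- sum(z[ionic] * C_bulk[ionic])
  scale <- sum(abs(z[ionic]) * C_bulk[ionic])
  if (scale > 0 && abs(net) > 1e-12 * scale)
    stop("ionic species are not electroneutral: sum z_i C_i = ",
         format(net), " A^-3", call. = FALSE)

  v <- sphere_volume(a)
  v0 <- sum(v) / K1
  Gamma_B <- 1 - sum(v * C_bulk)
  if (Gamma_B <= 0)
    stop("infeasible composition: bulk void fraction Gamma_B = ",
         format(Gamma_B), " <= 0 (over-packed bulk)", call. = FALSE)
  if (any(v * C_bulk >= 1))
    stop("infeasible composition: v_i C_i^B >= 1 for species ",
         paste(species$name[v * C_bulk >= 1], collapse = ", "), call. = FALSE)

  structure(list(
    name = as.character(species$name), z = z, a = a, v = v,
    conc_M = conc_M, C_bulk = C_bulk, K = K1 - 1L,
    v0 = v0, Gamma_B = Gamma_B, T = T
  ), class = "pnpb_composition")
}

#' Convenience constructor for a salt solution in water
#'
#' @param name character vector of ion names.
#' @param z integer valences of the ions.
#' @param radius_A ionic radii in Angstrom.
#' @param conc_M bulk ion concentrations in mol/L.
#' @param water_radius_A water radius in Angstrom.
#' @param water_conc_M bulk water concentration in mol/L (55.5 M for liquid
#'   water at room temperature).
#' @param T temperature in kelvin.
#' @return a `pnpb_composition`.
#' @export
electrolyte <- function(name, z, radius_A, conc_M,
                        water_radius_A = 1.4, water_conc_M = 55.5,
                        T = 298.15) {
  make_composition(data.frame(
    name = c(name, "H2O"),
    z = c(z, 0),
    radius_A = c(radius_A, water_radius_A),
    conc_M = c(conc_M, water_conc_M)), T = T)
}

#' @export
print.pnpb_composition <- function(x, ...) {
  cat("Electrolyte composition (", x$K, " ionic species + water, T = ",
      x$T, " K)\n", sep = "")
  df <- data.frame(name = x$name, z = x$z, radius_A = x$a,
                   v_A3 = round(x$v, 3), conc_M = x$conc_M)
  print(df, row.names = FALSE)
  cat(sprintf("v0 = %.4f A^3, Gamma_B = %.6f\n", x$v0, x$Gamma_B))
  invisible(x)
}

#' Void volume fraction of a concentration state
#'
#' `Gamma = 1 - sum_i v_i C_i` over all particle species including water.
#'
#' @param C concentration state: a numeric vector of length K+1 (one value
#'   per species) or an n x (K+1) matrix of per-node concentrations, A^-3.
#' @param comp a `pnpb_composition`.
#' @return void fraction, scalar or length-n vector.
#' @export
void_fraction <- function(C, comp) {
  if (is.matrix(C)) {
    stopifnot(ncol(C) == comp$K + 1)
    G <- 1 - as.vector(C %*% comp$v)
  } else {
    stopifnot(length(C) == comp$K + 1)
    G <- 1 - sum(comp$v * C)
  }
  if (any(C < 0)) stop("concentrations must be >= 0")
  if (any(G <= 0))
    stop("saturation violation: sum v_i C_i >= 1 (void fraction <= 0)",
         call. = FALSE)
  G
}

#' Steric potential
#'
#' `S = ln(Gamma / Gamma_B)`: the entropic potential measuring local
#' crowding (S < 0) or emptiness (S > 0) relative to the bulk.
#'
#' @param Gamma local void fraction(s), > 0.
#' @param Gamma_B bulk void fraction, > 0.
#' @return dimensionless steric potential.
#' @export
steric_potential <- function(Gamma, Gamma_B) {
  if (any(Gamma <= 0) || Gamma_B <= 0)
    stop("void fractions must be positive to evaluate the steric potential")
  log(Gamma / Gamma_B)
}

#' Fermi (saturating) concentrations at given electric and steric potentials
#'
#' `C_i = C_i^B exp(-z_i phi + (v_i/v0) S)`; water has valence zero and
#' responds only to the steric potential. No self-consistency between `C`
#' and the void fraction is imposed here; see [fermi_state()] for the
#' self-consistent solve.
#'
#' @param phi reduced electric potential (kBT/e), scalar or length-n vector.
#' @param S steric potential, scalar or vector conformable with `phi`.
#' @param comp a `pnpb_composition`.
#' @return an n x (K+1) matrix of concentrations (A^-3); a vector input of
#'   length 1 gives a 1-row matrix.
#' @export
fermi_concentrations <- function(phi, S, comp) {
  n <- max(length(phi), length(S))
  phi <- rep_len(phi, n); S <- rep_len(S, n)
  p <- if (comp$v0 > 0) comp$v / comp$v0 else rep(0, comp$K + 1)
  expo <- outer(-phi, comp$z) + outer(S, p)
  C <- sweep(exp(expo), 2, comp$C_bulk, "*")
  ## 0 * exp(Inf) -> 0: a species absent from the bath stays absent
  C[, comp$C_bulk == 0] <- 0
  colnames(C) <- comp$name
  C
}

#' Self-consistent Fermi state at a given electric potential
#'
#' Solves the implicit system `C_i = C_i^B exp(-z_i phi + (v_i/v0) S)`,
#' `Gamma = 1 - sum v_i C_i`, `S = ln(Gamma/Gamma_B)` for the void fraction
#' at every node. The root in `Gamma` is unique in (0, 1); it is bracketed
#' and found by a vectorized bisection on `log(Gamma)` (robust for reduced
#' potentials up to about 1e6 and beyond, monotone residual, driven to the
#' representable precision of the root, well below `tol`).
#' Infinite potentials are mapped to the analytic saturation limit:
#' the species with diverging Boltzmann factor saturates at `C_i = 1/v_i`,
#' the void fraction tends to zero and all other species are excluded.
#'
#' @param phi reduced electric potential, length-n vector (may contain
#'   +/-Inf).
#' @param comp a `pnpb_composition`.
#' @param steric_scale continuation multiplier in `[0, 1]` applied to all
#'   particle volumes (0 recovers Boltzmann statistics); used by the
#'   nonlinear solvers, default 1.
#' @param exponent steric-energy weighting: `"volume_ratio"` (the default,
#'   exponent `v_i/v0` so that larger particles feel a proportionally
#'   larger steric energy) or `"uniform"` (exponent 1 for every
#'   finite-size species: the identical-steric-energy closure of the
#'   original binary Bikerman model).
#' @param tol relative tolerance of the fixed point.
#' @return list with `C` (n x (K+1) matrix), `Gamma`, `S` (length-n) and
#'   `Gamma_B` (the bulk void fraction at the given `steric_scale`).
#' @export
fermi_state <- function(phi, comp, steric_scale = 1,
                        exponent = c("volume_ratio", "uniform"),
                        tol = 1e-12) {
  stopifnot(steric_scale >= 0, steric_scale <= 1)
  exponent <- match.arg(exponent)
  n <- length(phi)
  vt <- steric_scale * comp$v
  GB <- 1 - sum(vt * comp$C_bulk)
  if (GB <= 0) stop("infeasible composition under steric_scale")
  K1 <- comp$K + 1

  if (steric_scale == 0 || all(vt == 0)) {
    C <- fermi_concentrations(phi, 0, comp)
    return(list(C = C, Gamma = rep(1, n), S = rep(0, n), Gamma_B = 1))
  }

  p <- if (exponent == "uniform") as.numeric(vt > 0) else vt / comp$v0
  finite <- is.finite(phi)
  Gamma <- rep(NA_real_, n); S <- rep(NA_real_, n)
  C <- matrix(0, n, K1, dimnames = list(NULL, comp$name))

  if (any(finite)) {
    ph <- phi[finite]
    ## log of v_i * C_i as a function of t = log(Gamma):
    ##   log(v_i C_i) = s_i + p_i t,  s_i = log(v_i C_i^B) - z_i phi - p_i log(GB)
    s <- outer(-ph, comp$z) + matrix(log(vt * comp$C_bulk) - p * log(GB),
                                     nrow = length(ph), ncol = K1,
                                     byrow = TRUE)
    keep <- vt > 0 & comp$C_bulk > 0
    s <- s[, keep, drop = FALSE]
    pk <- p[keep]
    ## residual g(t) = 1 - exp(t) - sum_i exp(s_i + p_i t), decreasing in t
    g <- function(t) 1 - exp(t) -
      rowSums(exp(s + tcrossprod(t, pk)))
    ## the root is bracketed in [lo, 0]: below lo every packing term is
    ## < exp(-50); 120 bisection steps drive the interval below the
    ## representable precision of t (the residual is monotone in t, so
    ## this is exact to machine precision, well inside `tol`)
    lo <- pmin(-1, -apply(sweep(s, 2, pk, "/"), 1, max) - 50 / min(pk))
    hi <- rep(0, length(ph))
    for (it in 1:120) {
      mid <- 0.5 * (lo + hi)
      pos <- g(mid) > 0
      lo <- ifelse(pos, mid, lo)
      hi <- ifelse(pos, hi, mid)
      if (max(hi - lo) < tol * 1e-3) break
    }
    ## take the below-root endpoint: guarantees sum v_i C_i < 1 strictly
    t <- lo
    Gamma[finite] <- exp(t)
    S[finite] <- t - log(GB)
    Cf <- matrix(0, length(ph), K1)
    Cf[, keep] <- exp(s + tcrossprod(t, pk)) /
      matrix(vt[keep], length(ph), sum(keep), byrow = TRUE)
    ## species with volume 0 follow the Boltzmann factor directly
    if (any(!keep)) {
      bz <- exp(outer(-ph, comp$z[!keep]))
      Cf[, !keep] <- sweep(bz, 2, comp$C_bulk[!keep], "*")
    }
    C[finite, ] <- Cf
  }

  if (any(!finite)) {
    ## analytic saturation limit: the most attracted species fills the
    ## available volume, Gamma -> 0, S -> -Inf, other species vanish
    for (i in which(!finite)) {
      drive <- -comp$z * phi[i]            # +Inf for saturating species
      drive[comp$C_bulk == 0] <- -Inf
      sat <- which(drive == Inf & vt > 0)
      if (length(sat) == 0)
        stop("infinite potential with no saturating finite-size species")
      sat <- sat[1]
      C[i, ] <- 0
      C[i, sat] <- 1 / vt[sat]
      Gamma[i] <- 0; S[i] <- -Inf
    }
  }

  list(C = C, Gamma = Gamma, S = S, Gamma_B = GB)
}

#' Saturation bound of the Fermi distribution
#'
#' Upper bound on the concentration of a species for any (even infinite)
#' electric potential: `v0/v_i^2` when `v_i <= v0`, `1/v_i` otherwise.
#'
#' @param comp a `pnpb_composition`.
#' @return named vector of bounds (A^-3); `Inf` for point particles.
#' @export
saturation_bound <- function(comp) {
  b <- ifelse(comp$v <= comp$v0, comp$v0 / comp$v^2, 1 / comp$v)
  b[comp$v == 0] <- Inf
  names(b) <- comp$name
  b
}

#' Ionic charge density
#'
#' `rho = sum_{i <= K} z_i C_i` over the ionic species (water excluded),
#' in units of e per cubic Angstrom.
#'
#' @param C concentration vector (length K+1) or n x (K+1) matrix, A^-3.
#' @param comp a `pnpb_composition`.
#' @return charge density in e A^-3.
#' @export
charge_density <- function(C, comp) {
  zion <- comp$z
  zion[comp$K + 1] <- 0
  if (is.matrix(C)) as.vector(C %*% zion) else sum(C * zion)
}
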