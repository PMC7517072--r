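## Internal unit system: lengths in Angstrom (A), energies in kBT, electric
## potentials reduced to kBT/e, number densities in A^-3. All electrostatic
## constants enter through the Bjerrum length, so no SI bookkeeping leaks
## into the model equations.

.pnpb <- list(
  kB   = 1.380649e-23,      # J/K
  e    = 1.602176634e-19,   # C
  eps0 = 8.8541878128e-12,  # F/m
  M_to_A3 = 6.02214076e-4   # 1 mol/L in particles per A^3
)

#' Convert molar concentration to number density
#'
#' @param conc_M concentration in mol/L.
#' @return number density in particles per cubic Angstrom.
#' @export
molar_to_number <- function(conc_M) conc_M * .pnpb$M_to_A3

#' Convert number density to molar concentration
#'
#' @param n number density in particles per cubic Angstrom.
#' @return concentration in mol/L.
#' @export
number_to_molar <- function(n) n / .pnpb$M_to_A3

#' Bjerrum length
#'
#' Distance at which the Coulomb energy of two unit charges in a medium of
#' relative permittivity `eps_r` equals the thermal energy kBT.
#'
#' @param eps_r relative permittivity of the medium (dimensionless).
#' @param T absolute temperature in kelvin.
#' @return Bjerrum length in Angstrom.
#' @export
bjerrum_length <- function(eps_r = 78.45, T = 298.15) {
  stopifnot(eps_r > 0, T > 0)
  1e10 * .pnpb$e^2 / (4 * pi * .pnpb$eps0 * eps_r * .pnpb$kB * T)
}

#' Volume of a sphere of radius `a`
#'
#' @param a radius in Angstrom.
#' @return volume in cubic Angstrom.
#' @export
sphere_volume <- function(a) 4 * pi * a^3 / 3

#' Debye screening length of an ionic solution
#'
#' `1 / sqrt(4 pi lB sum_i C_i z_i^2)` over the ionic species, with the
#' Bjerrum length `lB` evaluated at the composition's temperature.
#'
#' @param comp an [electrolyte_composition()] object.
#' @param eps_r relative permittivity of the solvent.
#' @return Debye length in Angstrom.
#' @export
debye_length <- function(comp, eps_r = 78.45) {
  lB <- bjerrum_length(eps_r, comp$T)
  ionic <- comp$z != 0
  s <- sum(comp$C_bulk[ionic] * comp$z[ionic]^2)
  if (s <= 0) return(Inf)
  1 / sqrt(4 * pi * lB * s)
}
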