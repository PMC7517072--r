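# pnpbik

Mean-field modelling of ionic solutions in which ions **and water** are
finite-size particles with interstitial voids — for electrochemists,
biophysicists and ion-channel modellers who need saturating (non-Boltzmann)
ion distributions, ion–ion/ion–water correlations, single-ion activity
coefficients, and atomic-scale binding-site energetics from one consistent
theory.

## The model in brief

Every species *i* (ions and water) occupies a volume `v_i = (4π/3)a_i³`;
the space not occupied is void. With bulk void fraction
`Γ_B = 1 − Σ v_i C_i^B` and local void fraction `Γ(x)`, the **steric
potential** `S = ln(Γ/Γ_B)` drives a saturating Fermi-type distribution

```
C_i = C_i^B exp(−z_i φ + (v_i/v0) S),         v0 = mean particle volume,
```

with `φ` the reduced electric potential (kBT/e). Concentrations can never
exceed `1/v_i`, even in infinite fields; with all volumes → 0 the
Boltzmann distribution is recovered. Correlations enter through one
length `l_c` in a fourth-order electrostatic operator

```
ε_s (l_c² Δ − 1) Δ φ = ρ_ion ,
```

whose output includes overscreening and a position-dependent effective
permittivity. The package provides:

* the steric core: compositions, void fractions, self-consistent Fermi
  states, the Gibbs free-energy functional (`make_composition`,
  `fermi_state`, `gibbs_free_energy`, …);
* a planar double-layer solver for the decomposed fourth-order system
  with steric/correlation continuation (`solve_equilibrium`), plus
  polarization and effective-permittivity outputs;
* steady-state Nernst–Planck–Bikerman transport with the generalized
  Scharfetter–Gummel exponential-fitting scheme — positivity- and
  current-preserving, Goldman–Hodgkin–Katz as a one-edge special case
  (`solve_pnpb_steady`, `sg_flux`, `bernoulli`);
* the closed-form generalized Debye–Hückel activity model: hydration-shell
  radius from the steric condition, concentration-dependent Born radius,
  two-mode screened reaction potential, `ln γ` in generalized, classical
  and extended modes, and parameter fitting (`gdh`,
  `activity_coefficient`, `fit_activity_parameters`);
* atomic-scale site energetics from point-charge structures (PQR):
  six-probe screened Coulomb potentials with a distance-dependent
  dielectric, site steric terms, and ΔG/ΔΔG selectivity bookkeeping
  (`site_electric_potential`, `site_steric_potential`,
  `free_energy_balance`, `total_potential_state`).

Units: lengths in Å, energies in kBT, potentials in kBT/e, concentrations
internally in Å⁻³ with molar converters; all electrostatic constants enter
through the Bjerrum length.

## Worked example: single-ion activity of Cl⁻ in 0.5 M LiCl

```r
library(pnpbik)

comp <- electrolyte(name = c("Li+", "Cl-"), z = c(1, -1),
                    radius_A = c(0.6, 1.81), conc_M = c(0.5, 0.5))
comp
#> Electrolyte composition (2 ionic species + water, T = 298.15 K)
#>  name  z radius_A   v_A3 conc_M
#>   Li+  1     0.60  0.905    0.5
#>   Cl- -1     1.81 24.838    0.5
#>   H2O  0     1.40 11.494   55.5
#> v0 = 12.4124 A^3, Gamma_B = 0.608085

cl <- hydration_spec("Cl-", z = -1, a_A = 1.81, R0_A = 2.266, O_w = 18,
                     alpha = c(0.052, -0.015, 0))
gdh(cl, comp)
#> Generalized Debye-Hueckel result for Cl-
#>   lB=7.1442  lD=4.3007  lD4=4.3188  lc=0.8001 A
#>   Lambda=1.667e-02  lambda1=0.23578  lambda2=1.22745 1/A  Theta=0.497268
#>   R_Born=2.3323  R_sh=5.1115 A  ln gamma=-0.396154
```

Reading the output: at 0.5 M about 39% of space is void
(`Gamma_B = 0.608`); the hydration shell of Cl⁻ holding 18 waters extends
to `R_sh = 5.11` Å; the steric correction `Lambda` lengthens the Debye
length slightly (4.301 → 4.319 Å); the two screening modes of the
correlated operator have decay lengths 1/λ₁ = 4.24 Å and 1/λ₂ = 0.81 Å;
and the resulting single-ion activity coefficient is
`γ_Cl = exp(−0.396) = 0.673`, the expected sub-unity value for a 0.5 M
1:1 electrolyte.

A command-line wrapper is installed with the package
(`inst/exec/pnpb`): `pnpb activity --salt LiCl --conc 0.5
--alpha 0.052,-0.015,0` prints the same number, and `pnpb edl`,
`pnpb transport`, `pnpb site-energy`, `pnpb fixtures` drive the other
pipelines from YAML scenario configs.

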