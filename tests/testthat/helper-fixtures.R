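## shared fixtures, built in code

salt_11 <- function(conc = 0.1, ...)
  electrolyte(c("Na+", "Cl-"), c(1, -1), c(0.95, 1.81), c(conc, conc), ...)

licl <- function(conc)
  electrolyte(c("Li+", "Cl-"), c(1, -1), c(0.6, 1.81), c(conc, conc))

kcsa_bath <- function()
  electrolyte(c("Na+", "K+", "Cl-"), c(1, 1, -1),
              c(0.95, 1.33, 1.81), c(0.4, 0.4, 0.8))

edl_comp <- function(water_radius_A = 1.4)
  electrolyte(c("C+", "A4-"), c(1, -4), c(4.65, 4.65), c(0.4, 0.1),
              water_radius_A = water_radius_A)

cl_spec <- function(alpha = c(0.052, -0.015, 0))
  hydration_spec("Cl-", -1, 1.81, 2.266, O_w = 18, alpha = alpha)

## compact solver settings for tests
fast_config <- function(...)
  solver_config(steric_steps = 5, corr_steps = 3, ...)
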