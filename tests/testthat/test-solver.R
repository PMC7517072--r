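dirichlet <- function(l, r)
  list(left = list(type = "dirichlet", value = l),
       right = list(type = "dirichlet", value = r))

test_that("central FD Poisson assembly is exact for quadratics", {
  g <- grid1d(2, 21)
  ## -(1 * phi')' = 2 with phi = x(2 - x): exact on quadratics
  sys <- assemble_poisson(g, 1, 2, dirichlet(0, 0))
  expect_equal(poisson_solve(sys), g$x * (2 - g$x), tolerance = 1e-12)
  ## zero source, zero BCs
  sys0 <- assemble_poisson(g, 3, 0, dirichlet(0, 0))
  expect_equal(poisson_solve(sys0), rep(0, 21), tolerance = 1e-14)
  ## all-Neumann has no gauge
  expect_error(assemble_poisson(g, 1, 0, list(
    left = list(type = "neumann", value = 0),
    right = list(type = "neumann", value = 0))), "gauge")
})

test_that("FD solution converges at second order on a smooth problem", {
  errs <- vapply(c(21, 41, 81, 161), function(n) {
    g <- grid1d(1, n)
    exact <- sin(2 * g$x)
    sys <- assemble_poisson(g, 1, 4 * sin(2 * g$x),
                            dirichlet(0, sin(2)))
    max(abs(poisson_solve(sys) - exact))
  }, numeric(1))
  orders <- log2(errs[-4] / errs[-1])
  expect_true(all(orders > 1.9))
})

test_that("interface stencil reduces to the standard scheme when materials match", {
  st <- interface_stencil(5, 5, 0, 0, 0.1)
  expect_equal(st[c("A1", "A2", "B1", "B2")],
               list(A1 = 0, A2 = 1, B1 = 1, B2 = 0))
  expect_identical(st$A0, 0)
  expect_identical(st$B0, 0)
})

test_that("interface scheme reproduces piecewise-linear jump solutions exactly", {
  epsL <- 2; epsR <- 80
  n <- 21; h <- 1 / (n - 1); gam <- 9.5 * h
  g <- grid1d(1, n, interfaces = gam)
  Jphi <- 0.3; Jq <- -0.7
  slope_r <- (2 * epsL + Jq) / epsR
  exact <- function(x) ifelse(x < gam, 2 * x,
                              slope_r * (x - gam) + 2 * gam + Jphi)
  eps <- ifelse(g$x <= gam, epsL, epsR)
  sys <- assemble_poisson(g, eps, 0, dirichlet(exact(0), exact(1)),
                          jumps = list(list(phi = Jphi, flux = Jq)))
  expect_equal(poisson_solve(sys), exact(g$x), tolerance = 1e-13)
})

test_that("two-material convergence order is at least 1.9", {
  epsL <- 2; epsR <- 80
  errs <- vapply(c(41, 81, 161, 321), function(n) {
    h <- 1 / (n - 1); i <- round(n / 2); gam <- (i - 0.5) * h
    g <- grid1d(1, n, interfaces = gam)
    shift <- sin(3 * gam) / 3 * (1 / epsL - 1 / epsR)
    exact <- function(x) ifelse(x < gam, sin(3 * x) / (3 * epsL),
                                sin(3 * x) / (3 * epsR) + shift)
    eps <- ifelse(g$x <= gam, epsL, epsR)
    sys <- assemble_poisson(g, eps, 3 * sin(3 * g$x),
                            dirichlet(exact(0), exact(1)))
    max(abs(poisson_solve(sys) - exact(g$x)))
  }, numeric(1))
  orders <- log2(errs[-4] / errs[-1])
  expect_true(all(orders > 1.9))
})

test_that("uncharged wall yields the trivial bulk state", {
  comp <- salt_11(0.1)
  st <- solve_equilibrium(domain_spec(L = 20, n = 101, sigma = 0),
                          comp, fast_config())
  expect_lt(max(abs(st$phi)), 1e-8)
  expect_equal(st$C, fermi_concentrations(rep(0, 101), 0, comp),
               tolerance = 1e-8)
  expect_lt(max(abs(st$S)), 1e-10)
})

test_that("point-ion limit matches the Gouy-Chapman closed form", {
  pt <- electrolyte(c("Na+", "Cl-"), c(1, -1), c(0, 0), c(0.1, 0.1),
                    water_radius_A = 0)
  st <- solve_equilibrium(domain_spec(L = 60, n = 601, sigma = 0.005),
                          pt, solver_config(steric_steps = 1))
  gc <- gouy_chapman_potential(st$x, 0.005, 0.1)
  expect_lt(max(abs(st$phi - gc)) / max(abs(gc)), 0.005)
})

test_that("screening neutrality holds on a deep domain", {
  ## L ~ 16 Debye lengths so the far-field truncation is below 1e-6
  comp <- electrolyte(c("Na+", "Cl-"), c(1, -1), c(0.95, 1.81),
                      c(0.5, 0.5))
  st <- solve_equilibrium(domain_spec(L = 70, n = 701, sigma = 0.003),
                          comp, fast_config())
  expect_lt(abs(charge_balance(st)) / 0.003, 1e-6)
})

test_that("converged concentrations satisfy the Fermi closure", {
  comp <- edl_comp()
  st <- solve_equilibrium(domain_spec(L = 40, n = 201, sigma = 0.01,
                                      eps_s = 80),
                          comp, fast_config())
  fs <- fermi_state(st$phi, comp)
  expect_lt(max(abs(fs$C - st$C) / pmax(st$C, 1e-300)), 1e-8)
})

test_that("contact concentration saturates below the volume bound up to 10x surface charge", {
  comp <- salt_11(0.1)
  bound <- saturation_bound(comp)
  for (sigma in c(0.02, 0.1, 0.2)) {   # up to 10 e / 50 A^2
    st <- solve_equilibrium(domain_spec(L = 30, n = 151, sigma = sigma),
                            comp, fast_config(max_iter = 5000))
    expect_true(all(st$C[1, ] < bound))
    expect_true(all(st$Gamma > 0))
  }
})

test_that("steric continuation reduces the stage residuals monotonically", {
  comp <- edl_comp()
  st <- solve_equilibrium(domain_spec(L = 40, n = 201, sigma = 0.02,
                                      eps_s = 80, lc = 0),
                          comp, fast_config(),
                          steric_exponent = "uniform")
  ## converged stage-end residuals all below tolerance, no blow-up across
  ## the steric ramp
  expect_true(all(st$stage_err < 1e-6))
})

test_that("polarization field: zero potential, linear-dielectric and cubic oracles", {
  comp <- salt_11(0.1)
  st <- solve_equilibrium(domain_spec(L = 20, n = 101, sigma = 0),
                          comp, fast_config())
  expect_lt(max(abs(polarization_field(st))), 1e-8)

  ## lc = 0 on a solved profile: P = (eps_w - 1) E
  st2 <- solve_equilibrium(domain_spec(L = 30, n = 301, sigma = 0.005),
                           comp, fast_config())
  h <- st2$x[2] - st2$x[1]
  d1 <- c((-3 * st2$phi[1] + 4 * st2$phi[2] - st2$phi[3]) / (2 * h),
          diff(st2$phi, lag = 2) / (2 * h),
          (3 * st2$phi[301] - 4 * st2$phi[300] + st2$phi[299]) / (2 * h))
  expect_equal(polarization_field(st2), -(78.45 - 1) * d1,
               tolerance = 1e-10)

  ## cubic phi with lc > 0: the third derivative is 0.006 exactly in the
  ## interior; the first central derivative of x^3 carries the standard
  ## h^2 f'''/6 correction
  fake <- st2
  fake$phi <- 0.001 * st2$x^3
  fake$domain$lc <- 2
  P <- polarization_field(fake)
  interior <- 4:298
  d1_exact <- 0.003 * st2$x[interior]^2 + 0.001 * h^2
  expect_equal(P[interior], 78.45 * 4 * 0.006 - (78.45 - 1) * d1_exact,
               tolerance = 1e-9)
})

test_that("effective permittivity is eps_w without correlations and in the far field", {
  comp <- salt_11(0.1)
  st <- solve_equilibrium(domain_spec(L = 30, n = 301, sigma = 0.005),
                          comp, fast_config())
  eh <- effective_permittivity(st)   # lc = 0
  expect_true(all(abs(eh[!is.na(eh)] - 78.45) < 1e-9))

  ## with correlations the dielectric response becomes an output: the
  ## profile deviates from eps_w inside the double layer
  edl <- edl_comp()
  stc <- solve_equilibrium(domain_spec(L = 40, n = 201, sigma = 0.005,
                                       eps_s = 80, lc = 3),
                           edl, fast_config(), steric_exponent = "uniform")
  eh2 <- effective_permittivity(stc)
  near <- eh2[stc$x < 10]
  expect_gt(max(abs(near[!is.na(near)] - 80)), 1)
})
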