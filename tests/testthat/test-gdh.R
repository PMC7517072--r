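test_that("screening lengths: classical Debye length and degenerate cases", {
  comp <- licl(0.1)
  sl <- screening_lengths(comp)
  expect_equal(sl$lD, 9.617, tolerance = 1e-3)
  ## equal ionic volumes: Lambda = 0, generalized = classical
  eqv <- electrolyte(c("A+", "B-"), c(1, -1), c(1.5, 1.5), c(0.2, 0.2))
  sl2 <- screening_lengths(eqv)
  expect_identical(sl2$Lambda, 0)
  expect_equal(sl2$lD4, sl2$lD, tolerance = 1e-12)
  ## point particles
  pt <- electrolyte(c("A+", "B-"), c(1, -1), c(0, 0), c(0.2, 0.2),
                    water_radius_A = 0)
  sl3 <- screening_lengths(pt)
  expect_identical(sl3$Lambda, 0)
  expect_equal(sl3$lD4, sl3$lD, tolerance = 1e-12)
})

test_that("spectral roots satisfy the Vieta identities and limits", {
  set.seed(11)
  for (k in 1:50) {
    lD4 <- stats::runif(1, 1, 50)
    lc <- stats::runif(1, 0, lD4 / 2)   # real-root regime
    ro <- spectral_roots(lc, lD4)
    expect_lte(ro$lambda1, ro$lambda2)
    expect_equal(ro$lambda1^2 + ro$lambda2^2, 1 / lc^2, tolerance = 1e-10)
    expect_equal(ro$lambda1^2 * ro$lambda2^2, 1 / (lc^2 * lD4^2),
                 tolerance = 1e-10)
  }
  ro0 <- spectral_roots(0, 4)
  expect_equal(ro0$lambda1, 1 / 4)
  expect_true(is.infinite(ro0$lambda2) && ro0$lc_zero)
  ## coalescing roots at the regime boundary
  roc <- spectral_roots(2, 4)
  expect_equal(roc$lambda1, roc$lambda2)
  expect_equal(roc$lambda1, 1 / (sqrt(2) * 2))
  expect_error(spectral_roots(3, 4), "complex")
})

test_that("Theta: printed form, coalescent continuation and limits", {
  ## printed ratio form agrees with the simplified implementation
  l1 <- 0.21; l2 <- 0.9; R <- 4.2
  printed <- (l1^2 - l2^2) / (l1^2 * (l2 * R + 1) - l2^2 * (l1 * R + 1))
  expect_equal(theta_factor(l1, l2, R), printed, tolerance = 1e-12)
  ## lambda1 -> 0 (infinite dilution): Theta -> 1
  expect_equal(theta_factor(1e-12, 0.5, 4), 1, tolerance = 1e-6)
  ## lc -> 0 limit: (Theta - 1)/R -> -1/(R + lD)
  lD <- 7.3; R <- 3.1
  th <- theta_factor(1 / lD, Inf, R)
  expect_equal((th - 1) / R, -1 / (R + lD), tolerance = 1e-12)
  ## coalescing roots: continuous along lambda2 -> lambda1
  lam <- 0.4
  th_lim <- theta_factor(lam, lam, R)
  th_near <- theta_factor(lam, lam + 1e-9, R)
  expect_equal(th_lim, th_near, tolerance = 1e-7)
})

test_that("hydration-shell radius reproduces the chloride value and responds monotonically", {
  spec <- cl_spec()
  dilute <- licl(1e-12)
  sh <- shell_radius(spec, dilute)
  expect_equal(sh$R_sh, 5.123, tolerance = 0.05 / 5.123)  # within 0.05 A
  ## brute-force residual scan agrees with the root
  vw <- dilute$v[3]; Cw <- dilute$C_bulk[3]
  resid <- function(V) log((V - vw * spec$O_w) / (V * dilute$Gamma_B)) -
    (dilute$v0 / vw) * log(spec$O_w / (V * Cw))
  Vgrid <- seq(vw * spec$O_w * 1.001, 2000, length.out = 40000)
  Vbest <- Vgrid[which.min(abs(resid(Vgrid)))]
  expect_equal(sh$V_sh, Vbest, tolerance = 1e-3)
  ## more voids (lower water content) shift the root; monotone response
  shells <- vapply(c(45, 50, 55.5), function(cw) {
    comp <- electrolyte(c("Li+", "Cl-"), c(1, -1), c(0.6, 1.81),
                        c(1e-12, 1e-12), water_conc_M = cw)
    shell_radius(spec, comp)$R_sh
  }, numeric(1))
  expect_true(all(diff(shells) < 0) || all(diff(shells) > 0))
  ## a bath without finite-size water cannot define a hydration shell
  dry <- electrolyte(c("Li+", "Cl-"), c(1, -1), c(0.6, 1.81),
                     c(1e-12, 1e-12), water_radius_A = 0)
  expect_error(shell_radius(spec, dry), "finite-size water")
  expect_error(shell_radius(hydration_spec("X-", -1, 1.81, 2.266,
                                           O_w = 0), dilute), "O_w > 0")
})

test_that("Born radius scaling matches the fitted-parameter arithmetic", {
  spec <- cl_spec()
  expect_equal(born_radius(spec, 0), spec$R0)
  expect_equal(born_radius(spec, 2.5) / spec$R0, 1.0447, tolerance = 1e-4)
  ## a zero-parameter ion keeps its dilute Born radius at any concentration
  na <- hydration_spec("Na+", 1, 0.95, 1.618, alpha = c(0, 0, 0))
  expect_equal(born_radius(na, 3), na$R0)
  bad <- hydration_spec("X-", -1, 1.81, 2.266, alpha = c(-10, 0, 0))
  expect_error(born_radius(bad, 1), "theta")
})

test_that("reaction potential is continuous across both interfaces", {
  set.seed(21)
  mk <- binary_salt("Li+", "Cl-", z = c(1, -1), radius_A = c(0.6, 1.81))
  for (k in 1:200) {
    conc <- stats::runif(1, 1e-4, 1.5)
    g <- gdh(cl_spec(), mk(conc))
    eps <- 1e-9
    for (R in c(g$R_Born, g$R_sh)) {
      lo <- reaction_potential(R * (1 - eps), g, -1)
      hi <- reaction_potential(R * (1 + eps), g, -1)
      expect_equal(lo, hi, tolerance = 1e-6)
    }
  }
  ## dilute center potential -> z lB / R0
  gd <- gdh(cl_spec(), mk(1e-12))
  expect_equal(reaction_potential(0, gd, -1), -gd$lB / 2.266,
               tolerance = 1e-6)
})

test_that("linearized potential collapses to the screened Coulomb form", {
  ## lc = 0, zero shell: phi = z lB exp(-r/lD)/r
  lD <- 9.62
  g <- list(lambda1 = 1 / lD, lambda2 = Inf, R_sh = 0, R_Born = 0,
            Theta = 1, lB = 7.14)
  r <- seq(0.5, 25, length.out = 40)
  expect_equal(reaction_potential(r, g, 1), 7.14 * exp(-r / lD) / r,
               tolerance = 1e-12)
})

test_that("activity coefficient limits and mode reductions", {
  mk <- binary_salt("Li+", "Cl-", z = c(1, -1), radius_A = c(0.6, 1.81))
  spec <- cl_spec()
  dil <- mk(1e-12)
  for (mode in c("generalized", "classical_DH", "extended_DHB"))
    expect_equal(exp(activity_coefficient(spec, dil, mode)), 1,
                 tolerance = 1e-5)
  ## generalized collapses to classical DH when Born scaling is off and
  ## the correlation/steric machinery is bypassed
  lB <- bjerrum_length(78.45, 298.15)
  comp <- mk(0.25)
  lD <- debye_length(comp)
  Rsh <- shell_radius(spec, comp)$R_sh
  th <- theta_factor(1 / lD, Inf, Rsh)   # lc = 0, Lambda = 0
  ln_gen <- 0.5 * lB * (th - 1) / Rsh    # R_Born = R0 term drops out
  ln_dh <- activity_coefficient(spec, comp, "classical_DH",
                                R_closest = Rsh)
  expect_equal(ln_gen, ln_dh, tolerance = 1e-10)
})

test_that("excess chemical potential equals kBT ln gamma identically", {
  mk <- binary_salt("Li+", "Cl-", z = c(1, -1), radius_A = c(0.6, 1.81))
  for (conc in c(0.01, 0.1, 0.5, 1.2)) {
    comp <- mk(conc)
    expect_equal(excess_chemical_potential(cl_spec(), comp),
                 activity_coefficient(cl_spec(), comp, "generalized"),
                 tolerance = 1e-12)
  }
})

test_that("limiting-law slope matches classical Debye-Hueckel within 1%", {
  ## steric/Born corrections off: equal-volume 1:1 salt, alpha = 0,
  ## shell radius negligible compared to the Debye length
  mk <- binary_salt("A+", "B-", z = c(1, -1), radius_A = c(1.2, 1.2))
  spec <- hydration_spec("B-", -1, 1.2, 2.0, O_w = 18, alpha = c(0, 0, 0))
  lB <- bjerrum_length()
  cc <- c(1e-6, 4e-6)
  lng <- vapply(cc, function(C) {
    comp <- mk(C)
    Rsh <- shell_radius(spec, comp)$R_sh
    th <- theta_factor(1 / debye_length(comp), Inf, Rsh)  # lc, Born off
    0.5 * lB * (th - 1) / Rsh
  }, numeric(1))
  slope <- diff(lng) / diff(sqrt(cc))
  ## classical DH limiting slope: -lB/2 * d(1/lD)/d sqrt(C)
  kappa_per_sqrtC <- sqrt(4 * pi * lB * 2 * molar_to_number(1))
  expect_equal(slope, -0.5 * lB * kappa_per_sqrtC, tolerance = 0.01)
})

test_that("Born-scaling parameters are recovered from synthetic activity data", {
  spec <- cl_spec()
  mk <- binary_salt("Li+", "Cl-", z = c(1, -1), radius_A = c(0.6, 1.81))
  truth <- c(0.05, -0.01, 0)
  tab <- generate_fixture("salt_table", alpha = truth)
  fit <- fit_activity_parameters(tab[, c("conc_M", "gamma")], spec, mk)
  expect_lt(max(abs(fit$alpha - truth)), 1e-6)
  expect_lt(fit$residual_norm, 1e-7)
  ## zero-parameter data returns the zero vector
  tab0 <- generate_fixture("salt_table", alpha = c(0, 0, 0))
  fit0 <- fit_activity_parameters(tab0[, c("conc_M", "gamma")], spec, mk)
  expect_lt(max(abs(fit0$alpha)), 1e-7)
  ## under-determined input errors out
  expect_error(
    fit_activity_parameters(tab[1:2, c("conc_M", "gamma")], spec, mk),
    "under-determined")
})

test_that("noisy synthetic data recovers parameters within 3 standard errors", {
  set.seed(42)
  spec <- cl_spec()
  mk <- binary_salt("Li+", "Cl-", z = c(1, -1), radius_A = c(0.6, 1.81))
  truth <- c(0.05, -0.01, 0)
  tab <- generate_fixture("salt_table", alpha = truth, n = 12)
  reps <- replicate(20, {
    noisy <- tab
    noisy$gamma <- noisy$gamma * exp(stats::rnorm(nrow(tab), 0, 0.01))
    fit_activity_parameters(noisy[, c("conc_M", "gamma")], spec, mk)$alpha
  })
  est <- rowMeans(reps)
  se <- apply(reps, 1, stats::sd) / sqrt(ncol(reps))
  expect_true(all(abs(est - truth) < 3 * pmax(se, 1e-6)))
})
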