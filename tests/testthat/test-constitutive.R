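test_that("deviatoric invariants match hand computations", {
  m <- cbind(c(1, 0, 0), c(0, 1, 0))

  inv <- deviatoric_invariants(deformation_state(diag(3), m))
  expect_equal(inv$i1bar, 3)
  expect_equal(inv$i4bar, c(1, 1))
  expect_equal(inv$jdet, 1)

  # isochoric uniaxial stretch: C = diag(l^2, 1/l, 1/l), J = 1
  l <- 2
  F <- diag(c(l, 1 / sqrt(l), 1 / sqrt(l)))
  inv <- deviatoric_invariants(deformation_state(F, m))
  expect_equal(inv$jdet, 1)
  expect_equal(inv$i4bar[1], 4)
  expect_equal(inv$i1bar, 4 + 1 / 2 + 1 / 2)

  # rotations leave C = I
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  inv <- deviatoric_invariants(deformation_state(R, m))
  expect_equal(inv$i1bar, 3)
  expect_equal(inv$i4bar, c(1, 1), tolerance = 1e-12)

  F_bad <- diag(c(-1, 1, 1))
  expect_error(deformation_state(F_bad, m), "det")
})

test_that("strain energy vanishes at the reference and matches a term-by-term evaluation", {
  pars <- example_materials()$mhgo
  m <- fiber_directions(pars$fiber_angle_deg)
  expect_equal(strain_energy_mhgo(deformation_state(diag(3), m), pars), 0)

  # independent term-by-term arithmetic for incompressible uniaxial stretch
  # with both fiber families along the loading axis
  l <- 1.2
  F <- diag(c(l, 1 / sqrt(l), 1 / sqrt(l)))
  m_ax <- cbind(c(1, 0, 0), c(1, 0, 0))
  i1 <- l^2 + 2 / l
  i4 <- l^2
  e <- pars$kappa * i1 + (1 - 3 * pars$kappa) * i4 - 1
  w_expect <- pars$c10 * (exp(pars$c01 * (i1 - 3)) - 1) +
    pars$k1 / (2 * pars$k2) * 2 * (exp(pars$k2 * e^2) - 1)
  expect_equal(strain_energy_mhgo(deformation_state(F, m_ax), pars),
               w_expect, tolerance = 1e-10)
})

test_that("full fiber dispersion (kappa = 1/3) erases fiber-direction dependence", {
  pars <- mhgo_params(c10 = 0.02, c01 = 5, k1 = 0.12, k2 = 15,
                      kappa = 1 / 3, d_incomp = 5e-4)
  F <- diag(c(1.15, 0.95, 1 / (1.15 * 0.95)))
  m1 <- fiber_directions(0)
  m2 <- fiber_directions(63)
  w1 <- strain_energy_mhgo(deformation_state(F, m1), pars)
  w2 <- strain_energy_mhgo(deformation_state(F, m2), pars)
  expect_equal(w1, w2, tolerance = 1e-12)
  s1 <- stress_mhgo(deformation_state(F, m1), pars)$cauchy
  s2 <- stress_mhgo(deformation_state(F, m2), pars)$cauchy
  expect_equal(s1, s2, tolerance = 1e-10)
})

test_that("stress is zero at the reference and objective under rotations", {
  pars <- example_materials()$mhgo
  m <- fiber_directions(pars$fiber_angle_deg)
  expect_equal(max(abs(stress_mhgo(deformation_state(diag(3), m), pars)$cauchy)), 0)

  th <- 0.4; ph <- 1.1
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1)) %*%
    rbind(c(1, 0, 0), c(0, cos(ph), -sin(ph)), c(0, sin(ph), cos(ph)))
  expect_equal(max(abs(stress_mhgo(deformation_state(R, m), pars)$cauchy)), 0,
               tolerance = 1e-12)

  F <- diag(c(1.1, 1.05, 1 / (1.1 * 1.05))) + 0.02
  w <- strain_energy_mhgo(deformation_state(F, m), pars)
  w_rot <- strain_energy_mhgo(deformation_state(R %*% F, m), pars)
  expect_equal(w, w_rot, tolerance = 1e-10)
  sig <- stress_mhgo(deformation_state(F, m), pars)$cauchy
  sig_rot <- stress_mhgo(deformation_state(R %*% F, m), pars)$cauchy
  expect_equal(sig_rot, R %*% sig %*% t(R), tolerance = 1e-8)
})

test_that("analytic stress matches the finite-difference energy gradient", {
  res <- material_verification(n = 100, seed = 42)
  expect_lt(res$max_rel_error, 1e-5)
  expect_true(res$pass)
})

test_that("chord force follows the tension-only Ogden law", {
  nh <- ogden_params(mu = 1, alpha = 2)   # neo-Hookean limit
  expect_equal(ogden_chord_force(1, nh, 1), 0)
  expect_equal(ogden_chord_force(1.5, nh, 1), 1.5 - 1.5^-2, tolerance = 1e-12)
  expect_equal(ogden_chord_force(0.9, nh, 1), 0)
  expect_error(ogden_chord_force(-0.1, nh, 1), "kinematics")
  expect_error(ogden_params(mu = 1, alpha = -2), "positive")

  # non-decreasing in stretch over the working range
  for (p in list(example_ogden(), ogden_params(c(0.1, 0.05), c(12, 4)))) {
    f <- ogden_chord_force(seq(0.8, 1.6, by = 0.01), p, 0.5)
    expect_true(all(diff(f) >= 0))
  }
})

test_that("maximum principal stress matches an independent eigen oracle", {
  expect_equal(max_principal_stress(diag(c(3, 2, 1))), 3)

  tau <- 0.7   # planar pure shear: eigenvalues +tau, -tau, 0
  S <- matrix(c(0, tau, 0, tau, 0, 0, 0, 0, 0), 3, 3)
  expect_equal(max_principal_stress(S), tau)

  set.seed(7)
  for (k in 1:20) {
    A <- matrix(rnorm(9), 3, 3); S <- (A + t(A)) / 2
    # characteristic polynomial det(S - x I) = -x^3 + c2 x^2 + c1 x + c0
    c2 <- sum(diag(S))
    c1 <- -(S[1, 1] * S[2, 2] - S[1, 2]^2 + S[1, 1] * S[3, 3] - S[1, 3]^2 +
              S[2, 2] * S[3, 3] - S[2, 3]^2)
    c0 <- det(S)
    roots <- Re(polyroot(c(c0, c1, c2, -1)))
    expect_equal(max_principal_stress(S), max(roots), tolerance = 1e-8)
  }

  expect_error(max_principal_stress(matrix(c(0, 1, 0, 0, 0, 0, 0, 0, 0), 3, 3)),
               "symmetric")
})

test_that("region averaging filters labels and excluded zones", {
  expect_equal(region_average(c(1, 2, 3), c("A", "A", "B"), "A"), 1.5)
  expect_error(region_average(c(1, 2), c("coaptation", "annulus"), "coaptation"),
               "no values")

  set.seed(11)
  vals <- rnorm(100)
  labs <- sample(c("AML", "P1", "P2", "P3"), 100, replace = TRUE)
  mask <- runif(100) < 0.2
  for (r in c("AML", "P2")) {
    expect_equal(region_average(vals, labs, r, exclude_mask = mask),
                 mean(vals[labs == r & !mask]))
  }
})
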