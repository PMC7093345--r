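# Kinematics utilities, analytic stress vs finite-difference oracle, and the
# quasi-linear viscoelastic history stress.

test_that("canonical deformations have the expected invariants", {
  expect_equal(make_uniaxial(1)$F, diag(3))
  inv <- isochoric_invariants(make_uniaxial(2)$F)
  expect_equal(inv$J, 1, tolerance = 1e-14)
  expect_equal(inv$I1_bar, 4 + 1, tolerance = 1e-12)  # lam^2 + 2/lam
  expect_equal(isochoric_invariants(make_uniaxial(2, incompressible = FALSE)$F)$J, 2)
  expect_equal(make_simple_shear(0)$F, diag(3))
  invs <- isochoric_invariants(make_simple_shear(0.5)$F)
  expect_identical(invs$J, 1)
  expect_equal(invs$I1_bar, 3.25, tolerance = 1e-14)
  expect_equal(isochoric_invariants(diag(3)), list(I1_bar = 3, I2_bar = 3, J = 1))
  # isochoric invariants are dilation-invariant
  dil <- isochoric_invariants(2 * diag(3))
  expect_equal(dil$I1_bar, 3, tolerance = 1e-14)
  expect_equal(dil$I2_bar, 3, tolerance = 1e-14)
  expect_equal(dil$J, 8, tolerance = 1e-14)
  inv15 <- isochoric_invariants(make_uniaxial(1.5)$F)
  expect_equal(inv15$I1_bar, 1.5^2 + 2 / 1.5, tolerance = 1e-12)
  expect_error(isochoric_invariants(matrix(0, 3, 3)), "positive")
})

test_that("both isochoric invariants are bounded below by 3", {
  set.seed(11)
  for (i in 1:50) {
    inv <- isochoric_invariants(random_F(0.2))
    expect_gte(inv$I1_bar, 3 - 1e-12)
    expect_gte(inv$I2_bar, 3 - 1e-12)
  }
})

test_that("fiber stretch follows |F a0|", {
  expect_equal(fiber_stretch(diag(3), c(0, 1, 0)), 1)
  expect_equal(fiber_stretch(make_uniaxial(1.2)), 1.2, tolerance = 1e-14)
  d <- make_uniaxial(1.2, a0 = c(0, 0, 1))
  expect_equal(fiber_stretch(d), 1.2^(-1 / 2), tolerance = 1e-14)
})

test_that("the numeric stress oracle reproduces the volumetric closed form", {
  K <- 2e6  # kPa
  W_vol <- function(F) 0.5 * K * log(det(F))^2
  # truncation error of the central difference is O(K h^2)
  expect_lt(max(abs(cauchy_stress_numeric(W_vol, diag(3)))), 1e-5)
  s <- cauchy_stress_numeric(W_vol, 1.1 * diag(3))
  J <- 1.1^3
  expect_lt(max(abs(s - K * log(J) / J * diag(3))) / (K * log(J) / J), 1e-8)
  expect_equal(s, t(s), tolerance = 1e-9)
})

test_that("analytic Cauchy stress agrees with the finite-difference oracle", {
  cc <- default_lib()$materials[["corpus callosum"]]
  en <- function(F) strain_energy(cc, deformation_state(F, c(1, 0, 0)))
  set.seed(23)
  for (i in 1:25) {
    F <- random_F()
    sa <- cauchy_stress_elastic(cc, deformation_state(F, c(1, 0, 0)))
    sn <- cauchy_stress_numeric(en, F)
    expect_lt(max(abs(sa - sn)) / max(abs(sa)), 1e-6)
  }
})

test_that("the energy is frame-indifferent and the matrix part isotropic", {
  cc <- default_lib()$materials[["corpus callosum"]]
  set.seed(31)
  for (i in 1:20) {
    F <- random_F()
    Q <- random_rotation()
    a0 <- c(1, 0, 0)
    w1 <- strain_energy(cc, deformation_state(F, a0))
    w2 <- strain_energy(cc, deformation_state(Q %*% F, a0))
    expect_equal(w2, w1, tolerance = 1e-10)
  }
  # with the fiber off, W is invariant under permutations of the stretches
  m <- transverse_iso("iso", C1_kPa = 1.2, C2_kPa = 0.4, K_GPa = 2)
  st <- c(1.2, 0.9, 1.05)
  w_ref <- strain_energy(m, deformation_state(diag(st)))
  for (p in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    expect_equal(strain_energy(m, deformation_state(diag(st[p]))), w_ref,
                 tolerance = 1e-12)
  }
})

test_that("history stress reduces to hyperelasticity without viscosity", {
  m <- transverse_iso("e", C1_kPa = 1, C4 = 50, C3_kPa = 0.05,
                      C5_kPa = 0.05 * 50 * exp(1), K_GPa = 2)
  hist <- list(diag(3), make_uniaxial(1.05)$F)
  s <- cauchy_stress(m, hist, dt_ms = 0.1)
  expect_equal(s, cauchy_stress_elastic(m, make_uniaxial(1.05)), tolerance = 1e-12)
  s0 <- cauchy_stress(m, list(diag(3), diag(3), diag(3)), dt_ms = 0.1)
  expect_equal(s0, matrix(0, 3, 3))
})

test_that("held deformation relaxes to the long-term hyperelastic stress", {
  m <- transverse_iso("v", C1_kPa = 1, K_GPa = 2,
                      prony = data.frame(S = 0.5, T_ms = 10))
  T1 <- 10
  dt <- T1 / 100
  tt <- seq(0, 5 * T1, by = dt)
  Fstep <- make_simple_shear(0.2)$F
  hist <- lapply(tt, function(t) if (t == 0) diag(3) else Fstep)
  s_end <- cauchy_stress(m, hist, dt)[1, 3]
  s_inf <- cauchy_stress_elastic(m, make_simple_shear(0.2))[1, 3]
  expect_lt(abs(s_end - s_inf) / abs(s_inf), exp(-5) * 0.5 * 1.1)
  # just after the step the overstress is (1 + S1) times the elastic stress
  s1 <- cauchy_stress(m, hist[1:2], dt)[1, 3]
  expect_equal(s1 / s_inf, 1.5, tolerance = 0.01)
})

test_that("the recursive Prony update converges to hereditary quadrature", {
  m <- transverse_iso("v", C1_kPa = 1, K_GPa = 2,
                      prony = data.frame(S = c(0.4, 0.2), T_ms = c(10, 1)))
  ramp <- function(t) min(t / 5, 1) * 0.2
  t_end <- 30
  # independent oracle: fine-grid hereditary integral over d(dev sigma)/ds
  tf <- seq(0, t_end, by = 0.002)
  dev13 <- vapply(tf, function(t)
    cauchy_stress_elastic(m, make_simple_shear(ramp(t)))[1, 3], numeric(1))
  dd <- diff(dev13)
  mid <- (tf[-1] + tf[-length(tf)]) / 2
  s_oracle <- dev13[length(tf)] +
    sum(0.4 * exp(-(t_end - mid) / 10) * dd) +
    sum(0.2 * exp(-(t_end - mid) / 1) * dd)
  err_at <- function(dt) {
    tt <- seq(0, t_end, by = dt)
    hist <- lapply(tt, function(t) make_simple_shear(ramp(t))$F)
    abs(cauchy_stress(m, hist, dt)[1, 3] - s_oracle) / abs(s_oracle)
  }
  e1 <- err_at(0.5)
  e2 <- err_at(0.25)
  expect_lt(e1, 0.005)
  expect_lt(e2, e1)
  expect_error(cauchy_stress(m, list(diag(3)), dt_ms = -1), "positive")
})
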