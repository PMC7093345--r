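# Constitutive layer: relaxation, Prony kernel, strain energy, fiber law,
# calibration, foam interpolation, volumetric response.

test_that("relaxation modulus recovers the tabulated moduli and decays monotonically", {
  lib <- default_lib()
  km_names <- c("gray cortex", "hippocampus", "cerebellum", "pia-arachnoid",
                "intervertebral disc")
  for (nm in km_names) {
    m <- lib$materials[[nm]]
    expect_equal(relaxation_modulus(m, 0), m$G0_kPa)
    expect_equal(relaxation_modulus(m, 1e9), m$Ginf_kPa, tolerance = 1e-6)
    g <- relaxation_modulus(m, seq(0, 200, by = 0.5))
    expect_true(all(diff(g) <= 0))
  }
  gc <- lib$materials[["gray cortex"]]
  # half-decay closed form: Ginf + (G0 - Ginf)/2
  expect_equal(relaxation_modulus(gc, log(2) / 0.05), 3.35, tolerance = 1e-9)
  expect_error(relaxation_modulus(gc, -1), "non-negative")
})

test_that("Prony relative modulus is normalized at t = 0 and decays", {
  expect_equal(prony_relative_modulus(data.frame(S = 1, T_ms = 10), 0), 1)
  terms <- data.frame(S = c(0.5, 0.5), T_ms = c(1, 100))
  expect_equal(prony_relative_modulus(terms, 0), 1)
  expect_equal(prony_relative_modulus(terms, 1),
               0.5 * exp(-1) + 0.5 * exp(-0.01), tolerance = 1e-14)
  g <- prony_relative_modulus(terms, seq(0, 50, by = 0.1))
  expect_true(all(diff(g) < 0))
  expect_error(prony_relative_modulus(data.frame(S = numeric(0), T_ms = numeric(0)), 1),
               "at least one")
  expect_error(prony_relative_modulus(data.frame(S = 1, T_ms = -2), 1), "positive")
})

test_that("strain energy vanishes at the identity and matches closed forms", {
  d0 <- deformation_state(diag(3))
  for (m in default_lib()$materials) {
    if (inherits(m, "transverse_iso")) expect_equal(strain_energy(m, d0), 0)
  }
  # matrix-only incompressible uniaxial: W = C1 (lam^2 + 2/lam - 3)
  m <- transverse_iso("mr", C1_kPa = 0.77, K_GPa = 2)
  lam <- 1.1
  expect_equal(strain_energy(m, make_uniaxial(lam)),
               0.77 * (lam^2 + 2 / lam - 3), tolerance = 1e-12)
  # crimped fibers carry no load in compression: no fiber energy at lam < 1
  cc <- default_lib()$materials[["corpus callosum"]]
  mat_only <- transverse_iso("m", C1_kPa = cc$C1_kPa, K_GPa = cc$K_GPa)
  d <- make_uniaxial(0.95)
  expect_equal(strain_energy(cc, d), strain_energy(mat_only, d))
  expect_error(deformation_state(diag(c(-1, 1, 1))), "positive")
})

test_that("fiber stress derivative is piecewise with continuous branches", {
  cc <- default_lib()$materials[["corpus callosum"]]
  expect_identical(fiber_stress_derivative(cc, 1), 0)
  expect_identical(fiber_stress_derivative(cc, 0.9), 0)
  ls <- cc$lambda_star
  toe <- cc$C3_kPa / ls * expm1(cc$C4 * (ls - 1))
  post <- (cc$C5_kPa * ls + cc$C6_kPa) / ls
  expect_equal(toe, post, tolerance = 1e-9)
  expect_equal(fiber_stress_derivative(cc, ls), post, tolerance = 1e-12)
  expect_error(fiber_stress_derivative(cc, -0.1), "positive")
})

test_that("branch continuity holds across random calibrations", {
  set.seed(7)
  for (i in 1:10) {
    m <- calibrate_fiber_params(matrix_G_kPa = runif(1, 0.5, 10),
                                target_ratio = runif(1, 1.2, 4),
                                lam_target = 1.02,
                                lambda_star = runif(1, 1.01, 1.05),
                                C4 = runif(1, 20, 80))
    ls <- m$lambda_star
    h <- 1e-10
    below <- fiber_stress_derivative(m, ls - h)
    above <- fiber_stress_derivative(m, ls + h)
    expect_equal(below, above, tolerance = 1e-6)
    at1 <- fiber_stress_derivative(m, 1 + 1e-12)
    expect_lt(abs(at1), 1e-9 * max(m$C3_kPa, 1))
  }
})

test_that("fiber calibration achieves the along/cross stiffness targets", {
  cc <- calibrate_fiber_params(matrix_G_kPa = 1.54, target_ratio = 2,
                               lam_target = 1.02)
  ratio <- uniaxial_tangent_stiffness(cc, 1.02, along = TRUE) /
    uniaxial_tangent_stiffness(cc, 1.02, along = FALSE)
  expect_equal(ratio, 2, tolerance = 0.05)
  # fiber contribution roughly doubles the matrix tangent along the fiber
  mat_only <- transverse_iso("m", C1_kPa = cc$C1_kPa, K_GPa = cc$K_GPa)
  t_mat <- uniaxial_tangent_stiffness(mat_only, 1.02, along = TRUE)
  t_fib <- uniaxial_tangent_stiffness(cc, 1.02, along = TRUE) - t_mat
  expect_equal(t_fib / t_mat, 1, tolerance = 0.05)
  # degenerate request: ratio 1 means no reinforcement
  iso <- calibrate_fiber_params(matrix_G_kPa = 3, target_ratio = 1)
  expect_equal(iso$C3_kPa, 0)
  expect_equal(iso$C5_kPa, 0)
  # brainstem matrix is exactly twice the cc matrix modulus
  bs <- calibrate_fiber_params(matrix_G_kPa = 3.08, target_ratio = 2,
                               lam_target = 1.02)
  expect_equal(small_strain_shear_modulus(bs) / small_strain_shear_modulus(cc),
               2, tolerance = 1e-10)
})

test_that("small-strain shear modulus probe matches 2(C1+C2) and G0", {
  m <- transverse_iso("mr", C1_kPa = 0.5, C2_kPa = 0.5, K_GPa = 2)
  expect_equal(small_strain_shear_modulus(m), 2, tolerance = 1e-3)
  expect_equal(small_strain_shear_modulus(m, "along"),
               small_strain_shear_modulus(m, "across"), tolerance = 1e-9)
  gc <- default_lib()$materials[["gray cortex"]]
  expect_identical(small_strain_shear_modulus(gc), 5.16)
})

test_that("volumetric pressure follows K ln(J)/J and recovers K in the slope", {
  expect_identical(volumetric_pressure(2, 1), 0)
  expect_equal(volumetric_pressure(3.7, exp(1)), 3.7 / exp(1), tolerance = 1e-15)
  # slope w.r.t. volumetric strain recovers K over many magnitudes
  for (K in 10^seq(-3, 4)) {
    slope <- volumetric_pressure(K, 1.001) / log(1.001)
    expect_equal(slope, K, tolerance = 1e-3)
  }
  expect_error(volumetric_pressure(2, 0), "positive")
})

test_that("foam stress interpolates tabulated curves and stays monotone", {
  f <- make_foam_curves()
  expect_identical(as.numeric(foam_stress(f, 0, 50)), 0)
  # identity interpolation at a stored rate and breakpoint
  cv <- f$curves[[2]]
  s <- foam_stress(f, cv$strain[10], f$rates[2])
  expect_equal(as.numeric(s), cv$stress_MPa[10])
  expect_false(attr(s, "extrapolated"))
  # betweenness at an intermediate rate
  two <- foam_curves(c(1, 100),
                     list(data.frame(strain = c(0, 0.2, 0.5), stress_MPa = c(0, 0.05, 0.2)),
                          data.frame(strain = c(0, 0.2, 0.5), stress_MPa = c(0, 0.08, 0.3))))
  lo <- as.numeric(foam_stress(two, 0.3, 1))
  hi <- as.numeric(foam_stress(two, 0.3, 100))
  mid <- as.numeric(foam_stress(two, 0.3, 10))
  expect_true(mid >= lo && mid <= hi)
  # clamped outside the stored rate range
  expect_equal(as.numeric(foam_stress(two, 0.3, 1e6)), hi)
  expect_equal(as.numeric(foam_stress(two, 0.3, 0)), lo)
  # linear continuation beyond the last point, flagged
  ex <- foam_stress(two, 0.7, 1)
  expect_true(attr(ex, "extrapolated"))
  slope <- (0.2 - 0.05) / 0.3
  expect_equal(as.numeric(ex), 0.2 + slope * 0.2, tolerance = 1e-12)
  # monotonicity in rate and strain (property over the generated family)
  strains <- seq(0, 0.8, by = 0.05)
  vals <- sapply(c(0.01, 0.3, 5, 60, 400, 1000), function(r)
    as.numeric(foam_stress(f, strains, r)))
  expect_true(all(apply(vals, 1, function(v) all(diff(v) >= -1e-12))))
  expect_true(all(apply(vals, 2, function(v) all(diff(v) >= 0))))
  # invalid family rejected
  expect_error(foam_curves(c(1, 100),
    list(data.frame(strain = c(0, 0.2), stress_MPa = c(0, 0.3)),
         data.frame(strain = c(0, 0.2), stress_MPa = c(0, 0.1)))),
    "non-decreasing in rate")
})

test_that("parameter constructors enforce their invariants", {
  expect_error(kelvin_maxwell("x", 1, 2, 0.05), "exceed")
  expect_error(kelvin_maxwell("x", 2, -1, 0.05), "positive")
  expect_error(kelvin_maxwell("x", 2, 1, -0.05), "positive")
  expect_error(transverse_iso("x", C1_kPa = -1), "positive")
  expect_error(transverse_iso("x", C1_kPa = 1, lambda_star = 0.99), "exceed")
  expect_error(linear_elastic("x", 100, 0.5), "nu")
  expect_error(linear_elastic("x", -5, 0.3), "positive")
})
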