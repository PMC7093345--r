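# Fixture generators and the shipped material library.

test_that("the default library replicates the tabulated parameter rows", {
  lib <- default_lib()
  expect_identical(lib$materials[["gray cortex"]]$G0_kPa, 5.16)
  expect_identical(lib$materials[["gray cortex"]]$Ginf_kPa, 1.54)
  expect_identical(lib$materials[["gray cortex"]]$beta_per_ms, 0.05)
  expect_identical(lib$materials[["hippocampus"]]$G0_kPa, 10.32)
  expect_identical(lib$materials[["hippocampus"]]$Ginf_kPa, 3.08)
  expect_identical(lib$materials[["cerebellum"]]$G0_kPa, 4.64)
  expect_identical(lib$materials[["cerebellum"]]$Ginf_kPa, 1.38)
  expect_identical(lib$materials[["pia-arachnoid"]]$G0_kPa, 1379)
  expect_identical(lib$materials[["pia-arachnoid"]]$Ginf_kPa, 153)
  expect_identical(lib$materials[["pia-arachnoid"]]$beta_per_ms, 0.04)
  expect_identical(lib$materials[["intervertebral disc"]]$G0_kPa, 1000)
  expect_identical(lib$materials[["dura mater"]]$E_MPa, 31.5)
  expect_identical(lib$materials[["dura mater"]]$nu, 0.45)
  expect_identical(lib$materials[["skull, diploe layer"]]$E_MPa, 600)
  expect_identical(lib$materials[["skull, cortical layer"]]$E_MPa, 15000)
  expect_identical(lib$materials[["vertebral body"]]$E_MPa, 7000)
  # brain materials share the 2 GPa bulk modulus
  for (nm in c("gray cortex", "hippocampus", "cerebellum", "corpus callosum",
               "brainstem tracts")) {
    expect_identical(lib$materials[[nm]]$K_GPa, 2)
  }
  # brainstem matrix is twice as stiff as the cc matrix
  expect_equal(small_strain_shear_modulus(lib$materials[["brainstem tracts"]]) /
                 small_strain_shear_modulus(lib$materials[["corpus callosum"]]),
               2, tolerance = 1e-9)
  expect_identical(lib$materials[["supporting foam"]]$density_kg_mm3, 1.362e-8)
  # name-based extraction through the library [[ method
  expect_identical(lib[["vertebral body"]]$E_MPa, 7000)
})

test_that("library serialization round-trips exactly", {
  lib <- default_lib()
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  write_material_library(lib, path)
  back <- read_material_library(path)
  expect_identical(names(back$materials), names(lib$materials))
  for (nm in names(lib$materials)) {
    a <- lib$materials[[nm]]
    b <- back$materials[[nm]]
    expect_identical(class(a), class(b))
    for (f in names(a)) {
      if (is.numeric(a[[f]])) expect_identical(a[[f]], b[[f]], label = paste(nm, f))
    }
    if (inherits(a, "transverse_iso")) {
      expect_identical(a$prony$S, b$prony$S)
      expect_identical(a$prony$T_ms, b$prony$T_ms)
    }
  }
})

test_that("suction pulse set covers the nine peak/duration combinations", {
  pulses <- make_suction_pulses()
  expect_length(pulses, 9L)
  expect_equal(max(pulses[["4psi_25ms"]]$p_kPa), 4 * 6.894757, tolerance = 1e-9)
  expect_equal(max(pulses[["2psi_100ms"]]$p_kPa), 2 * 6.894757, tolerance = 1e-9)
  for (p in pulses) {
    expect_identical(p$p_kPa[1], 0)
    expect_true(all(p$p_kPa >= 0))
    # support confined to the nominal duration
    expect_true(all(p$p_kPa[p$t_ms > p$duration_ms + 1e-9] == 0))
  }
})

test_that("generated foam families satisfy the type invariants", {
  f <- make_foam_curves()
  expect_length(f$curves, 4L)
  expect_identical(f$density_kg_mm3, 1.362e-8)
  expect_true(all(diff(f$rates) > 0))
  for (cv in f$curves) {
    expect_identical(cv$strain[1], 0)
    expect_identical(cv$stress_MPa[1], 0)
    expect_true(all(diff(cv$stress_MPa) >= 0))
    # truncated before the densification asymptote
    expect_lte(max(cv$strain), 0.95 * 0.9 + 1e-12)
  }
  stiff <- make_foam_curves(stiffness_scale = 2)
  expect_equal(stiff$curves[[1]]$stress_MPa, 2 * f$curves[[1]]$stress_MPa)
})

test_that("default impact configs differ only in the impact speed", {
  cfgs <- default_impact_configs()
  expect_identical(cfgs[["h2.25m"]]$impactor_v0_ms, 6.15)
  expect_identical(cfgs[["h1.25m"]]$impactor_v0_ms, 4.54)
  expect_identical(cfgs[["h2.25m"]]$impactor_mass_kg, 0.45)
  expect_identical(cfgs[["h2.25m"]]$helmet_mass_kg, 0.0028)
  a <- cfgs[["h2.25m"]]; b <- cfgs[["h1.25m"]]
  a$impactor_v0_ms <- b$impactor_v0_ms
  expect_identical(unclass(a), unclass(b))
})

test_that("reference corridors are reproducible and converge to the base", {
  base <- pulse_curve()
  clean <- make_reference_corridor(base, n = 4, noise_sd = 0, seed = 3)
  expect_true(all(clean$corridor$sd == 0))
  expect_equal(clean$corridor$mean, base$v)
  r1 <- make_reference_corridor(base, n = 16, noise_sd = 0.2, time_jitter_ms = 0.5,
                                seed = 11)
  r2 <- make_reference_corridor(base, n = 16, noise_sd = 0.2, time_jitter_ms = 0.5,
                                seed = 11)
  expect_identical(r1$corridor$mean, r2$corridor$mean)
  expect_identical(r1$corridor$sd, r2$corridor$sd)
  # law-of-large-numbers bound on the corridor mean
  noise_sd <- 0.25
  big <- make_reference_corridor(base, n = 200, noise_sd = noise_sd, seed = 4)
  expect_lt(max(abs(big$corridor$mean - base$v)), 3 * noise_sd / sqrt(200))
  # the generator leaves the caller's RNG state untouched
  set.seed(99); before <- .Random.seed
  invisible(make_reference_corridor(base, n = 5, noise_sd = 0.1, seed = 1))
  expect_identical(.Random.seed, before)
})
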