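# Constitutive laws: Kelvin-Maxwell shear relaxation, transversely isotropic
# fiber-reinforced hyperelasticity (Weiss-type uncrimping fiber), linear
# elasticity, and tabulated rate-dependent foam.
#
# Unit conventions in this layer follow the tissue tables: shear moduli and the
# Mooney-Rivlin constants in kPa, decay constants in 1/ms, times in ms, bulk
# moduli in GPa, foam stresses in MPa. The pairing (kPa, ms, 1/ms) is
# self-consistent; the impact simulator converts to SI internally.

#' Kelvin-Maxwell viscoelastic material
#'
#' Shear relaxation of the form `G(t) = Ginf + (G0 - Ginf) exp(-beta t)`,
#' the model used for isotropic brain tissue, meninges and intervertebral
#' disc in rodent head models.
#'
#' @param name tissue name.
#' @param G0_kPa short-term shear modulus, kPa.
#' @param Ginf_kPa long-term shear modulus, kPa; must be below `G0_kPa`.
#' @param beta_per_ms decay constant, 1/ms.
#' @param K_GPa bulk modulus, GPa (brain tissues default to 2 GPa).
#' @param density_kg_m3 mass density, kg/m^3. Not tabulated in the source
#'   data; the default is a conventional soft-tissue value.
#' @param brain logical; whether this entry counts as brain tissue (shares
#'   the declared bulk-modulus default).
#' @return an object of class `kelvin_maxwell`.
#' @export
kelvin_maxwell <- function(name, G0_kPa, Ginf_kPa, beta_per_ms,
                           K_GPa = if (brain) 2 else NULL,
                           density_kg_m3 = 1040, brain = FALSE) {
  stop_if(!is_scalar_num(G0_kPa) || !is_scalar_num(Ginf_kPa) ||
            !is_scalar_num(beta_per_ms), "moduli and beta must be finite scalars")
  stop_if(!(G0_kPa > Ginf_kPa), "G0 must exceed Ginf")
  stop_if(!(Ginf_kPa > 0), "Ginf must be positive")
  stop_if(!(beta_per_ms > 0), "beta must be positive")
  if (!is.null(K_GPa)) stop_if(!(K_GPa > 0), "K must be positive")
  structure(list(name = name, G0_kPa = as.numeric(G0_kPa),
                 Ginf_kPa = as.numeric(Ginf_kPa),
                 beta_per_ms = as.numeric(beta_per_ms),
                 K_GPa = if (is.null(K_GPa)) NULL else as.numeric(K_GPa),
                 density_kg_m3 = as.numeric(density_kg_m3),
                 brain = isTRUE(brain)),
            class = "kelvin_maxwell")
}

#' @export
print.kelvin_maxwell <- function(x, ...) {
  cat(sprintf("Kelvin-Maxwell material '%s': G0 = %g kPa, Ginf = %g kPa, beta = %g /ms\n",
              x$name, x$G0_kPa, x$Ginf_kPa, x$beta_per_ms))
  invisible(x)
}

#' Shear relaxation modulus
#'
#' Evaluates `G(t) = Ginf + (G0 - Ginf) exp(-beta t)` for a
#' [kelvin_maxwell()] material.
#'
#' @param p a `kelvin_maxwell` material.
#' @param t_ms time(s) since load application, ms; must be non-negative.
#' @return shear modulus in kPa, same length as `t_ms`.
#' @export
relaxation_modulus <- function(p, t_ms) {
  stopifnot(inherits(p, "kelvin_maxwell"))
  stop_if(any(!is.finite(t_ms)) || any(t_ms < 0), "t_ms must be non-negative")
  p$Ginf_kPa + (p$G0_kPa - p$Ginf_kPa) * exp(-p$beta_per_ms * t_ms)
}

#' Prony-series relative relaxation modulus
#'
#' `g(t) = sum_i S_i exp(-t / T_i)`, the dimensionless relaxation kernel of
#' quasi-linear viscoelasticity. `S_i` are modulus fractions, `T_i`
#' characteristic times in ms.
#'
#' @param terms a data frame or matrix with columns `S` and `T_ms` (or a list
#'   of `(S, T)` pairs); at most six terms are meaningful in the target
#'   material card but any positive number is accepted.
#' @param t_ms time(s), ms, non-negative.
#' @return relative modulus, same length as `t_ms`; equals `sum(S)` at `t = 0`.
#' @export
prony_relative_modulus <- function(terms, t_ms) {
  terms <- as_prony(terms)
  stop_if(nrow(terms) == 0L, "at least one Prony term is required")
  stop_if(any(t_ms < 0) || any(!is.finite(t_ms)), "t_ms must be non-negative")
  vapply(t_ms, function(t) sum(terms$S * exp(-t / terms$T_ms)), numeric(1))
}

# normalize Prony term input to a data.frame with columns S, T_ms
as_prony <- function(terms) {
  if (is.null(terms)) return(data.frame(S = numeric(0), T_ms = numeric(0)))
  if (is.matrix(terms)) terms <- as.data.frame(terms)
  if (is.list(terms) && !is.data.frame(terms)) {
    terms <- do.call(rbind, lapply(terms, function(p) data.frame(S = p[[1]], T_ms = p[[2]])))
  }
  if (is.data.frame(terms)) {
    nm <- names(terms)
    if (!all(c("S", "T_ms") %in% nm)) {
      stopifnot(ncol(terms) >= 2L)
      names(terms)[1:2] <- c("S", "T_ms")
    }
  }
  stop_if(any(terms$S < 0), "Prony fractions S must be non-negative")
  stop_if(any(terms$T_ms <= 0), "Prony times T must be positive")
  data.frame(S = as.numeric(terms$S), T_ms = as.numeric(terms$T_ms))
}

#' Transversely isotropic fiber-reinforced hyperelastic material
#'
#' Mooney-Rivlin matrix plus a single-family crimped-fiber reinforcement
#' (Weiss-type uncrimping law) and a volumetric penalty
#' `U(J) = K/2 [ln J]^2`. Shear viscosity enters through a Prony series
#' applied to the deviatoric stress (see [cauchy_stress()]).
#'
#' The continuity constant `C6` is derived from stress continuity at the
#' uncrimping stretch: `C6 = C3 (exp(C4 (l* - 1)) - 1) - C5 l*`.
#'
#' @param name tissue name.
#' @param C1_kPa,C2_kPa Mooney-Rivlin matrix constants, kPa
#'   (small-strain matrix shear modulus is `2 (C1 + C2)`).
#' @param C3_kPa fiber exponential stress scale, kPa.
#' @param C4 fiber uncrimping rate, dimensionless.
#' @param C5_kPa post-crimp fiber stiffness, kPa.
#' @param lambda_star uncrimping stretch (> 1) at which fibers are straight.
#' @param K_GPa bulk modulus, GPa.
#' @param prony Prony terms (`S`, `T_ms`), at most two active pairs in the
#'   source material card; may be `NULL` for a purely elastic response.
#' @param density_kg_m3 mass density, kg/m^3.
#' @return an object of class `transverse_iso`.
#' @export
transverse_iso <- function(name, C1_kPa, C2_kPa = 0, C3_kPa = 0, C4 = 0,
                           C5_kPa = 0, lambda_star = 1.02, K_GPa = 2,
                           prony = NULL, density_kg_m3 = 1040) {
  stop_if(!(C1_kPa + C2_kPa > 0), "C1 + C2 must be positive")
  stop_if(C3_kPa < 0 || C4 < 0 || C5_kPa < 0, "C3, C4, C5 must be non-negative")
  stop_if(!(lambda_star > 1), "lambda_star must exceed 1")
  stop_if(!(K_GPa > 0), "K must be positive")
  prony <- as_prony(prony)
  C6_kPa <- C3_kPa * (expm1(C4 * (lambda_star - 1))) - C5_kPa * lambda_star
  structure(list(name = name, C1_kPa = as.numeric(C1_kPa),
                 C2_kPa = as.numeric(C2_kPa), C3_kPa = as.numeric(C3_kPa),
                 C4 = as.numeric(C4), C5_kPa = as.numeric(C5_kPa),
                 C6_kPa = as.numeric(C6_kPa),
                 lambda_star = as.numeric(lambda_star),
                 K_GPa = as.numeric(K_GPa), prony = prony,
                 density_kg_m3 = as.numeric(density_kg_m3), brain = TRUE),
            class = "transverse_iso")
}

#' @export
print.transverse_iso <- function(x, ...) {
  cat(sprintf(
    "Transversely isotropic material '%s': C1 = %.4g, C2 = %.4g, C3 = %.4g, C5 = %.4g kPa; C4 = %.4g; lambda* = %g\n",
    x$name, x$C1_kPa, x$C2_kPa, x$C3_kPa, x$C5_kPa, x$C4, x$lambda_star))
  if (nrow(x$prony)) {
    cat("  Prony terms (S, T ms):",
        paste(sprintf("(%.3g, %.3g)", x$prony$S, x$prony$T_ms), collapse = " "), "\n")
  }
  invisible(x)
}

#' Linear elastic material
#'
#' @param name structure name.
#' @param E_MPa elastic modulus, MPa.
#' @param nu Poisson ratio in `[0, 0.5)`.
#' @param density_kg_m3 mass density, kg/m^3.
#' @export
linear_elastic <- function(name, E_MPa, nu, density_kg_m3 = 1800) {
  stop_if(!(E_MPa > 0), "E must be positive")
  stop_if(!(nu >= 0 && nu < 0.5), "nu must be in [0, 0.5)")
  structure(list(name = name, E_MPa = as.numeric(E_MPa), nu = as.numeric(nu),
                 density_kg_m3 = as.numeric(density_kg_m3), brain = FALSE),
            class = "linear_elastic")
}

#' @export
print.linear_elastic <- function(x, ...) {
  cat(sprintf("Linear elastic material '%s': E = %g MPa, nu = %g\n",
              x$name, x$E_MPa, x$nu))
  invisible(x)
}

#' Derivative of the fiber reinforcement energy
#'
#' Piecewise fiber stress term `dF/dl` of the uncrimping law: zero for
#' `l <= 1` (crimped fibers carry no compressive load), exponential toe region
#' `(C3/l)(exp(C4 (l-1)) - 1)` for `1 < l < l*`, and linear post-crimp response
#' `(C5 l + C6)/l` for `l >= l*`. Continuous at both breakpoints by
#' construction of `C6`.
#'
#' @param p a `transverse_iso` material.
#' @param lam fiber stretch(es), positive.
#' @return fiber stress derivative, kPa.
#' @export
fiber_stress_derivative <- function(p, lam) {
  stopifnot(inherits(p, "transverse_iso"))
  stop_if(any(lam <= 0), "fiber stretch must be positive")
  out <- numeric(length(lam))
  toe <- lam > 1 & lam < p$lambda_star
  post <- lam >= p$lambda_star
  out[toe] <- p$C3_kPa / lam[toe] * expm1(p$C4 * (lam[toe] - 1))
  out[post] <- (p$C5_kPa * lam[post] + p$C6_kPa) / lam[post]
  out
}

# Fiber reinforcement energy F(lambda) (kPa). Toe region integrated
# numerically (smooth integrand); linear branch in closed form.
fiber_energy <- function(p, lam) {
  stopifnot(inherits(p, "transverse_iso"))
  stop_if(any(lam <= 0), "fiber stretch must be positive")
  one <- function(l) {
    if (l <= 1 || (p$C3_kPa == 0 && p$C5_kPa == 0)) return(0)
    toe_int <- function(up) {
      stats::integrate(function(s) p$C3_kPa / s * expm1(p$C4 * (s - 1)),
                       lower = 1, upper = up, rel.tol = 1e-12,
                       abs.tol = 1e-14)$value
    }
    if (l < p$lambda_star) return(toe_int(l))
    toe_int(p$lambda_star) + p$C5_kPa * (l - p$lambda_star) +
      p$C6_kPa * log(l / p$lambda_star)
  }
  vapply(lam, one, numeric(1))
}

#' Strain energy density
#'
#' `W = C1 (I1b - 3) + C2 (I2b - 3) + F(lambda) + K/2 [ln J]^2` with isochoric
#' invariants `I1b`, `I2b`, volume ratio `J` and fiber stretch `lambda`
#' computed from the deformation state.
#'
#' @param p a `transverse_iso` material.
#' @param d a [deformation_state()].
#' @return energy density in kPa.
#' @export
strain_energy <- function(p, d) {
  stopifnot(inherits(p, "transverse_iso"), inherits(d, "deformation_state"))
  inv <- isochoric_invariants(d$F)
  lam <- fiber_stretch(d$F, d$a0)
  K_kPa <- p$K_GPa * 1e6
  p$C1_kPa * (inv$I1_bar - 3) + p$C2_kPa * (inv$I2_bar - 3) +
    fiber_energy(p, lam) + 0.5 * K_kPa * log(inv$J)^2
}

#' Volumetric pressure from the logarithmic penalty
#'
#' Pressure conjugate to the volume ratio for `U(J) = K/2 [ln J]^2`:
#' `p(J) = dU/dJ = K ln(J) / J`. Zero at `J = 1`; its slope with respect to
#' the volumetric strain `ln J` recovers `K` as `J -> 1`.
#'
#' @param K bulk modulus (any unit; the result carries the same unit).
#' @param J volume ratio, positive.
#' @export
volumetric_pressure <- function(K, J) {
  stop_if(any(J <= 0), "J must be positive")
  K * log(J) / J
}

#' Small-strain shear modulus probe
#'
#' Numeric probe used by the calibration and stiffness-ratio checks: for a
#' hyperelastic material the Cauchy shear stress of a simple-shear state at
#' `gamma = 1e-4` divided by `gamma`; for a Kelvin-Maxwell material the
#' instantaneous modulus `G0`.
#'
#' @param material a `transverse_iso` or `kelvin_maxwell` material.
#' @param direction `"along"` shears in a plane containing the fiber,
#'   `"across"` orthogonal to it; identical for isotropic response.
#' @param gamma probe shear strain.
#' @return shear modulus, kPa.
#' @export
small_strain_shear_modulus <- function(material, direction = c("along", "across"),
                                       gamma = 1e-4) {
  direction <- match.arg(direction)
  if (inherits(material, "kelvin_maxwell")) return(material$G0_kPa)
  stopifnot(inherits(material, "transverse_iso"))
  plane <- if (direction == "along") c(1L, 3L) else c(2L, 3L)
  s_p <- cauchy_stress_elastic(material, make_simple_shear(gamma, plane = plane))
  s_m <- cauchy_stress_elastic(material, make_simple_shear(-gamma, plane = plane))
  (s_p[plane[1], plane[2]] - s_m[plane[1], plane[2]]) / (2 * gamma)
}

# Tangent d(sigma_axial)/d(lambda) of an incompressible uniaxial stretch, by
# central difference of the analytic Cauchy stress. `along` selects whether
# the fiber lies on the loading axis or transverse to it.
uniaxial_tangent_stiffness <- function(p, lam, along = TRUE, h = 1e-5) {
  axis_dir <- if (along) c(1, 0, 0) else c(0, 0, 1)
  s11 <- function(l) {
    d <- make_uniaxial(l, incompressible = TRUE)
    d$a0 <- axis_dir / sqrt(sum(axis_dir^2))
    # deviatoric response only: subtract lateral stress as in a uniaxial test
    s <- cauchy_stress_elastic(p, d)
    s[1, 1] - s[2, 2]
  }
  (s11(lam + h) - s11(lam - h)) / (2 * h)
}

#' Calibrate fiber-reinforcement constants
#'
#' Builds a [transverse_iso()] material whose small-strain matrix shear
#' modulus equals `matrix_G_kPa` (neo-Hookean split, `C2 = 0`,
#' `2 C1 = matrix_G`) and whose along-fiber : cross-fiber uniaxial
#' tangent-stiffness ratio at `lam_target` equals `target_ratio`. `C3` is
#' solved numerically; `C5` is set so the fiber stress is C1-continuous at
#' `lambda_star`, which fixes `C6` through stress continuity.
#'
#' @param matrix_G_kPa small-strain matrix shear modulus, kPa.
#' @param target_ratio desired along/cross tangent-stiffness ratio (> 0);
#'   a ratio of 1 returns a degenerate isotropic material (no fibers).
#' @param lam_target fiber stretch at which the ratio is enforced.
#' @param lambda_star uncrimping stretch.
#' @param C4 uncrimping rate (held fixed during calibration).
#' @param K_GPa bulk modulus, GPa.
#' @param prony Prony terms carried into the returned material.
#' @param name name of the returned material.
#' @param tol relative tolerance on the achieved ratio.
#' @return a calibrated `transverse_iso` material.
#' @export
calibrate_fiber_params <- function(matrix_G_kPa, target_ratio = 2,
                                   lam_target = 1.02, lambda_star = 1.02,
                                   C4 = 50, K_GPa = 2, prony = NULL,
                                   name = "calibrated", tol = 1e-6) {
  stop_if(!(matrix_G_kPa > 0), "matrix_G must be positive")
  stop_if(!(target_ratio >= 1), "target_ratio must be >= 1")
  stop_if(!(lam_target > 1), "lam_target must exceed 1")
  C1 <- matrix_G_kPa / 2
  build <- function(C3) {
    C5 <- C3 * C4 * exp(C4 * (lambda_star - 1))  # C1-continuity at lambda*
    transverse_iso(name, C1_kPa = C1, C2_kPa = 0, C3_kPa = C3, C4 = C4,
                   C5_kPa = C5, lambda_star = lambda_star, K_GPa = K_GPa,
                   prony = prony)
  }
  if (abs(target_ratio - 1) < 1e-12) return(build(0))
  ratio_of <- function(C3) {
    m <- build(C3)
    uniaxial_tangent_stiffness(m, lam_target, along = TRUE) /
      uniaxial_tangent_stiffness(m, lam_target, along = FALSE)
  }
  f <- function(C3) ratio_of(C3) - target_ratio
  lo <- 0
  hi <- matrix_G_kPa
  it <- 0
  while (f(hi) < 0) {
    hi <- hi * 4
    it <- it + 1
    stop_if(it > 60, "fiber calibration failed to bracket the target ratio ",
            "(matrix_G = ", matrix_G_kPa, ", ratio = ", target_ratio, ")")
  }
  C3 <- stats::uniroot(f, c(lo, hi), tol = tol * max(hi, 1))$root
  m <- build(C3)
  achieved <- ratio_of(C3)
  stop_if(abs(achieved / target_ratio - 1) > 0.05,
          "fiber calibration did not converge: achieved ratio ", achieved)
  m
}

#' Rate-dependent foam curve family
#'
#' Family of compressive engineering stress-strain curves indexed by strain
#' rate, the input format of tabulated low-density-foam material cards.
#'
#' @param rates strictly increasing engineering strain rates, 1/s.
#' @param curves list (one per rate) of data frames with columns `strain`
#'   (dimensionless, strictly increasing from 0) and `stress_MPa`
#'   (non-decreasing from 0).
#' @param density_kg_mm3 foam density, kg/mm^3.
#' @return an object of class `foam_curves`.
#' @export
foam_curves <- function(rates, curves, density_kg_mm3 = 1.362e-8) {
  stop_if(length(rates) != length(curves), "one curve per rate is required")
  stop_if(any(diff(rates) <= 0), "rates must be strictly increasing")
  for (cv in curves) {
    stop_if(!all(c("strain", "stress_MPa") %in% names(cv)),
            "curves need columns strain, stress_MPa")
    stop_if(cv$strain[1] != 0 || cv$stress_MPa[1] != 0,
            "each curve must start at (0, 0)")
    stop_if(any(diff(cv$strain) <= 0), "strains must be strictly increasing")
    stop_if(any(diff(cv$stress_MPa) < 0), "stresses must be non-decreasing")
  }
  curves <- lapply(curves, function(cv)
    data.frame(strain = as.numeric(cv$strain),
               stress_MPa = as.numeric(cv$stress_MPa)))
  f <- structure(list(rates = as.numeric(rates), curves = curves,
                      density_kg_mm3 = as.numeric(density_kg_mm3)),
                 class = "foam_curves")
  # cross-rate monotonicity at common strains
  if (length(rates) > 1L) {
    grid <- seq(0, min(vapply(curves, function(cv) max(cv$strain), numeric(1))),
                length.out = 25L)
    vals <- vapply(seq_along(rates),
                   function(i) curve_stress(curves[[i]], grid)$stress,
                   numeric(length(grid)))
    stop_if(any(apply(vals, 1, function(v) any(diff(v) < -1e-12))),
            "stress must be non-decreasing in rate at any common strain")
  }
  f
}

#' @export
print.foam_curves <- function(x, ...) {
  cat(sprintf("Rate-dependent foam: %d curves at rates [%s] /s, density %.4g kg/mm^3\n",
              length(x$rates), paste(signif(x$rates, 3), collapse = ", "),
              x$density_kg_mm3))
  invisible(x)
}

# Linear interpolation on a single curve; linear continuation of the last
# segment beyond the tabulated range, flagged.
curve_stress <- function(cv, strain) {
  n <- nrow(cv)
  extrap <- strain > cv$strain[n]
  s <- stats::approx(cv$strain, cv$stress_MPa, xout = pmin(strain, cv$strain[n]),
                     method = "linear", rule = 2)$y
  if (any(extrap)) {
    slope <- (cv$stress_MPa[n] - cv$stress_MPa[n - 1]) /
      (cv$strain[n] - cv$strain[n - 1])
    s[extrap] <- cv$stress_MPa[n] + slope * (strain[extrap] - cv$strain[n])
  }
  list(stress = s, extrapolated = extrap)
}

#' Foam stress lookup
#'
#' Engineering stress at a compressive strain and strain rate. Interpolation
#' is linear in strain on each tabulated curve and piecewise-linear in
#' `log10(rate)` between the two neighbouring curves; rates outside the
#' stored range are clamped to the nearest curve. Strains beyond the last
#' tabulated point continue the final segment linearly and are flagged in the
#' `"extrapolated"` attribute of the result.
#'
#' @param f a [foam_curves()] family.
#' @param strain compressive engineering strain(s), non-negative.
#' @param rate engineering strain rate, 1/s, non-negative scalar.
#' @return stress in MPa with attribute `extrapolated` (logical vector).
#' @export
foam_stress <- function(f, strain, rate) {
  stopifnot(inherits(f, "foam_curves"))
  stop_if(any(strain < 0), "strain must be non-negative")
  stop_if(!is_scalar_num(rate) || rate < 0, "rate must be a non-negative scalar")
  r <- f$rates
  if (rate <= r[1] || length(r) == 1L) {
    cs <- curve_stress(f$curves[[1]], strain)
    return(structure(cs$stress, extrapolated = cs$extrapolated))
  }
  if (rate >= r[length(r)]) {
    cs <- curve_stress(f$curves[[length(r)]], strain)
    return(structure(cs$stress, extrapolated = cs$extrapolated))
  }
  i <- findInterval(rate, r)
  if (rate == r[i]) {
    cs <- curve_stress(f$curves[[i]], strain)
    return(structure(cs$stress, extrapolated = cs$extrapolated))
  }
  w <- (log10(rate) - log10(r[i])) / (log10(r[i + 1]) - log10(r[i]))
  lo <- curve_stress(f$curves[[i]], strain)
  hi <- curve_stress(f$curves[[i + 1]], strain)
  structure((1 - w) * lo$stress + w * hi$stress,
            extrapolated = lo$extrapolated | hi$extrapolated)
}
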