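# Continuum kinematics on homogeneous deformation states: canonical test
# deformations, isochoric invariants, fiber stretch, the analytic Cauchy
# stress of the fiber-reinforced material, its quasi-linear viscoelastic
# extension over a deformation history, and a central-difference stress
# oracle used to verify the analytic implementation.

#' Deformation state
#'
#' A homogeneous deformation gradient together with a reference fiber
#' direction. Derived quantities (volume ratio, isochoric invariants, fiber
#' stretch) are available through [isochoric_invariants()] and
#' [fiber_stretch()].
#'
#' @param F 3x3 deformation gradient with positive determinant.
#' @param a0 reference fiber direction; normalized to unit length.
#' @return an object of class `deformation_state`.
#' @export
deformation_state <- function(F, a0 = c(1, 0, 0)) {
  F <- matrix(as.numeric(F), 3, 3)
  stop_if(!all(is.finite(F)), "F must be finite")
  stop_if(det(F) <= 0, "det(F) must be positive")
  n <- sqrt(sum(a0^2))
  stop_if(n == 0, "fiber direction must be non-zero")
  structure(list(F = F, a0 = a0 / n), class = "deformation_state")
}

#' @export
print.deformation_state <- function(x, ...) {
  inv <- isochoric_invariants(x$F)
  cat(sprintf("Deformation state: J = %.6g, I1_bar = %.6g, I2_bar = %.6g, fiber stretch = %.6g\n",
              inv$J, inv$I1_bar, inv$I2_bar, fiber_stretch(x$F, x$a0)))
  invisible(x)
}

#' Uniaxial stretch deformation
#'
#' Principal stretches `(lam, lam^-1/2, lam^-1/2)` when incompressible
#' (volume-preserving), `(lam, 1, 1)` otherwise, with the stretch on the
#' first axis.
#'
#' @param lam axial stretch, positive.
#' @param incompressible logical.
#' @param a0 reference fiber direction.
#' @export
make_uniaxial <- function(lam, incompressible = TRUE, a0 = c(1, 0, 0)) {
  stop_if(!(lam > 0), "stretch must be positive")
  lat <- if (incompressible) lam^(-1 / 2) else 1
  deformation_state(diag(c(lam, lat, lat)), a0 = a0)
}

#' Simple shear deformation
#'
#' `F = I + gamma e_i (x) e_j` for the axis pair `plane = c(i, j)`; volume
#' preserving with `I1_bar = 3 + gamma^2`.
#'
#' @param gamma shear strain.
#' @param plane integer pair `(i, j)` selecting the shear component `F[i, j]`.
#' @param a0 reference fiber direction.
#' @export
make_simple_shear <- function(gamma, plane = c(1L, 3L), a0 = c(1, 0, 0)) {
  stop_if(!is.finite(gamma), "gamma must be finite")
  stop_if(plane[1] == plane[2], "shear plane needs two distinct axes")
  F <- diag(3)
  F[plane[1], plane[2]] <- gamma
  deformation_state(F, a0 = a0)
}

#' Isochoric strain invariants
#'
#' Invariants of the volume-normalized right Cauchy-Green tensor:
#' `I1_bar = J^{-2/3} tr(C)` and
#' `I2_bar = J^{-4/3} ((tr C)^2 - tr(C^2)) / 2` with `C = F'F`. Both are
#' at least 3, with equality exactly for a pure dilation.
#'
#' @param F 3x3 deformation gradient (or a `deformation_state`).
#' @return list with `I1_bar`, `I2_bar`, `J`.
#' @export
isochoric_invariants <- function(F) {
  if (inherits(F, "deformation_state")) F <- F$F
  J <- det(F)
  stop_if(J <= 0, "det(F) must be positive")
  C <- crossprod(F)
  trC <- sum(diag(C))
  trC2 <- sum(C * C)  # tr(C %*% C) for symmetric C
  list(I1_bar = J^(-2 / 3) * trC,
       I2_bar = J^(-4 / 3) * 0.5 * (trC^2 - trC2),
       J = J)
}

#' Fiber stretch
#'
#' `lambda = |F a0|`, the stretch of a material line element along the
#' reference fiber direction.
#'
#' @param F 3x3 deformation gradient (or a `deformation_state`).
#' @param a0 unit reference fiber direction.
#' @export
fiber_stretch <- function(F, a0 = c(1, 0, 0)) {
  if (inherits(F, "deformation_state")) {
    a0 <- F$a0
    F <- F$F
  }
  a0 <- a0 / sqrt(sum(a0^2))
  sqrt(sum((F %*% a0)^2))
}

#' Analytic hyperelastic Cauchy stress
#'
#' Closed-form Cauchy stress of the fiber-reinforced Mooney-Rivlin energy:
#' deviatoric isochoric part from `I1_bar`, `I2_bar`, fiber part
#' `(dF/dl) l / J a (x) a` along the deformed fiber direction (not
#' deviatorically projected), and hydrostatic part `K ln(J)/J I`.
#'
#' @param p a [transverse_iso()] material.
#' @param d a [deformation_state()].
#' @return 3x3 Cauchy stress in kPa.
#' @export
cauchy_stress_elastic <- function(p, d) {
  stopifnot(inherits(p, "transverse_iso"), inherits(d, "deformation_state"))
  F <- d$F
  J <- det(F)
  stop_if(J <= 0, "det(F) must be positive")
  B <- tcrossprod(F)
  Bbar <- J^(-2 / 3) * B
  I1b <- sum(diag(Bbar))
  Bbar2 <- Bbar %*% Bbar
  I2b <- 0.5 * (I1b^2 - sum(diag(Bbar2)))
  A <- (p$C1_kPa + I1b * p$C2_kPa) * Bbar - p$C2_kPa * Bbar2
  iso <- (2 / J) * (A - sum(diag(A)) / 3 * diag(3))
  lam <- fiber_stretch(F, d$a0)
  fib <- matrix(0, 3, 3)
  if (lam > 1 && (p$C3_kPa > 0 || p$C5_kPa > 0)) {
    a <- as.numeric(F %*% d$a0) / lam
    fib <- fiber_stress_derivative(p, lam) * lam / J * tcrossprod(a)
  }
  vol <- p$K_GPa * 1e6 * log(J) / J * diag(3)
  iso + fib + vol
}

#' Finite-difference Cauchy stress oracle
#'
#' Brute-force verification stress: `sigma = J^-1 (dW/dF) F'` with the nine
#' partial derivatives taken by central differences on the components of `F`
#' (relative step `h`). If the resulting tensor is asymmetric beyond
#' `sym_tol`, the step is refined once by Richardson extrapolation.
#'
#' @param energy_fn function of a 3x3 matrix returning an energy density.
#' @param F 3x3 deformation gradient.
#' @param h relative finite-difference step.
#' @param sym_tol relative asymmetry tolerance triggering refinement.
#' @return 3x3 Cauchy stress (units of `energy_fn`).
#' @export
cauchy_stress_numeric <- function(energy_fn, F, h = 1e-6, sym_tol = 1e-6) {
  if (inherits(F, "deformation_state")) F <- F$F
  J <- det(F)
  stop_if(J <= 0, "det(F) must be positive")
  grad_at <- function(step) {
    P <- matrix(0, 3, 3)
    for (i in 1:3) for (j in 1:3) {
      hij <- step * max(abs(F[i, j]), 1)
      Fp <- F; Fp[i, j] <- Fp[i, j] + hij
      Fm <- F; Fm[i, j] <- Fm[i, j] - hij
      P[i, j] <- (energy_fn(Fp) - energy_fn(Fm)) / (2 * hij)
    }
    P
  }
  sig <- grad_at(h) %*% t(F) / J
  asym <- max(abs(sig - t(sig))) / max(abs(sig), .Machine$double.eps)
  if (asym > sym_tol) {
    # Richardson: combine steps h and h/2 to cancel the leading error term
    s2 <- grad_at(h / 2) %*% t(F) / J
    sig <- (4 * s2 - sig) / 3
  }
  (sig + t(sig)) / 2
}

#' Viscoelastic Cauchy stress over a deformation history
#'
#' Quasi-linear viscoelastic stress at the final time of a uniformly sampled
#' deformation history. The instantaneous hyperelastic stress is augmented by
#' Prony overstress terms acting on its deviatoric part,
#' `h_i' = S_i d(dev sigma_e)/dt - h_i / T_i`, integrated by the recursive
#' exponential update that is exact for piecewise-linear stress histories.
#' With all `S_i = 0` the hyperelastic stress is recovered; under a held
#' deformation the stress relaxes to the long-term hyperelastic value.
#'
#' @param p a [transverse_iso()] material (its `prony` table supplies the
#'   `S_i`, `T_i`).
#' @param history list of `deformation_state`s (or 3x3 matrices) at uniform
#'   time spacing, starting at the identity.
#' @param dt_ms time step between history entries, ms.
#' @param full logical; return the stress at every step instead of the final
#'   one.
#' @return 3x3 Cauchy stress in kPa (or a list of them if `full = TRUE`).
#' @export
cauchy_stress <- function(p, history, dt_ms, full = FALSE) {
  stopifnot(inherits(p, "transverse_iso"))
  stop_if(!is_scalar_num(dt_ms) || dt_ms <= 0, "dt_ms must be a positive scalar")
  states <- lapply(history, function(x) {
    if (inherits(x, "deformation_state")) x else deformation_state(x)
  })
  n <- length(states)
  stop_if(n < 1L, "history must be non-empty")
  sig_e <- lapply(states, function(d) cauchy_stress_elastic(p, d))
  dev <- function(s) s - sum(diag(s)) / 3 * diag(3)
  terms <- p$prony
  if (nrow(terms) == 0L) {
    return(if (full) sig_e else sig_e[[n]])
  }
  hlist <- lapply(seq_len(nrow(terms)), function(i) matrix(0, 3, 3))
  out <- vector("list", n)
  out[[1]] <- sig_e[[1]]
  if (n > 1) {
    dprev <- dev(sig_e[[1]])
    for (k in 2:n) {
      dcur <- dev(sig_e[[k]])
      for (i in seq_len(nrow(terms))) {
        Ti <- terms$T_ms[i]
        e <- exp(-dt_ms / Ti)
        # exact update for linear-in-time dev stress across the step
        hlist[[i]] <- e * hlist[[i]] +
          terms$S[i] * (dcur - dprev) * (Ti / dt_ms) * (1 - e)
      }
      out[[k]] <- sig_e[[k]] + Reduce(`+`, hlist)
      dprev <- dcur
    }
  }
  if (full) out else out[[n]]
}
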