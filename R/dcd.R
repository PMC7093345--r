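# Reduced-order model of the dynamic cortical deformation (DCD) suction
# experiment: a standard-linear-solid creep compliance driven by a vacuum
# pressure pulse through a hereditary integral.

#' Suction load pulse
#'
#' Vacuum-pressure history applied to the cortical surface (suction positive).
#'
#' @param t_ms uniform time grid, ms.
#' @param p_kPa pressure values, kPa, non-negative, zero at `t = 0`.
#' @param peak_psi nominal peak in psi (2, 3 or 4 in the source experiments).
#' @param duration_ms nominal pulse duration in ms (25, 50 or 100).
#' @export
suction_load <- function(t_ms, p_kPa, peak_psi = NA, duration_ms = NA) {
  stop_if(!is_uniform_grid(t_ms), "time grid must be uniform and increasing")
  stop_if(length(t_ms) != length(p_kPa), "t and p must have equal length")
  stop_if(p_kPa[1] != 0, "pressure must start at zero")
  stop_if(any(p_kPa < -1e-12), "suction pressure must be non-negative")
  structure(list(t_ms = t_ms, p_kPa = p_kPa, peak_psi = peak_psi,
                 duration_ms = duration_ms),
            class = "suction_load")
}

#' @export
print.suction_load <- function(x, ...) {
  cat(sprintf("Suction pulse: %.3g kPa peak (%s psi nominal), %s ms duration, %d samples\n",
              max(x$p_kPa), format(x$peak_psi), format(x$duration_ms),
              length(x$t_ms)))
  invisible(x)
}

#' Standard-linear-solid surface response model
#'
#' Creep compliance `Jc(t) = Jinf - (Jinf - J0) exp(-t/tau)` mapping applied
#' suction pressure to cortical surface displacement. The `membrane_kind`
#' mirrors the meningeal material models compared in the suction experiment:
#' `"elastic"` and `"elasto-plastic"` respond without lag at the quasi-static
#' compliance, `"viscoelastic"` creeps between `J0` and `Jinf`.
#'
#' @param J0_mm_kPa instantaneous compliance, mm/kPa.
#' @param Jinf_mm_kPa long-term compliance, mm/kPa (`>= J0`).
#' @param tau_ms retardation time, ms.
#' @param membrane_kind one of `"elastic"`, `"elasto-plastic"`,
#'   `"viscoelastic"`.
#' @export
sls_response_model <- function(J0_mm_kPa, Jinf_mm_kPa = J0_mm_kPa,
                               tau_ms = 1e-9,
                               membrane_kind = c("viscoelastic", "elastic",
                                                 "elasto-plastic")) {
  membrane_kind <- match.arg(membrane_kind)
  stop_if(!(J0_mm_kPa > 0), "J0 must be positive")
  stop_if(Jinf_mm_kPa < J0_mm_kPa, "Jinf must be at least J0")
  stop_if(!(tau_ms > 0), "tau must be positive")
  if (membrane_kind != "viscoelastic") {
    # rate-independent kinds collapse to the quasi-static compliance
    J0_mm_kPa <- Jinf_mm_kPa <- max(J0_mm_kPa, Jinf_mm_kPa)
  }
  structure(list(J0_mm_kPa = J0_mm_kPa, Jinf_mm_kPa = Jinf_mm_kPa,
                 tau_ms = tau_ms, membrane_kind = membrane_kind),
            class = "sls_response_model")
}

#' @export
print.sls_response_model <- function(x, ...) {
  cat(sprintf("SLS response model (%s): J0 = %g, Jinf = %g mm/kPa, tau = %g ms\n",
              x$membrane_kind, x$J0_mm_kPa, x$Jinf_mm_kPa, x$tau_ms))
  invisible(x)
}

#' Cortical surface displacement under a suction pulse
#'
#' Hereditary-integral creep response
#' `u(t) = int Jc(t - s) dp(s)` with
#' `Jc(t) = Jinf - (Jinf - J0) exp(-t/tau)`, evaluated by the recursive
#' exponential update that is exact for piecewise-linear pressure histories.
#' Rate-independent membrane kinds return `J0 p(t)` pointwise (no lag); the
#' viscoelastic kind lags the pressure during both loading and unloading and
#' returns to zero after full unload.
#'
#' @param m an [sls_response_model()].
#' @param load a [suction_load()].
#' @return displacement [time_series()] in mm on the load's grid.
#' @export
creep_displacement <- function(m, load) {
  stopifnot(inherits(m, "sls_response_model"), inherits(load, "suction_load"))
  t <- load$t_ms
  p <- load$p_kPa
  if (m$membrane_kind != "viscoelastic") {
    return(time_series(t, m$J0_mm_kPa * p, unit = "mm"))
  }
  n <- length(t)
  dt <- t[2] - t[1]
  e <- exp(-dt / m$tau_ms)
  w <- (m$tau_ms / dt) * (1 - e)  # exact for linear p across each step
  r <- numeric(n)  # r(t) = int exp(-(t-s)/tau) dp(s)
  for (k in 2:n) r[k] <- e * r[k - 1] + w * (p[k] - p[k - 1])
  u <- m$Jinf_mm_kPa * p - (m$Jinf_mm_kPa - m$J0_mm_kPa) * r
  time_series(t, u, unit = "mm")
}
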