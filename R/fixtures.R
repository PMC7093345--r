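# Synthetic-data generation: suction pulse sets, foam curve families, and
# experimental-like response corridors. Together with the shipped material
# library these make every module testable without external data.

#' Suction pulse set
#'
#' The nine vacuum-pressure histories of the cortical-suction experiment:
#' peaks of 2, 3 and 4 psi crossed with durations of 25, 50 and 100 ms.
#' Pressures are converted at 1 psi = 6.894757 kPa. Each pulse rises and
#' falls with half-cosine ramps occupying 10% of the duration at either end,
#' so the pulse support equals the nominal duration and `p(0) = 0`.
#'
#' @param peaks_psi pulse peaks, psi.
#' @param durations_ms pulse durations, ms.
#' @param dt_ms sample spacing.
#' @param tail_ms quiet time appended after the pulse (for observing
#'   recovery).
#' @return named list of [suction_load()]s (`"2psi_25ms"`, ...).
#' @export
make_suction_pulses <- function(peaks_psi = c(2, 3, 4),
                                durations_ms = c(25, 50, 100),
                                dt_ms = 0.25, tail_ms = 100) {
  out <- list()
  for (pk in peaks_psi) for (du in durations_ms) {
    t <- seq(0, du + tail_ms, by = dt_ms)
    ramp <- 0.1 * du
    p <- numeric(length(t))
    rise <- t <= ramp
    hold <- t > ramp & t <= du - ramp
    fall <- t > du - ramp & t <= du
    p[rise] <- 0.5 * (1 - cos(pi * t[rise] / ramp))
    p[hold] <- 1
    p[fall] <- 0.5 * (1 - cos(pi * (du - t[fall]) / ramp))
    out[[sprintf("%gpsi_%gms", pk, du)]] <-
      suction_load(t, pk * PSI_KPA * p, peak_psi = pk, duration_ms = du)
  }
  out
}

#' Synthetic rate-dependent foam curve family
#'
#' Parametric compressive stress-strain curves with a linear-plus-plateau
#' region and a densification asymptote,
#' `sigma(e) = s_r (a e + b e^2 / (1 - e/e_d))`, truncated at `0.95 e_d`,
#' with a rate factor `s_r` increasing in `log10(rate)` so the family is
#' monotone in rate. Emulates the four-curve tabulated input of a
#' low-density polyurethane bed foam; it is a synthetic stand-in, not the
#' unpublished characterization data.
#'
#' @param stiffness_scale overall multiplier on stress.
#' @param rates_per_s strain rates of the family, 1/s.
#' @param a_MPa,b_MPa shape constants of the parametric curve.
#' @param dens_strain densification strain `e_d`.
#' @param rate_coeff rate-factor increment per decade of strain rate.
#' @param n_points samples per curve.
#' @param density_kg_mm3 foam density.
#' @return a [foam_curves()] family.
#' @export
make_foam_curves <- function(stiffness_scale = 1,
                             rates_per_s = c(0.01, 1, 100, 1000),
                             a_MPa = 0.30, b_MPa = 0.05, dens_strain = 0.9,
                             rate_coeff = 0.06, n_points = 40,
                             density_kg_mm3 = 1.362e-8) {
  stop_if(!(stiffness_scale > 0), "stiffness_scale must be positive")
  eps <- seq(0, 0.95 * dens_strain, length.out = n_points)
  r0 <- rates_per_s[1]
  curves <- lapply(rates_per_s, function(r) {
    fac <- stiffness_scale * (1 + rate_coeff * log10(r / r0))
    data.frame(strain = eps,
               stress_MPa = fac * (a_MPa * eps +
                                     b_MPa * eps^2 / (1 - eps / dens_strain)))
  })
  foam_curves(rates_per_s, curves, density_kg_mm3 = density_kg_mm3)
}

#' Experimental-like response corridor
#'
#' Generates `n` perturbed replicates of a base curve (additive Gaussian
#' noise, optional Gaussian timing jitter) and their corridor, emulating the
#' replicate sets behind experimental mean +/- sd corridors. Fully
#' reproducible under a fixed seed; the caller's RNG state is untouched.
#'
#' @param base_curve a [time_series()].
#' @param n number of replicates (>= 2).
#' @param noise_sd additive noise standard deviation (units of the curve).
#' @param time_jitter_ms sd of the per-replicate time shift.
#' @param seed integer seed.
#' @return list with `curves` (list of [time_series()]) and `corridor`.
#' @export
make_reference_corridor <- function(base_curve, n = 16, noise_sd = 0,
                                    time_jitter_ms = 0, seed = 1) {
  stopifnot(inherits(base_curve, "time_series"))
  stop_if(n < 2, "need at least two replicates")
  t <- base_curve$t_ms
  curves <- with_seed(seed, {
    lapply(seq_len(n), function(i) {
      v <- base_curve$v
      if (time_jitter_ms > 0) {
        shift <- stats::rnorm(1, 0, time_jitter_ms)
        v <- stats::approx(t + shift, v, xout = t, rule = 2)$y
      }
      if (noise_sd > 0) v <- v + stats::rnorm(length(v), 0, noise_sd)
      time_series(t, v, unit = base_curve$unit)
    })
  })
  list(curves = curves, corridor = build_corridor(curves))
}
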