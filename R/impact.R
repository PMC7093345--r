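# Planar reduced-order simulator of the guided drop-weight impact onto a
# helmeted rodent head resting on a foam bed.
#
# Mechanism: a vertically guided impactor strikes the helmet disk through a
# unilateral penalty spring-dashpot whose contact normal is tilted by the
# helmet inclination angle (plus the current head pitch). The tilt splits the
# impulse into a normal component (linear acceleration) and a tangential
# component with a moment arm about the head's centre of mass (rotation),
# which is the minimal mechanism behind the inverse linear/rotational
# trade-off observed across helmet-angle cases. The head is supported by a
# rate-dependent foam element and coupled to a body mass (on its own foam
# element) through a rotational neck spring-damper; the translational neck
# spring acts through the centre of mass. Sideways (out-of-plane) tilts reuse
# the same planar model: the in-plane normal impulse is reduced by cos(angle)
# and the out-of-plane component is carried as a lateral-force bookkeeping
# channel. Internally everything is SI (m, s, N, kg); configuration fields
# carry unit-suffixed names in the experiment's units.

#' Drop-impact configuration
#'
#' Lumped description of a guided drop-weight impact onto a helmeted rodent
#' head on a foam bed. Defaults mirror the instrumented impact-acceleration
#' experiments: a 450 g brass impactor at 6.15 m/s (2.25 m drop), a 2.8 g
#' titanium helmet disk, a 400 g animal. Head pitch inertia and the neck
#' constants are not measurable from the published setup; their defaults are
#' calibration artifacts chosen so the baseline angular-velocity history
#' shows its first (negative) peak within 2 ms of contact and the opposite
#' second peak near 5 ms.
#'
#' @param impactor_v0_ms impactor speed just before contact, m/s (positive).
#' @param impactor_mass_kg impactor mass.
#' @param helmet_mass_kg helmet disk mass (lumped into the head).
#' @param head_mass_kg head mass.
#' @param head_pitch_inertia_kgm2 pitch moment of inertia about the head COM.
#' @param body_mass_kg rest-of-animal mass resting on its own foam element.
#' @param helmet_angle_deg signed helmet inclination; in the sagittal plane
#'   positive tilts forward (anterior edge down), negative backward.
#' @param plane `"sagittal"` or `"lateral"` (sideways tilt).
#' @param contact_stiffness_N_mm penalty contact stiffness.
#' @param contact_stiffness_scale multiplier on the stiffness (0.8 / 1 / 1.2
#'   in the skull-stiffness sweep); `"rigid"` is represented by 100.
#' @param contact_damping_Ns_mm contact dashpot constant.
#' @param helmet_offset_mm in-plane offset `(x, z)` of the helmet contact
#'   point from the head COM, mm (x anterior, z up); the default posterior
#'   offset reflects the helmet position on the posterior half of the skull
#'   and makes the first rotational phase an extension (negative omega_y).
#' @param neck_rot_stiffness_Nmm_rad,neck_rot_damping_Nmm_s_rad rotational
#'   neck spring-damper between head pitch and body.
#' @param neck_trans_stiffness_N_mm,neck_trans_damping_Ns_mm translational
#'   neck spring-damper (through the COM).
#' @param foam a [foam_curves()] family for the supporting foam.
#' @param foam_area_mm2,foam_thickness_mm head-foam contact patch and
#'   crushable thickness (the head rests on a 10 mm step rise of the bed).
#' @param body_foam_area_mm2 body-foam contact patch.
#' @param step_rise_mm height of the foam step under the head.
#' @param foam_hysteresis unloading force fraction (foam energy dissipation).
#' @param initial_gap_mm initial impactor-helmet gap (free flight).
#' @param dt_ms integrator step, ms.
#' @param t_end_ms simulated duration, ms (>= 15 covers the full event).
#' @return an object of class `impact_config`.
#' @export
impact_config <- function(impactor_v0_ms = 6.15,
                          impactor_mass_kg = 0.45,
                          helmet_mass_kg = 0.0028,
                          head_mass_kg = 0.042,
                          head_pitch_inertia_kgm2 = 1.3e-5,
                          body_mass_kg = 0.358,
                          helmet_angle_deg = 0,
                          plane = c("sagittal", "lateral"),
                          contact_stiffness_N_mm = 600,
                          contact_stiffness_scale = 1,
                          contact_damping_Ns_mm = 0.02,
                          helmet_offset_mm = c(-2.5, 9),
                          neck_rot_stiffness_Nmm_rad = 9400,
                          neck_rot_damping_Nmm_s_rad = 4.4,
                          neck_trans_stiffness_N_mm = 1,
                          neck_trans_damping_Ns_mm = 0.005,
                          foam = NULL,
                          foam_area_mm2 = 600,
                          foam_thickness_mm = 120,
                          body_foam_area_mm2 = 3000,
                          step_rise_mm = 10,
                          foam_hysteresis = 0.2,
                          initial_gap_mm = 0.5,
                          dt_ms = 0.001,
                          t_end_ms = 15) {
  plane <- match.arg(plane)
  if (identical(contact_stiffness_scale, "rigid")) contact_stiffness_scale <- 100
  stop_if(impactor_v0_ms < 0, "impactor_v0_ms is a speed; use a non-negative value")
  for (m in c(impactor_mass_kg, helmet_mass_kg, head_mass_kg, body_mass_kg))
    stop_if(!(m > 0), "all masses must be positive")
  stop_if(!(head_pitch_inertia_kgm2 > 0), "pitch inertia must be positive")
  stop_if(!(contact_stiffness_N_mm > 0) || !(contact_stiffness_scale > 0),
          "contact stiffness must be positive")
  stop_if(!(dt_ms > 0), "dt must be positive")
  stop_if(t_end_ms < 15, "t_end_ms must be at least 15 ms to cover the event")
  if (is.null(foam)) foam <- make_foam_curves()
  stopifnot(inherits(foam, "foam_curves"))
  structure(list(impactor_v0_ms = impactor_v0_ms,
                 impactor_mass_kg = impactor_mass_kg,
                 helmet_mass_kg = helmet_mass_kg,
                 head_mass_kg = head_mass_kg,
                 head_pitch_inertia_kgm2 = head_pitch_inertia_kgm2,
                 body_mass_kg = body_mass_kg,
                 helmet_angle_deg = helmet_angle_deg, plane = plane,
                 contact_stiffness_N_mm = contact_stiffness_N_mm,
                 contact_stiffness_scale = contact_stiffness_scale,
                 contact_damping_Ns_mm = contact_damping_Ns_mm,
                 helmet_offset_mm = helmet_offset_mm,
                 neck_rot_stiffness_Nmm_rad = neck_rot_stiffness_Nmm_rad,
                 neck_rot_damping_Nmm_s_rad = neck_rot_damping_Nmm_s_rad,
                 neck_trans_stiffness_N_mm = neck_trans_stiffness_N_mm,
                 neck_trans_damping_Ns_mm = neck_trans_damping_Ns_mm,
                 foam = foam, foam_area_mm2 = foam_area_mm2,
                 foam_thickness_mm = foam_thickness_mm,
                 body_foam_area_mm2 = body_foam_area_mm2,
                 step_rise_mm = step_rise_mm,
                 foam_hysteresis = foam_hysteresis,
                 initial_gap_mm = initial_gap_mm,
                 dt_ms = dt_ms, t_end_ms = t_end_ms),
            class = "impact_config")
}

#' @export
print.impact_config <- function(x, ...) {
  cat(sprintf("Impact config: %.3g kg impactor at %.3g m/s, helmet angle %g deg (%s), contact %g N/mm x %g, dt %g ms\n",
              x$impactor_mass_kg, x$impactor_v0_ms, x$helmet_angle_deg,
              x$plane, x$contact_stiffness_N_mm, x$contact_stiffness_scale,
              x$dt_ms))
  invisible(x)
}

# static foam compression (m) balancing weight `w` (N) on `area` mm^2;
# `fac0` is the loading/unloading blend factor at zero rate
static_foam_compression <- function(foam, area_mm2, thick_m, w_N, fac0 = 1) {
  f <- function(s) fac0 * foam_stress(foam, s / thick_m, 0)[1] * area_mm2 - w_N
  if (f(0) >= 0) return(0)
  hi <- 0.5 * thick_m
  if (f(hi) < 0) return(hi)
  stats::uniroot(f, c(0, hi), tol = 1e-14)$root
}

# precompute a fast single-rate foam interpolator table for the integrator
foam_fast_table <- function(foam) {
  lapply(foam$curves, function(cv) {
    n <- nrow(cv)
    list(x = cv$strain, y = cv$stress_MPa,
         slope_end = (cv$stress_MPa[n] - cv$stress_MPa[n - 1]) /
           (cv$strain[n] - cv$strain[n - 1]))
  })
}

# fast equivalent of foam_stress() for scalar strain/rate inside the
# integrator loop (no validation, no attributes)
fast_foam_stress <- function(tabs, lrates, strain, rate) {
  one <- function(tab, s) {
    n <- length(tab$x)
    if (s >= tab$x[n]) return(tab$y[n] + tab$slope_end * (s - tab$x[n]))
    i <- findInterval(s, tab$x)
    if (i < 1L) i <- 1L
    tab$y[i] + (tab$y[i + 1] - tab$y[i]) * (s - tab$x[i]) / (tab$x[i + 1] - tab$x[i])
  }
  nr <- length(lrates)
  lr <- log10(max(rate, 1e-12))
  if (lr <= lrates[1] || nr == 1L) return(one(tabs[[1]], strain))
  if (lr >= lrates[nr]) return(one(tabs[[nr]], strain))
  i <- findInterval(lr, lrates)
  w <- (lr - lrates[i]) / (lrates[i + 1] - lrates[i])
  (1 - w) * one(tabs[[i]], strain) + w * one(tabs[[i + 1]], strain)
}

# force model shared by the derivative function and the audit; y is the
# state vector, returns forces and power channels (all SI)
impact_forces <- function(y, pr) {
  zi <- y[1]; vi <- y[2]; xh <- y[3]; vxh <- y[4]; zh <- y[5]; vzh <- y[6]
  th <- y[7]; om <- y[8]; zb <- y[9]; vzb <- y[10]
  ct <- cos(th); st <- sin(th)
  # helmet contact point in world frame (offset rotated by pitch)
  rcx <- ct * pr$hx + st * pr$hz
  rcz <- -st * pr$hx + ct * pr$hz
  pcz <- zh + rcz
  vpcx <- vxh + om * rcz
  vpcz <- vzh - om * rcx
  pen <- pcz - zi
  Fc <- 0
  if (pen > 0) {
    Fc <- pr$kc * pen + pr$cc * (vpcz - vi)
    if (Fc < 0) Fc <- 0
  }
  if (pr$plane == "sagittal") {
    phi <- pr$alpha + th
    Fhx <- -Fc * sin(phi)
    Fhz <- -Fc * cos(phi)
    Flat <- 0
  } else {
    Fhx <- 0
    Fhz <- -Fc * cos(pr$alpha)
    Flat <- Fc * abs(sin(pr$alpha))
  }
  Fiz <- -Fhz                       # vertical reaction on the impactor
  # contact moment about the head COM, work-consistent with the contact-point
  # velocity vp = vcom + om * (rcz, -rcx)
  tau_c <- Fhx * rcz - Fhz * rcx

  # head foam (vertical, through COM); smooth loading/unloading blend
  sh <- pr$sh0 + (pr$zh0 - zh)
  Ffh <- 0
  if (sh > 0) {
    sdot <- -vzh
    rate <- max(sdot, 0) / pr$th_f
    fac <- pr$hyst + (1 - pr$hyst) * 0.5 * (1 + tanh(sdot / 0.02))
    Ffh <- fac * fast_foam_stress(pr$ftab, pr$lrates, sh / pr$th_f, rate) * pr$Ah
  }
  # body foam
  sb <- pr$sb0 + (pr$zb0 - zb)
  Ffb <- 0
  if (sb > 0) {
    sdot_b <- -vzb
    rate_b <- max(sdot_b, 0) / pr$th_f
    fac_b <- pr$hyst + (1 - pr$hyst) * 0.5 * (1 + tanh(sdot_b / 0.02))
    Ffb <- fac_b * fast_foam_stress(pr$ftab, pr$lrates, sb / pr$th_f, rate_b) * pr$Ab
  }

  # neck: translational spring-damper through the COM, rotational on pitch
  relx <- xh - pr$xh0
  relz <- (zh - pr$zh0) - (zb - pr$zb0)
  Fnx <- -pr$kt * relx - pr$ct * vxh
  Fnz <- -pr$kt * relz - pr$ct * (vzh - vzb)
  Mn <- -pr$kr * th - pr$cr * om

  list(Fc = Fc, pen = pen, Fhx = Fhx, Fhz = Fhz, Fiz = Fiz, Flat = Flat,
       tau_c = tau_c, Ffh = Ffh, Ffb = Ffb, Fnx = Fnx, Fnz = Fnz, Mn = Mn,
       vpcx = vpcx, vpcz = vpcz)
}

impact_deriv <- function(t, y, pr) {
  f <- impact_forces(y, pr)
  vi <- y[2]; vxh <- y[4]; vzh <- y[6]; om <- y[8]; vzb <- y[10]
  ai <- -G_STD + f$Fiz / pr$mi
  ax <- (f$Fhx + f$Fnx) / pr$mh
  az <- -G_STD + (f$Fhz + f$Ffh + f$Fnz) / pr$mh
  aa <- (f$tau_c + f$Mn) / pr$I
  ab <- -G_STD + (f$Ffb - f$Fnz) / pr$mb
  # power absorbed by each non-gravity element (positive = extracted)
  P_contact <- -(f$Fhx * f$vpcx + f$Fhz * f$vpcz) - f$Fiz * vi
  P_foam_h <- -f$Ffh * vzh
  P_foam_b <- -f$Ffb * vzb
  P_neck <- -(f$Fnx * vxh + f$Fnz * (vzh - vzb)) - f$Mn * om
  list(c(vi, ai, vxh, ax, vzh, az, om, aa, vzb, ab),
       Fc = f$Fc, pen = f$pen, Flat = f$Flat, Ffh = f$Ffh, Ffb = f$Ffb,
       ai = ai, ax = ax, az = az, aa = aa,
       P_contact = P_contact, P_foam_h = P_foam_h, P_foam_b = P_foam_b,
       P_neck = P_neck)
}

#' Simulate a drop impact
#'
#' Integrates the planar rigid-body model (impactor z; head x, z, pitch;
#' body z) with a fixed-step 4th-order Runge-Kutta scheme. The impactor is
#' constrained to vertical translation and is in free flight (acceleration
#' exactly -g) until first contact; the contact is a unilateral penalty and
#' its force is zero whenever the gap is open. The simulation is fully
#' deterministic.
#'
#' @param cfg an [impact_config()].
#' @return an object of class `impact_result` with the channel history
#'   (data frame), the peak summary, contact time, acceleration pulse
#'   duration and the energy audit.
#' @export
simulate_impact <- function(cfg) {
  stopifnot(inherits(cfg, "impact_config"))
  mm <- 1e-3
  mh <- cfg$head_mass_kg + cfg$helmet_mass_kg
  th_f <- cfg$foam_thickness_mm * mm
  Ah <- cfg$foam_area_mm2      # MPa * mm^2 = N
  Ab <- cfg$body_foam_area_mm2
  fac0 <- (1 + cfg$foam_hysteresis) / 2  # blend factor at zero rate
  sh0 <- static_foam_compression(cfg$foam, Ah, th_f, mh * G_STD, fac0)
  sb0 <- static_foam_compression(cfg$foam, Ab, th_f, cfg$body_mass_kg * G_STD, fac0)
  zh0 <- cfg$step_rise_mm * mm          # head on the foam step
  zb0 <- 0
  hx <- cfg$helmet_offset_mm[1] * mm
  hz <- cfg$helmet_offset_mm[2] * mm
  pr <- list(mi = cfg$impactor_mass_kg, mh = mh, mb = cfg$body_mass_kg,
             I = cfg$head_pitch_inertia_kgm2,
             kc = cfg$contact_stiffness_N_mm * cfg$contact_stiffness_scale / mm,
             cc = cfg$contact_damping_Ns_mm / mm,
             alpha = cfg$helmet_angle_deg * pi / 180, plane = cfg$plane,
             hx = hx, hz = hz,
             kr = cfg$neck_rot_stiffness_Nmm_rad * mm,
             cr = cfg$neck_rot_damping_Nmm_s_rad * mm,
             kt = cfg$neck_trans_stiffness_N_mm / mm,
             ct = cfg$neck_trans_damping_Ns_mm / mm,
             foam = cfg$foam, ftab = foam_fast_table(cfg$foam),
             lrates = log10(pmax(cfg$foam$rates, 1e-12)),
             Ah = Ah, Ab = Ab, th_f = th_f,
             hyst = cfg$foam_hysteresis,
             sh0 = sh0, sb0 = sb0, zh0 = zh0, zb0 = zb0, xh0 = 0)
  zi0 <- zh0 + hz + cfg$initial_gap_mm * mm
  y0 <- c(zi = zi0, vi = -cfg$impactor_v0_ms, xh = 0, vxh = 0,
          zh = zh0, vzh = 0, th = 0, om = 0, zb = zb0, vzb = 0)
  times <- seq(0, cfg$t_end_ms * 1e-3, by = cfg$dt_ms * 1e-3)
  sol <- deSolve::rk4(y0, times, impact_deriv, pr)
  h <- as.data.frame(sol)
  names(h)[1] <- "t_s"
  bad <- !all(is.finite(as.matrix(h)))
  if (bad) stop("impact integration became unstable; reduce dt_ms (currently ",
                cfg$dt_ms, " ms)", call. = FALSE)

  t_ms <- h$t_s * 1e3
  contact_idx <- which(h$Fc > 0)
  contact_time_ms <- if (length(contact_idx)) t_ms[contact_idx[1]] else NA_real_
  # duration of the first continuous contact episode
  pulse_ms <- NA_real_
  if (length(contact_idx)) {
    brk <- which(diff(contact_idx) > 1)
    last <- if (length(brk)) contact_idx[brk[1]] else contact_idx[length(contact_idx)]
    pulse_ms <- t_ms[last] - contact_time_ms
  }
  a_res_g <- sqrt(h$ax^2 + h$az^2) / G_STD
  history <- data.frame(t_ms = t_ms,
                        impactor_z_mm = (h$zi - zi0) / mm,
                        impactor_v_ms = h$vi,
                        impactor_a_ms2 = h$ai,
                        head_x_mm = h$xh / mm,
                        head_z_mm = (h$zh - zh0) / mm,
                        head_ax_g = h$ax / G_STD,
                        head_az_g = h$az / G_STD,
                        head_a_res_g = a_res_g,
                        head_ay_ms2 = h$Flat / mh,
                        pitch_rad = h$th,
                        omega_y_rad_s = h$om,
                        body_z_mm = (h$zb - zb0) / mm,
                        contact_force_N = h$Fc,
                        contact_pen_mm = h$pen / mm,
                        lateral_force_N = h$Flat,
                        foam_force_head_N = h$Ffh,
                        foam_force_body_N = h$Ffb,
                        P_contact_W = h$P_contact,
                        P_foam_head_W = h$P_foam_h,
                        P_foam_body_W = h$P_foam_b,
                        P_neck_W = h$P_neck,
                        vi = h$vi, vxh = h$vxh, vzh = h$vzh,
                        om = h$om, vzb = h$vzb,
                        zi = h$zi, zh = h$zh, zb = h$zb, th = h$th)
  res <- structure(list(history = history, config = cfg,
                        contact_time_ms = contact_time_ms,
                        pulse_duration_ms = pulse_ms,
                        peaks = NULL, energy = NULL),
                   class = "impact_result")
  if (!is.na(contact_time_ms)) {
    disp_contact <- history$impactor_z_mm[contact_idx[1]]
    res$peaks <- extract_peaks(
      time_series(t_ms, a_res_g, "g"),
      time_series(t_ms, history$omega_y_rad_s, "rad/s"),
      time_series(t_ms, history$impactor_z_mm - disp_contact, "mm"),
      contact_time_ms)
  }
  res$energy <- energy_audit(res)
  res
}

#' @export
print.impact_result <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Impact result: v0 = %.3g m/s, helmet angle %g deg (%s)\n",
              cfg$impactor_v0_ms, cfg$helmet_angle_deg, cfg$plane))
  if (!is.null(x$peaks)) print(x$peaks)
  cat(sprintf("  pulse duration %.3f ms; energy residual %.3g%% of input\n",
              x$pulse_duration_ms, 100 * x$energy$residual_rel))
  invisible(x)
}

#' @export
summary.impact_result <- function(object, ...) {
  print(object)
  cat("Energy ledger (J):\n")
  e <- object$energy$ledger
  for (nm in names(e)) cat(sprintf("  %-18s %10.4g\n", nm, e[[nm]]))
  invisible(object)
}

#' @export
plot.impact_result <- function(x, ...) {
  h <- x$history
  op <- graphics::par(mfrow = c(3, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(h$t_ms, h$head_a_res_g, type = "l", xlab = "time [ms]",
                 ylab = "linear acc [g]", ...)
  graphics::plot(h$t_ms, h$omega_y_rad_s, type = "l", xlab = "time [ms]",
                 ylab = "omega_y [rad/s]", ...)
  graphics::plot(h$t_ms, h$impactor_z_mm, type = "l", xlab = "time [ms]",
                 ylab = "impactor z [mm]", ...)
  invisible(x)
}

#' Energy audit of an impact simulation
#'
#' Recomputes every energy term by independent trapezoidal integration of
#' the recorded force-times-velocity channels and checks closure:
#' kinetic + gravitational potential + energy absorbed by the contact, the
#' two foam elements and the neck must equal the initial total at every
#' sample. The relative residual is normalized by the initial kinetic
#' energy.
#'
#' @param result an `impact_result`.
#' @return list with the per-term `ledger` (J), the time-resolved closure
#'   `residual_t`, and the maximal relative residual `residual_rel`.
#' @export
energy_audit <- function(result) {
  stopifnot(inherits(result, "impact_result"))
  h <- result$history
  cfg <- result$config
  mh <- cfg$head_mass_kg + cfg$helmet_mass_kg
  t <- h$t_ms * 1e-3
  KE <- 0.5 * cfg$impactor_mass_kg * h$vi^2 +
    0.5 * mh * (h$vxh^2 + h$vzh^2) +
    0.5 * cfg$head_pitch_inertia_kgm2 * h$om^2 +
    0.5 * cfg$body_mass_kg * h$vzb^2
  PE <- cfg$impactor_mass_kg * G_STD * (h$zi - h$zi[1]) +
    mh * G_STD * (h$zh - h$zh[1]) +
    cfg$body_mass_kg * G_STD * (h$zb - h$zb[1])
  W_contact <- cumtrapz(t, h$P_contact_W)
  W_foam_h <- cumtrapz(t, h$P_foam_head_W)
  W_foam_b <- cumtrapz(t, h$P_foam_body_W)
  W_neck <- cumtrapz(t, h$P_neck_W)
  total <- KE + PE + W_contact + W_foam_h + W_foam_b + W_neck
  resid <- total - total[1]
  E0 <- max(KE[1], max(abs(PE - PE[1])), .Machine$double.eps)
  n <- length(t)
  ledger <- list(kinetic = KE[n], potential = PE[n],
                 contact_absorbed = W_contact[n],
                 foam_head_absorbed = W_foam_h[n],
                 foam_body_absorbed = W_foam_b[n],
                 neck_absorbed = W_neck[n],
                 reference_energy = E0)
  list(ledger = ledger, residual_t = resid,
       residual_rel = max(abs(resid)) / E0)
}

run_case <- function(cfg, angle = NULL, plane = NULL, scale = NULL) {
  if (!is.null(angle)) cfg$helmet_angle_deg <- angle
  if (!is.null(plane)) cfg$plane <- plane
  if (!is.null(scale)) {
    cfg$contact_stiffness_scale <- if (identical(scale, "rigid")) 100 else scale
  }
  simulate_impact(cfg)
}

#' Helmet-angle parametric sweep
#'
#' Simulates the helmet-inclination cases (backward / forward 2 and 5 degrees
#' in the sagittal plane, 2 and 5 degrees sideways) against the flat baseline
#' and tabulates the percent change of the peak kinematics.
#'
#' @param cfg baseline [impact_config()] (its angle is forced to 0).
#' @param angles_deg unsigned tilt magnitudes for each direction.
#' @param keep_results logical; attach the individual `impact_result`s.
#' @return list of class `impact_sweep` with the percent-change `table`,
#'   the named `peaks`, and optionally `results`.
#' @export
sweep_helmet_angle <- function(cfg, angles_deg = c(2, 5), keep_results = FALSE) {
  stopifnot(inherits(cfg, "impact_config"))
  cases <- list()
  for (a in angles_deg) {
    cases[[sprintf("B_%gdeg", a)]] <- list(angle = -a, plane = "sagittal")
    cases[[sprintf("F_%gdeg", a)]] <- list(angle = a, plane = "sagittal")
    cases[[sprintf("S_%gdeg", a)]] <- list(angle = a, plane = "lateral")
  }
  base <- run_case(cfg, angle = 0, plane = "sagittal")
  results <- lapply(cases, function(cs) run_case(cfg, cs$angle, cs$plane))
  peaks <- lapply(results, `[[`, "peaks")
  out <- list(table = percent_change_table(peaks, base$peaks),
              peaks = peaks, baseline = base$peaks)
  if (keep_results) {
    out$results <- results
    out$baseline_result <- base
  }
  structure(out, class = "impact_sweep")
}

#' Contact-stiffness parametric sweep
#'
#' Simulates reduced / raised / rigid contact-stiffness cases against the
#' baseline, standing in for the skull-modulus variation of the full model
#' (skull stiffness enters the reduced model only through the contact
#' stiffness scale).
#'
#' @param cfg baseline [impact_config()].
#' @param scales stiffness multipliers; `"rigid"` maps to 100.
#' @param keep_results logical; attach the individual `impact_result`s.
#' @return list of class `impact_sweep` (see [sweep_helmet_angle()]); also
#'   carries the `pulse_ms` durations per case.
#' @export
sweep_contact_stiffness <- function(cfg, scales = list(0.8, 1.2, "rigid"),
                                    keep_results = FALSE) {
  stopifnot(inherits(cfg, "impact_config"))
  nm <- vapply(scales, function(s)
    if (identical(s, "rigid")) "E_skull_Rigid"
    else if (s < 1) "E_skull_L" else "E_skull_H", character(1))
  base <- run_case(cfg, angle = 0, plane = "sagittal", scale = 1)
  results <- lapply(scales, function(s)
    run_case(cfg, angle = 0, plane = "sagittal", scale = s))
  names(results) <- nm
  peaks <- lapply(results, `[[`, "peaks")
  out <- list(table = percent_change_table(peaks, base$peaks),
              peaks = peaks, baseline = base$peaks,
              pulse_ms = c(Baseline = base$pulse_duration_ms,
                           vapply(results, `[[`, numeric(1), "pulse_duration_ms")))
  if (keep_results) {
    out$results <- results
    out$baseline_result <- base
  }
  structure(out, class = "impact_sweep")
}

#' @export
print.impact_sweep <- function(x, ...) {
  print(x$table)
  invisible(x)
}

#' Default drop-impact configurations
#'
#' The two instrumented drop heights: 2.25 m (impact speed 6.15 m/s) and
#' 1.25 m (4.54 m/s); all other parameters identical.
#'
#' @return named list of two [impact_config()]s.
#' @export
default_impact_configs <- function() {
  list("h2.25m" = impact_config(impactor_v0_ms = 6.15),
       "h1.25m" = impact_config(impactor_v0_ms = 4.54))
}
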