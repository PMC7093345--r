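# Validation-metric layer: time-series container, experimental corridors,
# peak extraction in the experiment's time windows, a CORA-like biofidelity
# rating, and percent-change tables for parametric sweeps.

#' Uniform time series
#'
#' @param t_ms strictly increasing uniform time grid, ms.
#' @param v values, finite, same length as `t_ms`.
#' @param unit unit tag (e.g. `"g"`, `"rad/s"`, `"mm"`, `"kPa"`).
#' @export
time_series <- function(t_ms, v, unit = "") {
  stop_if(length(t_ms) != length(v), "t and v must have equal length")
  stop_if(!is_uniform_grid(t_ms), "t must be a strictly increasing uniform grid")
  stop_if(any(!is.finite(v)), "values must be finite")
  structure(list(t_ms = as.numeric(t_ms), v = as.numeric(v), unit = unit),
            class = "time_series")
}

#' @export
print.time_series <- function(x, ...) {
  cat(sprintf("Time series: %d samples over [%g, %g] ms%s, range [%.4g, %.4g]\n",
              length(x$t_ms), x$t_ms[1], x$t_ms[length(x$t_ms)],
              if (nzchar(x$unit)) paste0(" [", x$unit, "]") else "",
              min(x$v), max(x$v)))
  invisible(x)
}

#' @export
plot.time_series <- function(x, ...) {
  graphics::plot(x$t_ms, x$v, type = "l", xlab = "time [ms]",
                 ylab = x$unit, ...)
  invisible(x)
}

same_grid <- function(a, b, tol = 1e-9) {
  length(a$t_ms) == length(b$t_ms) &&
    max(abs(a$t_ms - b$t_ms)) <= tol * max(1, abs(a$t_ms[length(a$t_ms)]))
}

#' Experimental response corridor
#'
#' Pointwise mean and sample standard deviation (n - 1 denominator) of two or
#' more response curves on an identical grid; the corridor band
#' `mean +/- sd` is the usual biofidelity target region.
#'
#' @param curves list of at least two [time_series()] on the same grid.
#' @return object of class `corridor` with `t_ms`, `mean`, `sd`.
#' @export
build_corridor <- function(curves) {
  stop_if(length(curves) < 2L, "at least two curves are required")
  stopifnot(all(vapply(curves, inherits, logical(1), "time_series")))
  for (cv in curves[-1]) stop_if(!same_grid(curves[[1]], cv),
                                 "curves must share one grid")
  vals <- vapply(curves, function(cv) cv$v, numeric(length(curves[[1]]$v)))
  structure(list(t_ms = curves[[1]]$t_ms,
                 mean = rowMeans(vals),
                 sd = apply(vals, 1, stats::sd),
                 n = length(curves)),
            class = "corridor")
}

#' @export
print.corridor <- function(x, ...) {
  cat(sprintf("Corridor from n = %d curves, %d samples; max sd = %.4g\n",
              x$n, length(x$t_ms), max(x$sd)))
  invisible(x)
}

#' @export
plot.corridor <- function(x, ...) {
  up <- x$mean + x$sd
  lo <- x$mean - x$sd
  graphics::plot(x$t_ms, x$mean, type = "n", ylim = range(up, lo),
                 xlab = "time [ms]", ylab = "response", ...)
  graphics::polygon(c(x$t_ms, rev(x$t_ms)), c(up, rev(lo)),
                    col = "grey85", border = NA)
  graphics::lines(x$t_ms, x$mean, lwd = 2)
  invisible(x)
}

#' Peak kinematics summary
#'
#' Extracts the impact-experiment peak metrics with their conventional time
#' windows (all relative to first contact): peak linear acceleration within
#' the first 1 ms, the lower negative angular-velocity peak within 2 ms, the
#' higher positive angular-velocity peak thereafter (by 15 ms), and the
#' (negative) extreme impactor displacement.
#'
#' @param acc linear-acceleration [time_series()] in g (magnitude).
#' @param omega angular-velocity [time_series()] in rad/s (signed).
#' @param disp impactor-displacement [time_series()] in mm (signed).
#' @param contact_time_ms time of first contact, ms.
#' @param windows list with elements `lin`, `omega_neg`, `omega_pos`
#'   (each `c(lo, hi)` in ms after contact).
#' @return object of class `peak_summary`.
#' @export
extract_peaks <- function(acc, omega, disp, contact_time_ms,
                          windows = list(lin = c(0, 1), omega_neg = c(0, 2),
                                         omega_pos = c(2, 15))) {
  stopifnot(inherits(acc, "time_series"), inherits(omega, "time_series"),
            inherits(disp, "time_series"))
  stop_if(!same_grid(acc, omega) || !same_grid(acc, disp),
          "all series must share one grid")
  pick <- function(ts, win, fn) {
    sel <- ts$t_ms > contact_time_ms + win[1] & ts$t_ms <= contact_time_ms + win[2]
    stop_if(!any(sel), "peak window [", win[1], ", ", win[2],
            "] ms after contact contains no samples")
    idx <- which(sel)[fn(ts$v[sel])]
    list(value = ts$v[idx], t_ms = ts$t_ms[idx])
  }
  lin <- pick(acc, windows$lin, which.max)
  wn <- pick(omega, windows$omega_neg, which.min)
  wp <- pick(omega, windows$omega_pos, which.max)
  di <- list(value = min(disp$v), t_ms = disp$t_ms[which.min(disp$v)])
  structure(list(lin_peak = lin, omega_neg_peak = wn, omega_pos_peak = wp,
                 impactor_disp_min = di, contact_time_ms = contact_time_ms),
            class = "peak_summary")
}

#' @export
print.peak_summary <- function(x, ...) {
  cat(sprintf("Peaks (contact at %.3f ms):\n", x$contact_time_ms))
  cat(sprintf("  linear acc     %8.1f g     at %.3f ms\n",
              x$lin_peak$value, x$lin_peak$t_ms))
  cat(sprintf("  omega_y neg    %8.2f rad/s at %.3f ms\n",
              x$omega_neg_peak$value, x$omega_neg_peak$t_ms))
  cat(sprintf("  omega_y pos    %8.2f rad/s at %.3f ms\n",
              x$omega_pos_peak$value, x$omega_pos_peak$t_ms))
  cat(sprintf("  impactor disp  %8.2f mm    at %.3f ms\n",
              x$impactor_disp_min$value, x$impactor_disp_min$t_ms))
  invisible(x)
}

snap1 <- function(x, tol = 1e-12) if (x > 1 - tol) 1 else max(0, x)

#' CORA-like biofidelity rating
#'
#' Scalar rating in `[0, 1]` (1 = perfect match) combining a corridor
#' sub-rating with cross-correlation sub-ratings, in the spirit of the CORA
#' standard but with a documented, open decomposition:
#'
#' * corridor: pointwise 1 inside the inner band, linear falloff to 0 at the
#'   outer band, averaged over time. With an experimental [build_corridor()]
#'   the bands are mean +/- sd and mean +/- `outer_k` sd; without one they
#'   are 5% and 50% of the reference peak amplitude around the reference.
#' * phase: from the lag maximizing the cross-correlation within
#'   +/- `max_shift_frac` of the duration.
#' * size: ratio of the smaller to the larger absolute-area of the curves.
#' * shape: correlation coefficient at the optimal lag, clipped to `[0, 1]`.
#'
#' Combined score: `0.5 * corridor + 0.5 * mean(size, phase, shape)`.
#'
#' @param candidate,reference [time_series()] on a common grid; the reference
#'   must not be identically zero.
#' @param corridor optional [build_corridor()] result on the same grid.
#' @param max_shift_frac maximum lag scanned, as a fraction of the duration.
#' @param outer_k outer corridor band in units of sd.
#' @return object of class `rating_score` with components `corridor_score`,
#'   `size`, `phase`, `shape`, `combined`.
#' @export
rate_curve <- function(candidate, reference, corridor = NULL,
                       max_shift_frac = 0.2, outer_k = 3) {
  stopifnot(inherits(candidate, "time_series"), inherits(reference, "time_series"))
  stop_if(!same_grid(candidate, reference), "curves must share one grid")
  x <- candidate$v
  y <- reference$v
  n <- length(y)
  A <- max(abs(y))
  stop_if(A == 0, "reference curve is identically zero")
  eps <- 1e-12 * A

  # corridor sub-rating
  if (is.null(corridor)) {
    mid <- y
    inner <- rep(0.05 * A, n)
    outer <- rep(0.50 * A, n)
  } else {
    stopifnot(inherits(corridor, "corridor"))
    stop_if(!same_grid(candidate, corridor), "corridor must share the grid")
    mid <- corridor$mean
    inner <- corridor$sd
    outer <- outer_k * corridor$sd
  }
  dev <- abs(x - mid)
  pt <- ifelse(dev <= inner + eps, 1,
               ifelse(dev >= outer, 0,
                      (outer - dev) / pmax(outer - inner, eps)))
  corr_score <- snap1(mean(pt))

  # lag scan for phase and shape
  L <- max(0L, floor(max_shift_frac * (n - 1)))
  best_s <- 0L
  best_rho <- -Inf
  for (s in seq.int(-L, L)) {
    if (s >= 0) {
      xa <- x[(1 + s):n]; ya <- y[1:(n - s)]
    } else {
      xa <- x[1:(n + s)]; ya <- y[(1 - s):n]
    }
    if (length(xa) < 3L) next
    sx <- stats::sd(xa); sy <- stats::sd(ya)
    rho <- if (sx < eps || sy < eps) {
      if (max(abs(xa - ya)) <= eps) 1 else 0
    } else {
      stats::cor(xa, ya)
    }
    if (rho > best_rho + 1e-15 || (abs(rho - best_rho) <= 1e-15 && abs(s) < abs(best_s))) {
      best_rho <- rho
      best_s <- s
    }
  }
  phase <- if (L == 0L) 1 else snap1(1 - abs(best_s) / L)
  shape <- snap1(if (is.finite(best_rho)) best_rho else 0)

  # size: absolute-area ratio
  ix <- trapz(candidate$t_ms, abs(x))
  iy <- trapz(reference$t_ms, abs(y))
  size <- if (max(ix, iy) == 0) 1 else snap1(min(ix, iy) / max(ix, iy))
  if (stats::sd(x) < eps && ix < eps) {
    shape <- 0
    phase <- 0
  }

  combined <- 0.5 * corr_score + 0.5 * mean(c(size, phase, shape))
  structure(list(corridor_score = corr_score, size = size, phase = phase,
                 shape = shape, combined = snap1(combined)),
            class = "rating_score")
}

#' @export
print.rating_score <- function(x, ...) {
  cat(sprintf("Biofidelity rating: combined = %.3f (corridor %.3f, size %.3f, phase %.3f, shape %.3f)\n",
              x$combined, x$corridor_score, x$size, x$phase, x$shape))
  invisible(x)
}

#' Percent-change table against a baseline case
#'
#' Tabulates `100 (case - baseline) / |baseline|` for the peak metrics of a
#' named set of [extract_peaks()] summaries, in the layout of a parametric
#' sweep report: rows `Linear Acc`, `Wy(p)` (positive angular-velocity peak)
#' and `Wy(n)` (negative peak), one column per case. The `Wy(n)` metric is
#' the magnitude of the negative peak, so a deeper extension peak counts as
#' an increase (the reporting convention of the experimental sweep tables).
#' Zero baseline metrics yield `NA` entries. Values are kept at full
#' precision; rounding is applied only when printing.
#'
#' @param cases named list of `peak_summary` objects.
#' @param baseline the baseline `peak_summary`.
#' @return a data frame of class `percent_change_table`.
#' @export
percent_change_table <- function(cases, baseline) {
  stopifnot(inherits(baseline, "peak_summary"))
  stop_if(is.null(names(cases)) || any(names(cases) == ""),
          "cases must be named")
  metric <- function(ps) c(`Linear Acc` = ps$lin_peak$value,
                           `Wy(p)` = ps$omega_pos_peak$value,
                           `Wy(n)` = abs(ps$omega_neg_peak$value))
  base <- metric(baseline)
  out <- vapply(cases, function(ps) {
    v <- metric(ps)
    ifelse(base == 0, NA_real_, 100 * (v - base) / abs(base))
  }, numeric(3))
  out <- as.data.frame(out)
  class(out) <- c("percent_change_table", class(out))
  out
}

#' @export
print.percent_change_table <- function(x, digits = 2, ...) {
  cat("Kinematics changes relative to baseline (%):\n")
  y <- as.data.frame(lapply(x, round, digits = digits))
  rownames(y) <- rownames(x)
  print.data.frame(y, ...)
  invisible(x)
}
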