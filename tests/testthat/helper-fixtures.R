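# Shared fixtures. Heavy simulations are computed once per test run and
# cached so that unit and acceptance tests reuse them.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

default_lib <- function() cached("lib", default_material_library())

baseline_result <- function() cached("baseline", simulate_impact(impact_config()))

low_drop_result <- function() {
  cached("low_drop", simulate_impact(impact_config(impactor_v0_ms = 4.54)))
}

angle_sweep <- function() cached("angle_sweep", sweep_helmet_angle(impact_config()))

stiffness_sweep <- function() {
  cached("stiffness_sweep", sweep_contact_stiffness(impact_config()))
}

# random admissible deformation gradient with J in [0.9, 1.1]
random_F <- function(spread = 0.05) {
  repeat {
    F <- diag(3) + matrix(stats::rnorm(9, 0, spread), 3, 3)
    if (det(F) > 0.1) break
  }
  Jt <- stats::runif(1, 0.9, 1.1)
  F * (Jt / det(F))^(1 / 3)
}

# random proper rotation matrix
random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# a smooth nonzero test curve for the rating metric
pulse_curve <- function(n = 201, t_end = 20) {
  t <- seq(0, t_end, length.out = n)
  time_series(t, exp(-((t - 6) / 2.5)^2) * 2.0, unit = "mm")
}
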