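# Internal helpers shared across modules.

# 1 psi in kPa; the suction experiments are specified in psi, everything else in SI.
PSI_KPA <- 6.894757

# standard gravity, m/s^2 (accelerations are reported in multiples of this)
G_STD <- 9.80665

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if <- function(cond, ...) if (isTRUE(cond)) stop(..., call. = FALSE)

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# trapezoidal integral of y over x
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

# cumulative trapezoid, same length as x, starting at 0
cumtrapz <- function(x, y) {
  n <- length(x)
  c(0, cumsum((y[-1] + y[-n]) * diff(x) / 2))
}

# Evaluate `expr` under a private RNG stream, restoring the caller's state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# check a numeric vector forms a strictly increasing uniform grid
is_uniform_grid <- function(t, rel_tol = 1e-8) {
  if (length(t) < 2L) return(TRUE)
  d <- diff(t)
  all(d > 0) && (max(d) - min(d)) <= rel_tol * max(abs(d))
}

# tiny deterministic FNV-1a hash of an R object, for provenance headers
config_hash <- function(x) {
  raw <- as.integer(serialize(x, connection = NULL, version = 3))
  h <- 5381
  for (b in raw) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

provenance_lines <- function(what, cfg = NULL) {
  v <- as.character(utils::packageVersion("headimpact"))
  c(sprintf("# headimpact %s :: %s", v, what),
    if (!is.null(cfg)) sprintf("# config-hash %s", config_hash(cfg)))
}
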