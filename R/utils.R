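# Internal helpers shared across modules.

# Evaluate `code` under a local RNG state seeded with `seed`, restoring the
# caller's state afterwards so generators behave as pure functions.
with_local_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Stationary unit-variance Ornstein-Uhlenbeck paths on a regular grid, as
# an n x m matrix (columns = independent factors). Exact discretisation
# x[t+1] = phi x[t] + sqrt(1-phi^2) eps, realised with a recursive filter;
# the first sample is drawn from the stationary law.
ou_paths <- function(n, m, dt, tau) {
  stopifnot(n >= 1, dt > 0, tau > 0)
  phi <- exp(-dt / tau)
  eps <- matrix(stats::rnorm(n * m), n, m)
  if (n > 1L) eps[-1, ] <- eps[-1, ] * sqrt(1 - phi^2)
  matrix(as.numeric(stats::filter(eps, phi, method = "recursive")), n, m)
}

ou_path <- function(n, dt, tau) ou_paths(n, 1L, dt, tau)[, 1]

# Gamma-density kernel normalised to peak 1, evaluated at times t >= 0.
# Used for pharmacokinetic-like drug-onset ramps.
gamma_onset <- function(t, shape = 3, scale = 120) {
  stopifnot(shape > 1, scale > 0)
  v <- stats::dgamma(t, shape = shape, scale = scale)
  mode_t <- (shape - 1) * scale
  v / stats::dgamma(mode_t, shape = shape, scale = scale)
}

# Trapezoidal integral with explicit x coordinates.
trapz_integral <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  if (sum(keep) < 2L) return(NA_real_)
  pracma::trapz(x[keep], y[keep])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
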