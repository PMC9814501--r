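# Shared fixtures: tiny model molecules built in code, and quadrature
# oracles kept independent of the closed forms they check.

# random all-coupled toy for Slater-Condon / matrix-element oracles
make_random_toy <- function(seed, m = 4, n_occupied = 2, lambda = 1) {
  set.seed(seed)
  v <- chargemig:::symmetrise_v8(array(stats::runif(m^4, -1, 1), rep(m, 4)))
  en <- sort(stats::runif(m, -20, -1))
  model_molecule(en, n_occupied = n_occupied, two_electron = v,
                 hole_index = 1, special_index = n_occupied + 1,
                 coupling_scale = lambda, validate = FALSE)
}

# weak-coupling shake-up toy with an absorbing special state: the
# Lorentzian-broadened golden rule is the exact weak-coupling decay rate
# when the absorber width is twice the broadening.
make_flux_toy <- function(seed, lambda = 0.04, eta = 0.2) {
  set.seed(seed)
  m <- 4
  v <- chargemig:::symmetrise_v8(array(stats::runif(m^4, 0.1, 1), rep(m, 4)))
  v <- chargemig:::damp_repeated_indices(v, 0.02)
  eh <- -20 + stats::runif(1, -0.3, 0.3)
  ea <- -3
  ed <- (eh + ea) / 2 + c(-0.15, 0.1) + stats::runif(2, -0.05, 0.05)
  mol <- model_molecule(c(eh, sort(ed), ea), n_occupied = 3, two_electron = v,
                        hole_index = 1, special_index = 4,
                        hole_weights = c(1, 0, 0), coupling_scale = lambda)
  mol$cap <- c(0, 0, 0, 2 * eta)
  mol
}

# bound shake-up toy (no absorber) for GKBA-vs-CI cross-method checks
make_shakeup_toy <- function(seed, lambda = 0.15) {
  set.seed(seed)
  m <- 3
  v <- chargemig:::symmetrise_v8(array(stats::runif(m^4, 0.1, 1), rep(m, 4)))
  v <- chargemig:::damp_repeated_indices(v, 0.1)
  model_molecule(c(-10, -6, -2), n_occupied = 2, two_electron = v,
                 hole_index = 1, special_index = 3,
                 hole_weights = c(1, 0), coupling_scale = lambda)
}

# half-filling noninteracting ground state of the Hubbard dimer
dimer_quench_state <- function() {
  structure(list(alpha = diag(c(1, 0) + 0i), beta = diag(c(1, 0) + 0i),
                 occupied_so = c(1L, 3L), hole = NA_integer_),
            class = "dm_state")
}

# brute-force numeric convolution of H(s) exp(-s/tau) with a Gaussian;
# the integrand mass sits within a few sigma of s = t, so finite limits
# keep integrate() from missing a displaced spike
quad_emg <- function(t, tau, sigma) {
  vapply(t, function(ti) {
    lo <- max(0, ti - 14 * sigma)
    hi <- ti + 14 * sigma
    if (hi <= lo) return(0)
    stats::integrate(function(s) exp(-s / tau) * stats::dnorm(ti - s, 0, sigma),
                     lower = lo, upper = hi, rel.tol = 1e-12)$value
  }, numeric(1))
}
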