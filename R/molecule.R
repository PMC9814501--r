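# Few-orbital model molecules standing in for ab-initio adenine.
#
# A model_molecule carries spatial-orbital energies (eV), a real 4-index
# two-electron integral table in the physicist convention <pq|v|rs> with the
# 8-fold permutational symmetry of real orbitals, dipole matrix elements
# (a.u.), a designated inner-valence hole orbital and a designated "special"
# shake-up virtual, XUV hole weights, and a global coupling scale lambda
# multiplying all two-electron integrals.
#
# Spin-orbital convention: closed-shell reference; spin-orbital i in
# 1..2M maps to spatial ((i - 1) %% M) + 1 and spin 1 (alpha, i <= M) or
# 2 (beta). Spin-orbital integrals are
# <PQ|v|RS> = v[p,q,r,s] * delta(sP,sR) * delta(sQ,sS).

# Symmetrise a 4-index array over the 8-element group valid for real
# orbitals in the physicist convention: particle exchange <pq|rs> = <qp|sr>,
# real hermiticity <pq|rs> = <rs|pq>, and bra-ket index swap within one
# particle <pq|rs> = <rq|ps>, closed under composition.
v8_group <- list(
  c(1, 2, 3, 4), c(2, 1, 4, 3), c(3, 4, 1, 2), c(4, 3, 2, 1),
  c(3, 2, 1, 4), c(1, 4, 3, 2), c(4, 1, 2, 3), c(2, 3, 4, 1)
)

symmetrise_v8 <- function(v) {
  Reduce(`+`, lapply(v8_group, function(p) aperm(v, p))) / 8
}

check_v8 <- function(v, tol = 1e-9) {
  max(abs(v - symmetrise_v8(v))) < tol
}

# scale all elements whose index 4-tuple has any repeated orbital; the
# condition is a multiset property, hence closed under the symmetry group
damp_repeated_indices <- function(v, factor) {
  s1 <- slice.index(v, 1); s2 <- slice.index(v, 2)
  s3 <- slice.index(v, 3); s4 <- slice.index(v, 4)
  distinct <- s1 != s2 & s1 != s3 & s1 != s4 & s2 != s3 & s2 != s4 & s3 != s4
  v[!distinct] <- v[!distinct] * factor
  v
}

#' Construct a few-orbital model molecule
#'
#' @param orbital_energies Spatial-orbital energies in eV, occupied block
#'   first (each ascending). All virtuals must be bound (negative energy)
#'   unless `validate = FALSE` (used internally for quasi-continuum
#'   extensions and toy fixtures).
#' @param n_occupied Number of occupied spatial orbitals (doubly occupied in
#'   the neutral).
#' @param two_electron 4-index array `v[p,q,r,s]` of `<pq|v|rs>` in eV,
#'   physicist convention, 8-fold symmetric. Stored unscaled; every consumer
#'   multiplies by `coupling_scale`.
#' @param dipole Array `c(M, M, 3)` of dipole matrix elements (a.u.),
#'   symmetric in the orbital pair.
#' @param hole_index Spatial index of the designated inner-valence hole.
#' @param special_index Spatial index of the designated special shake-up
#'   virtual (the LUMO+6 analogue).
#' @param hole_weights XUV ionisation probability per occupied spatial
#'   orbital; must sum to 1.
#' @param coupling_scale Dimensionless multiplier lambda on all two-electron
#'   integrals.
#' @param validate Check invariants (default `TRUE`).
#' @return An object of class `model_molecule`.
#' @export
model_molecule <- function(orbital_energies, n_occupied, two_electron,
                           dipole = NULL, hole_index = 1,
                           special_index = n_occupied + 1,
                           hole_weights = NULL, coupling_scale = 1,
                           validate = TRUE) {
  m <- length(orbital_energies)
  n_virtual <- m - n_occupied
  if (is.null(dipole)) dipole <- array(0, c(m, m, 3))
  if (is.null(hole_weights)) {
    hole_weights <- rep(0, n_occupied)
    hole_weights[hole_index] <- 1
  }
  mol <- structure(
    list(
      orbital_energies = orbital_energies,
      n_occupied = n_occupied,
      n_virtual = n_virtual,
      n_electrons = 2L * n_occupied,
      two_electron = two_electron,
      dipole = dipole,
      hole_index = as.integer(hole_index),
      special_index = as.integer(special_index),
      hole_weights = hole_weights,
      coupling_scale = coupling_scale
    ),
    class = "model_molecule"
  )
  if (validate) validate_molecule(mol)
  mol
}

validate_molecule <- function(mol) {
  m <- length(mol$orbital_energies)
  occ <- mol$orbital_energies[seq_len(mol$n_occupied)]
  vir <- mol$orbital_energies[mol$n_occupied + seq_len(mol$n_virtual)]
  if (is.unsorted(occ) || is.unsorted(vir))
    stop_invalid("orbital energies must ascend within the occupied and virtual blocks")
  if (mol$n_virtual > 0 && any(vir >= 0))
    stop_invalid("every virtual must be bound (negative energy)")
  if (abs(sum(mol$hole_weights) - 1) > 1e-9)
    stop_invalid("hole_weights must sum to 1")
  if (length(mol$hole_weights) != mol$n_occupied)
    stop_invalid("hole_weights must have one entry per occupied orbital")
  if (!all(dim(mol$two_electron) == m))
    stop_invalid("two_electron must be an M^4 array")
  if (!check_v8(mol$two_electron))
    stop_invalid("two_electron integrals violate the 8-fold real-orbital symmetry")
  if (mol$hole_index > mol$n_occupied)
    stop_invalid("hole_index must be occupied")
  if (mol$special_index <= mol$n_occupied || mol$special_index > m)
    stop_invalid("special_index must be a virtual")
  invisible(mol)
}

#' @export
print.model_molecule <- function(x, ...) {
  cat(sprintf(
    "<model_molecule> %d occupied + %d virtual spatial orbitals, lambda = %.5g\n",
    x$n_occupied, x$n_virtual, x$coupling_scale))
  cat(sprintf("  hole h* = orbital %d (%.2f eV), special a* = orbital %d (%.2f eV)\n",
              x$hole_index, x$orbital_energies[x$hole_index],
              x$special_index, x$orbital_energies[x$special_index]))
  invisible(x)
}

#' Tidy orbital table of a model molecule
#'
#' @param x A `model_molecule`.
#' @param ... Unused.
#' @return A tibble with one row per spatial orbital: index, energy (eV),
#'   block, hole/special flags, hole weight.
#' @method tidy model_molecule
#' @export
tidy.model_molecule <- function(x, ...) {
  m <- length(x$orbital_energies)
  tibble::tibble(
    orbital = seq_len(m),
    energy_ev = x$orbital_energies,
    block = rep(c("occupied", "virtual"), c(x$n_occupied, x$n_virtual)),
    is_hole = seq_len(m) == x$hole_index,
    is_special = seq_len(m) == x$special_index,
    hole_weight = c(x$hole_weights, rep(NA_real_, x$n_virtual))
  )
}

# ---- spin-orbital helpers -------------------------------------------------

n_spatial <- function(mol) length(mol$orbital_energies)
so_count <- function(mol) 2L * n_spatial(mol)
so_spatial <- function(mol, i) ((i - 1L) %% n_spatial(mol)) + 1L
so_spin <- function(mol, i) ((i - 1L) %/% n_spatial(mol)) + 1L
so_energy <- function(mol, i) mol$orbital_energies[so_spatial(mol, i)]

# effective (lambda-scaled) spin-orbital integral <PQ|v|RS>, vectorised over
# none; used by the Slater-Condon path where only a few elements are needed
so_integral <- function(mol, P, Q, R, S) {
  if (so_spin(mol, P) != so_spin(mol, R) || so_spin(mol, Q) != so_spin(mol, S))
    return(0)
  mol$coupling_scale * mol$two_electron[
    so_spatial(mol, P), so_spatial(mol, Q), so_spatial(mol, R), so_spatial(mol, S)]
}

# occupied spin-orbitals of the neutral closed shell
neutral_occupation <- function(mol) {
  m <- n_spatial(mol)
  c(seq_len(mol$n_occupied), m + seq_len(mol$n_occupied))
}

#' Rescale the two-electron coupling
#'
#' @param mol A `model_molecule`.
#' @param coupling_scale New lambda.
#' @return The molecule with `coupling_scale` replaced (integrals untouched).
#' @export
set_coupling_scale <- function(mol, coupling_scale) {
  mol$coupling_scale <- coupling_scale
  mol
}

# ---- generator ------------------------------------------------------------

#' Generate an adenine-like model molecule
#'
#' Builds a random few-orbital molecule emulating the electronic-structure
#' features the charge-migration analysis relies on: a single deep
#' inner-valence hole orbital (carrying the full XUV ionisation weight), a
#' valence block whose two-hole removal energies cover the shake-up
#' resonance window, bound virtuals inside that window, and one designated
#' special virtual whose binding energy sits strictly inside the
#' two-NIR-photon ionisation window. The two deepest valence orbitals are
#' placed so that their pair removal energy is resonant with refilling the
#' hole while promoting an electron to the special state (the model
#' analogue of the near-degenerate two-hole configurations that feed the
#' slow shake-up state); the special state's integrals are damped by
#' `special_coupling`, so after calibration it is the slow few-fs channel
#' while the other virtuals relax within a few hundred attoseconds.
#'
#' With `calibrate = TRUE` the global coupling lambda is adjusted (bisection
#' plus an exact quadratic-scaling polish, tolerance `calibrate_tol`) so the
#' golden-rule characteristic time of the special state equals `target_tau`.
#'
#' @param n_occupied Number of occupied spatial orbitals (`>= 3`).
#' @param n_virtual Number of bound virtual spatial orbitals (`>= 2`).
#' @param seed Integer seed; all randomness derives from it.
#' @param calibrate Calibrate lambda to `target_tau` (default `TRUE`).
#' @param target_tau Characteristic shake-up time of the special state, fs.
#'   Default 2.5 fs, the value reported for the special (LUMO+6-like) state.
#' @param special_binding Binding energy of the special virtual in eV;
#'   default 3.0 eV, strictly inside the two-photon window
#'   `(1.77, 3.54]` eV for 1.77 eV probe photons.
#' @param special_coupling Relative scale of integrals involving the special
#'   virtual (default 0.4; applied as an orbital factor so the 8-fold
#'   symmetry is preserved).
#' @param hartree_damp Relative scale of the density-density integral
#'   classes (default 0.1): their static mean-field shifts are treated as
#'   already absorbed in the effective orbital energies.
#' @param eta Lorentzian broadening (eV) used during calibration; see
#'   [fgr_options()].
#' @param calibrate_tol Calibration tolerance on the characteristic time, fs.
#' @return A `model_molecule`.
#' @export
#' @examples
#' mol <- make_adenine_like_molecule(seed = 1)
#' characteristic_times(mol)
make_adenine_like_molecule <- function(n_occupied = 5, n_virtual = 3,
                                       seed = 1, calibrate = TRUE,
                                       target_tau = 2.5,
                                       special_binding = 3.0,
                                       special_coupling = 0.4,
                                       hartree_damp = 0.1,
                                       eta = 0.2,
                                       calibrate_tol = 1e-3) {
  if (n_occupied < 3 || n_virtual < 2)
    stop_invalid("need n_occupied >= 3 and n_virtual >= 2")
  if (special_binding <= cm_constants$nir_photon_ev ||
      special_binding > 2 * cm_constants$nir_photon_ev)
    stop_invalid("special_binding must lie in the two-photon window (1.77, 3.54] eV")
  set.seed(seed)
  m <- n_occupied + n_virtual

  # one deep inner-valence hole near -20 eV; valence block above -12 eV so
  # the hole alone is "inner valence"
  e_hole <- -20 + stats::runif(1, -0.5, 0.5)
  e_special <- -special_binding
  # a group of three quasi-degenerate deep-valence orbitals whose pair
  # removal energies straddle the resonance for refilling the hole while
  # promoting an electron to the special state: this gives the special
  # state a small dense band of final configurations (irreversible,
  # golden-rule-like decay rather than a two-level recurrence)
  e_d0 <- (e_hole + e_special) / 2
  n_deep <- min(3L, n_occupied - 2L)
  # fixed offset pattern tiles the resonance band so the pair removal
  # energies sample the Lorentzian broadening evenly (clustering them at
  # exact resonance would make the broadened golden-rule sum overestimate
  # the dynamical decay rate)
  offsets <- c(-0.4, -0.1, 0.3)[seq_len(n_deep)]
  e_deep <- e_d0 + offsets / 2 + stats::runif(n_deep, -0.03, 0.03)
  # shallow valence orbitals anchored so that (deep, shallow) pair removal
  # energies are resonant with promotion to the non-special virtuals
  n_shallow <- n_occupied - 1L - n_deep
  b_anchor <- stats::runif(n_shallow, 0.7, 1.4)
  e_shallow <- e_hole - b_anchor - e_deep[1]
  e_val <- sort(c(e_deep, e_shallow))
  occ_e <- c(e_hole, e_val)

  # non-special virtuals on the resonances of (deep_k, shallow) pairs: all
  # of them have several open shake-up channels for every seed; jitter
  # keeps them off exact degeneracy
  deep_cycle <- rep(e_deep, length.out = max(n_virtual - 1, 1))
  shallow_cycle <- rep(e_shallow, length.out = max(n_virtual - 1, 1))
  vir_rest <- (deep_cycle + shallow_cycle)[seq_len(n_virtual - 1)] - e_hole +
    stats::rnorm(n_virtual - 1, 0, 0.05)
  vir_rest <- pmin(vir_rest, -0.4) # keep bound
  vir_e <- sort(c(e_special, vir_rest))
  energies <- c(occ_e, vir_e)
  special_index <- n_occupied + which(abs(vir_e - e_special) < 1e-12)[1]

  # two-electron integrals: positive random magnitudes ~0.1..1 eV,
  # 8-fold symmetrised; orbital factor damps couplings of the special state
  v <- array(stats::runif(m^4, 0.1, 1), rep(m, 4))
  v <- symmetrise_v8(v)
  s <- rep(1, m); s[special_index] <- special_coupling
  v <- v * outer(outer(s, s), outer(s, s)) # s_p s_q s_r s_s, keeps symmetry
  # suppress every element with a repeated orbital index (closed under the
  # 8-fold group): these carry the static Hartree/exchange shifts and
  # density-coupled one-body terms, which the model regards as already
  # absorbed in the effective orbital energies. Only all-distinct-index
  # "pure scattering" elements survive at full strength, so the engineered
  # Koopmans resonances stay resonant in the interacting dynamics.
  v <- damp_repeated_indices(v, hartree_damp)

  # dipoles: symmetric, z-dominant, modest
  dip <- array(0, c(m, m, 3))
  dz <- matrix(stats::rnorm(m * m, 0, 0.2), m)
  dip[, , 3] <- (dz + t(dz)) / 2

  # XUV hole weight: all on the single inner-valence orbital, so the
  # statistical golden-rule sum and the sudden-hole dynamics describe the
  # same initial condition
  w <- rep(0, n_occupied); w[1] <- 1

  mol <- model_molecule(
    orbital_energies = energies, n_occupied = n_occupied,
    two_electron = v, dipole = dip, hole_index = 1L,
    special_index = special_index, hole_weights = w, coupling_scale = 1
  )
  if (calibrate) {
    mol <- calibrate_special_state(mol, target_tau = target_tau, eta = eta,
                                   tol = calibrate_tol)
  }
  mol
}

#' Calibrate the coupling scale to a target shake-up time
#'
#' Adjusts `coupling_scale` so the golden-rule characteristic time of the
#' special virtual equals `target_tau`. A bisection on lambda brackets the
#' target; because the rate scales exactly as lambda^2, a final closed-form
#' polish `lambda <- lambda * sqrt(tau/target)` makes the calibration
#' idempotent to machine precision.
#'
#' @param mol A `model_molecule`.
#' @param target_tau Target characteristic time in fs.
#' @param eta Lorentzian broadening in eV.
#' @param tol Tolerance on the achieved time in fs.
#' @return The calibrated molecule.
#' @export
calibrate_special_state <- function(mol, target_tau = 2.5, eta = 0.2,
                                    tol = 1e-3) {
  opts <- fgr_options(broadening_eta = eta)
  tau_at <- function(lambda) {
    special_tau(set_coupling_scale(mol, lambda), opts)
  }
  if (!is.finite(tau_at(mol$coupling_scale)))
    cond_error("chargemig_calibration_error",
               "shake-up rate of the special state is identically zero; cannot calibrate")
  lo <- 1e-4; hi <- 1e4
  if (tau_at(lo) < target_tau || tau_at(hi) > target_tau)
    cond_error("chargemig_calibration_error", "target time outside bracket")
  for (it in 1:200) {
    mid <- sqrt(lo * hi)
    tm <- tau_at(mid)
    if (abs(tm - target_tau) < tol) break
    if (tm > target_tau) lo <- mid else hi <- mid
  }
  lambda <- sqrt(lo * hi)
  # exact polish: Gamma ~ lambda^2 => tau ~ 1/lambda^2
  lambda <- lambda * sqrt(tau_at(lambda) / target_tau)
  set_coupling_scale(mol, lambda)
}

special_tau <- function(mol, opts = fgr_options()) {
  tab <- characteristic_times(mol, opts)
  tab$tau_fs[tab$orbital == mol$special_index]
}

#' Hubbard-dimer test molecule
#'
#' Two-site Hubbard model (hopping `j_hop`, on-site repulsion `u`) expressed
#' in its bonding/antibonding molecular-orbital basis, where the on-site
#' interaction becomes `<pq|v|rs> = u/2` when the number of antibonding
#' labels is even and zero otherwise. `offset` shifts both orbital energies
#' (the physics is invariant; a negative offset keeps the antibonding level
#' formally bound).
#'
#' @param j_hop Hopping in eV (`> 0`); MO energies are `-j_hop`, `+j_hop`
#'   before the shift.
#' @param u On-site repulsion in eV.
#' @param offset Rigid energy shift in eV.
#' @return A `model_molecule` with 1 occupied + 1 virtual spatial orbital,
#'   half filling.
#' @export
hubbard_dimer_molecule <- function(j_hop = 1, u = 1, offset = -(j_hop + 1)) {
  v <- array(0, c(2, 2, 2, 2))
  for (p in 1:2) for (q in 1:2) for (r in 1:2) for (s in 1:2) {
    n_anti <- sum(c(p, q, r, s) == 2)
    if (n_anti %% 2 == 0) v[p, q, r, s] <- u / 2
  }
  model_molecule(
    orbital_energies = c(-j_hop + offset, j_hop + offset),
    n_occupied = 1L, two_electron = v,
    hole_index = 1L, special_index = 2L, hole_weights = 1,
    validate = FALSE
  )
}

# ---- JSON serialisation ---------------------------------------------------

#' Serialise / restore a model molecule as JSON
#'
#' @param mol A `model_molecule`.
#' @param path File path.
#' @return `write_molecule()` returns `path` invisibly; `read_molecule()` a
#'   `model_molecule`.
#' @export
write_molecule <- function(mol, path) {
  x <- unclass(mol)
  x$two_electron <- list(dim = dim(mol$two_electron),
                         values = as.vector(mol$two_electron))
  x$dipole <- list(dim = dim(mol$dipole), values = as.vector(mol$dipole))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_molecule
#' @export
read_molecule <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  model_molecule(
    orbital_energies = x$orbital_energies,
    n_occupied = x$n_occupied,
    two_electron = array(x$two_electron$values, x$two_electron$dim),
    dipole = array(x$dipole$values, x$dipole$dim),
    hole_index = x$hole_index,
    special_index = x$special_index,
    hole_weights = x$hole_weights,
    coupling_scale = x$coupling_scale,
    validate = FALSE
  )
}
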