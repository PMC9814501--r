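# Fermi's-golden-rule shake-up rates.
#
# After sudden XUV removal of an inner-valence electron h, the residual
# Coulomb interaction couples the one-hole cation determinant to
# two-hole-one-particle determinants in which the hole is refilled and a
# second electron is promoted to a bound virtual a (the shake-up state).
# Treating the Coulomb interaction as the perturbation and Koopmans
# energies in the energy-conserving delta (broadened to a Lorentzian of
# half-width eta), the rate into a given virtual is
#
#   Gamma(h -> a) = (2 pi / hbar) sum_{i<j} |<h a|v|i j> - <h a|v|j i>|^2
#                                  * delta_eta(e_i + e_j - e_h - e_a)
#
# summed over distinct occupied spin-orbital pairs of the cation and over
# the spin of the promoted electron. Hole channels are statistically summed
# with the XUV hole weights and the characteristic shake-up time is the
# inverse total rate.

#' Options for the golden-rule calculation
#'
#' @param broadening_eta Lorentzian half-width (eV) standing in for the
#'   energy-conserving delta function; must be positive. Default 0.2 eV.
#' @param pair_restriction `"distinct_pairs"` (sum over `i < j`, the
#'   declared convention) or `"all_ordered"` (sum over ordered pairs; twice
#'   the distinct-pair rate, provided for convention experiments).
#' @return A list of class `fgr_options`.
#' @export
fgr_options <- function(broadening_eta = 0.2,
                        pair_restriction = c("distinct_pairs", "all_ordered")) {
  if (broadening_eta <= 0) stop_invalid("broadening_eta must be > 0")
  structure(list(broadening_eta = broadening_eta,
                 pair_restriction = match.arg(pair_restriction)),
            class = "fgr_options")
}

lorentzian_delta <- function(x, eta) (eta / pi) / (x^2 + eta^2)

# Two-body matrix element between two determinants given as sorted
# spin-orbital occupation vectors, with the fermionic phase of the
# canonical (ascending) ordering. Only the cases needed here (identical or
# differing by exactly two spin-orbitals) are implemented.
slater_condon_two_body <- function(mol, occ_a, occ_b) {
  occ_a <- sort(occ_a); occ_b <- sort(occ_b)
  only_a <- setdiff(occ_a, occ_b)
  only_b <- setdiff(occ_b, occ_a)
  if (length(only_a) != 2 || length(only_b) != 2)
    stop_invalid("determinants must differ by exactly two spin-orbitals")
  m <- only_a[1]; n <- only_a[2]
  p <- only_b[1]; q <- only_b[2]
  phase <- (-1)^(match(m, occ_a) + match(n, occ_a) +
                 match(p, occ_b) + match(q, occ_b))
  phase * (so_integral(mol, m, n, p, q) - so_integral(mol, m, n, q, p))
}

#' Slater-Condon element of a shake-up transition
#'
#' Matrix element of the Coulomb interaction between the one-hole cation
#' determinant (hole in spin-orbital `h`) and the two-hole-one-particle
#' determinant in which `h` is refilled, `i` and `j` are emptied and the
#' virtual `a` is filled: `<a h|v|i j> - <a h|v|j i>` in the physicist
#' convention, including the fermionic phase of canonically ordered
#' determinants. Spin selection rules emerge from the spin-orbital
#' integrals; `i = j` gives zero by antisymmetry.
#'
#' @param mol A `model_molecule`.
#' @param h Spin-orbital index of the hole (occupied block).
#' @param i,j Occupied spin-orbital indices (`i != j`).
#' @param a Virtual spin-orbital index.
#' @return Matrix element in eV.
#' @export
slater_condon_element <- function(mol, h, i, j, a) {
  ms <- n_spatial(mol)
  occ_block <- function(k) so_spatial(mol, k) <= mol$n_occupied
  if (!occ_block(h) || !occ_block(i) || !occ_block(j))
    stop_invalid("h, i, j must be occupied spin-orbitals")
  if (occ_block(a)) stop_invalid("a must be a virtual spin-orbital")
  if (i == j) return(0)
  occ0 <- neutral_occupation(mol)
  occ_init <- setdiff(occ0, h)
  occ_fin <- sort(c(setdiff(occ_init, c(i, j)), h, a))
  slater_condon_two_body(mol, occ_fin, occ_init)
}

#' Golden-rule shake-up rate into one virtual
#'
#' @param mol A `model_molecule`.
#' @param hole Spatial index of the hole orbital (hole spin alpha by
#'   convention; rates are spin-symmetric).
#' @param virtual Spatial index of the target virtual.
#' @param opts An [fgr_options()].
#' @return Rate in 1/fs (promoted-electron spin summed).
#' @export
shakeup_rate <- function(mol, hole = mol$hole_index,
                         virtual = mol$special_index,
                         opts = fgr_options()) {
  if (hole > mol$n_occupied) stop_invalid("hole must be occupied")
  if (virtual <= mol$n_occupied) stop_invalid("virtual must be in the virtual block")
  eta <- opts$broadening_eta
  e <- mol$orbital_energies
  occ <- seq_len(mol$n_occupied)
  occ_nh <- setdiff(occ, hole) # alpha occupied of the cation
  vha <- mol$coupling_scale * mol$two_electron[hole, virtual, , ]
  de_pair <- outer(e[occ], e[occ], `+`) - e[hole] - e[virtual]
  gam_ev <- 0
  # same-spin (alpha,alpha) pairs, promoted electron alpha: antisymmetrised
  if (length(occ_nh) >= 2) {
    anti <- (vha[occ_nh, occ_nh] - t(vha[occ_nh, occ_nh]))^2 *
      lorentzian_delta(de_pair[occ_nh, occ_nh], eta)
    gam_ev <- gam_ev + sum(anti[upper.tri(anti)])
  }
  # opposite-spin pairs (p alpha refills the alpha hole, q beta promoted to
  # a beta): direct term only, all ordered (p, q) combinations are distinct
  # determinant pairs
  mix <- vha[occ_nh, occ, drop = FALSE]^2 *
    lorentzian_delta(de_pair[occ_nh, occ, drop = FALSE], eta)
  gam_ev <- gam_ev + sum(mix)
  if (opts$pair_restriction == "all_ordered") gam_ev <- 2 * gam_ev
  2 * pi / cm_constants$hbar_ev_fs * gam_ev # 1/fs
}

# reference implementation: explicit sum of Slater-Condon elements over
# distinct occupied spin-orbital pairs (used to validate the vectorised path)
shakeup_rate_sc <- function(mol, hole = mol$hole_index,
                            virtual = mol$special_index,
                            opts = fgr_options()) {
  ms <- n_spatial(mol)
  h_so <- hole
  occ_init <- setdiff(neutral_occupation(mol), h_so)
  eta <- opts$broadening_eta
  e_h <- mol$orbital_energies[hole]
  e_a <- mol$orbital_energies[virtual]
  gam_ev <- 0
  pairs <- utils::combn(occ_init, 2)
  for (a_so in c(virtual, ms + virtual)) {
    for (k in seq_len(ncol(pairs))) {
      i <- pairs[1, k]; j <- pairs[2, k]
      mel <- slater_condon_element(mol, h_so, i, j, a_so)
      if (mel == 0) next
      de <- so_energy(mol, i) + so_energy(mol, j) - e_h - e_a
      gam_ev <- gam_ev + mel^2 * lorentzian_delta(de, eta)
    }
  }
  if (opts$pair_restriction == "all_ordered") gam_ev <- 2 * gam_ev
  2 * pi / cm_constants$hbar_ev_fs * gam_ev
}

#' Characteristic shake-up times of all virtuals
#'
#' Statistically sums the golden-rule rates over the XUV hole channels with
#' the molecule's hole weights; the characteristic shake-up time of a
#' virtual is the inverse of its total rate (infinite where the rate
#' vanishes).
#'
#' @param mol A `model_molecule` (hole weights must sum to 1).
#' @param opts An [fgr_options()].
#' @return A tibble of class `shakeup_rates`, sorted by virtual energy, with
#'   columns `orbital`, `energy_ev`, `binding_ev`, `gamma_per_fs`, `tau_fs`,
#'   `photon_group`, `is_special`. The per-hole-channel breakdown is
#'   attached as `attr(, "by_hole")`.
#' @export
#' @examples
#' mol <- make_adenine_like_molecule(seed = 1)
#' characteristic_times(mol)
characteristic_times <- function(mol, opts = fgr_options()) {
  if (abs(sum(mol$hole_weights) - 1) > 1e-9)
    stop_invalid("hole_weights must sum to 1")
  virtuals <- mol$n_occupied + seq_len(mol$n_virtual)
  holes <- which(mol$hole_weights > 0)
  bh <- tidyr::expand_grid(orbital = virtuals, hole = holes)
  bh$weight <- mol$hole_weights[bh$hole]
  bh$gamma_per_fs <- purrr::map2_dbl(
    bh$hole, bh$orbital, function(h, a) shakeup_rate(mol, h, a, opts))
  tab <- bh |>
    dplyr::group_by(.data$orbital) |>
    dplyr::summarise(gamma_per_fs = sum(.data$weight * .data$gamma_per_fs),
                     .groups = "drop")
  tab$energy_ev <- mol$orbital_energies[tab$orbital]
  tab$binding_ev <- -tab$energy_ev
  tab$tau_fs <- ifelse(tab$gamma_per_fs > 0, 1 / tab$gamma_per_fs, Inf)
  tab$photon_group <- photon_group(tab$binding_ev)
  tab$is_special <- tab$orbital == mol$special_index
  tab <- tab[order(tab$energy_ev),
             c("orbital", "energy_ev", "binding_ev", "gamma_per_fs",
               "tau_fs", "photon_group", "is_special")]
  out <- tibble::new_tibble(tab, class = "shakeup_rates")
  attr(out, "by_hole") <- tibble::as_tibble(bh)
  out
}

#' Number of probe photons needed to ionise
#'
#' `ceiling(binding_energy / photon_energy)`, with exact integer multiples
#' (within 1e-9 eV) assigned to the lower group, so a binding energy of
#' exactly one photon needs one photon.
#'
#' @param binding_energy Binding energy (eV), positive; vectorised.
#' @param photon_energy Probe photon energy (eV), default 1.77 eV.
#' @return Integer photon group(s), `>= 1`.
#' @export
#' @examples
#' photon_group(c(1, 1.77, 3))
photon_group <- function(binding_energy, photon_energy = cm_constants$nir_photon_ev) {
  if (any(binding_energy <= 0) || photon_energy <= 0)
    stop_invalid("binding and photon energies must be positive")
  as.integer(ceiling((binding_energy - 1e-9) / photon_energy))
}
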