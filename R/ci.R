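# Exact configuration-interaction propagation in a fixed particle-number
# determinant basis. This is the validation oracle for the mean-field and
# GKBA propagators and for the golden-rule rates; it is only feasible for
# tiny molecules (Fock sector of at most 2^10 determinants).
#
# Spin-orbital index i in 1..2M; determinants are sorted integer vectors of
# occupied spin-orbitals with the canonical (ascending) fermionic ordering.

# spin-orbital one- and two-body tables (eV) for a molecule
so_tables <- function(mol) {
  m <- n_spatial(mol)
  n <- 2L * m
  e_so <- rep(mol$orbital_energies, 2)
  cap <- rep(mol$cap %||% rep(0, m), 2) # absorbing half-widths, eV
  # antisymmetrised <PQ||RS> = <PQ|RS> - <PQ|SR> with spin deltas
  v <- mol$coupling_scale * mol$two_electron
  sp <- function(i) ((i - 1L) %% m) + 1L
  sg <- function(i) ((i - 1L) %/% m) + 1L
  wso <- array(0, rep(n, 4))
  for (P in 1:n) for (Q in 1:n) for (R in 1:n) for (S in 1:n) {
    d1 <- if (sg(P) == sg(R) && sg(Q) == sg(S)) v[sp(P), sp(Q), sp(R), sp(S)] else 0
    d2 <- if (sg(P) == sg(S) && sg(Q) == sg(R)) v[sp(P), sp(Q), sp(S), sp(R)] else 0
    wso[P, Q, R, S] <- d1 - d2
  }
  dip <- matrix(0, n, n) # z-projection one-body dipole, a.u.
  dz <- mol$dipole[, , 3]
  dip[1:m, 1:m] <- dz
  dip[m + 1:m, m + 1:m] <- dz
  list(n_so = n, e_so = e_so, cap = cap, wso = wso, dipole = dip)
}

determinant_basis <- function(n_so, n_e) {
  if (choose(n_so, n_e) > 1024)
    cond_error("chargemig_capacity_error",
               "determinant basis exceeds 2^10 states")
  combs <- utils::combn(n_so, n_e)
  lapply(seq_len(ncol(combs)), function(i) combs[, i])
}

det_key <- function(d) paste(d, collapse = ",")

# Slater-Condon matrix elements of H0 = sum e_p n_p + (1/2) sum <PQ||RS>,
# and of a one-body operator, between canonical determinants.
ci_hamiltonian <- function(tables, basis) {
  nd <- length(basis)
  h <- matrix(0 + 0i, nd, nd)
  dmat <- matrix(0, nd, nd)
  e_c <- tables$e_so - 1i * tables$cap / 2
  w <- tables$wso
  dip <- tables$dipole
  for (a in seq_len(nd)) {
    da <- basis[[a]]
    pair_sum <- 0
    for (p in da) for (q in da) pair_sum <- pair_sum + w[p, q, p, q]
    h[a, a] <- sum(e_c[da]) + 0.5 * pair_sum
    dmat[a, a] <- sum(diag(dip)[da])
    if (a == nd) next
    for (b in (a + 1):nd) {
      db <- basis[[b]]
      only_a <- setdiff(da, db)
      nd_diff <- length(only_a)
      if (nd_diff > 2) next
      only_b <- setdiff(db, da)
      common <- intersect(da, db)
      if (nd_diff == 1) {
        m0 <- only_a; p0 <- only_b
        ph <- (-1)^(match(m0, da) + match(p0, db))
        two <- 0
        for (k in common) two <- two + w[m0, k, p0, k]
        el <- ph * two
        h[a, b] <- el; h[b, a] <- el
        dl <- ph * dip[m0, p0]
        dmat[a, b] <- dl; dmat[b, a] <- dl
      } else {
        m0 <- only_a[1]; n0 <- only_a[2]
        p0 <- only_b[1]; q0 <- only_b[2]
        ph <- (-1)^(match(m0, da) + match(n0, da) + match(p0, db) + match(q0, db))
        el <- ph * w[m0, n0, p0, q0]
        h[a, b] <- el; h[b, a] <- el
      }
    }
  }
  list(h0 = h, dipole = dmat)
}

# Brute-force second-quantised two-body matrix element
# <det_f| (1/2) sum w_pqrs c+_p c+_q c_s c_r |det_i>, built only from
# elementary creation/annihilation with bit-counting phases. Independent
# oracle for the Slater-Condon implementations.
second_quantised_element <- function(mol, det_f, det_i) {
  tables <- so_tables(mol)
  w <- tables$wso # antisymmetrised; (1/4) sum w<PQ||RS> c+p c+q cs cr
  n <- tables$n_so
  ann <- function(occ, p) {
    i <- match(p, occ)
    if (is.na(i)) return(NULL)
    list(occ = occ[-i], sign = (-1)^(i - 1))
  }
  cre <- function(occ, p) {
    if (p %in% occ) return(NULL)
    pos <- sum(occ < p)
    list(occ = sort(c(occ, p)), sign = (-1)^pos)
  }
  key_f <- det_key(sort(det_f))
  total <- 0
  occ0 <- sort(det_i)
  for (r in occ0) for (s in occ0) {
    if (r == s) next
    a1 <- ann(occ0, r); a2 <- ann(a1$occ, s)
    if (is.null(a2)) next
    for (p in 1:n) for (q in 1:n) {
      if (p == q) next
      if (w[p, q, r, s] == 0) next
      c1 <- cre(a2$occ, q)
      if (is.null(c1)) next
      c2 <- cre(c1$occ, p)
      if (is.null(c2)) next
      if (det_key(c2$occ) != key_f) next
      total <- total + 0.25 * w[p, q, r, s] * a1$sign * a2$sign * c1$sign * c2$sign
    }
  }
  total
}

# sparse one-body transition maps: for each (P,Q) the triplets
# (row = index of det with Q replaced by P, col = det index, sign)
ci_density_maps <- function(basis, n_so) {
  idx <- new.env(hash = TRUE)
  for (k in seq_along(basis)) assign(det_key(basis[[k]]), k, envir = idx)
  maps <- vector("list", n_so * n_so)
  for (P in 1:n_so) for (Q in 1:n_so) {
    rows <- integer(0); cols <- integer(0); signs <- numeric(0)
    for (k in seq_along(basis)) {
      occ <- basis[[k]]
      iq <- match(Q, occ)
      if (is.na(iq)) next
      s1 <- (-1)^(iq - 1)
      rest <- occ[-iq]
      if (P %in% rest) next
      pos <- sum(rest < P)
      newocc <- sort(c(rest, P))
      k2 <- get0(det_key(newocc), envir = idx)
      if (is.null(k2)) next
      rows <- c(rows, k2); cols <- c(cols, k); signs <- c(signs, s1 * (-1)^pos)
    }
    maps[[(P - 1) * n_so + Q]] <- list(rows = rows, cols = cols, signs = signs)
  }
  maps
}

ci_one_body_dm <- function(psi, maps, n_so) {
  rho <- matrix(0 + 0i, n_so, n_so)
  for (P in 1:n_so) for (Q in 1:n_so) {
    mp <- maps[[(P - 1) * n_so + Q]]
    if (!length(mp$rows)) next
    # <psi| c+_Q c_P |psi>: apply c+_P? use rho_PQ = <c+_Q c_P>
    # maps encode c+_P c_Q |det>; <c+_Q c_P> = conj(<c+_P c_Q>) -- fill both
    amp <- sum(Conj(psi[mp$rows]) * mp$signs * psi[mp$cols])
    rho[Q, P] <- rho[Q, P] + amp # <c+_P c_Q> contributes to rho_QP
  }
  rho
}

#' Sudden-ionisation initial state
#'
#' Removes one (alpha-spin) electron from occupied spatial orbital `h` of
#' the closed-shell neutral: the one-body density matrix is diagonal and
#' idempotent with `n_h(alpha) = 0`, all other occupied spin-orbitals 1,
#' virtuals 0; trace `N - 1`.
#'
#' @param mol A `model_molecule`.
#' @param h Occupied spatial orbital index of the hole (default the
#'   designated inner-valence hole).
#' @return A `dm_state`: spin blocks `alpha`, `beta` (complex M x M) plus
#'   the occupied spin-orbital list for the exact-CI representation.
#' @export
initial_state_sudden_hole <- function(mol, h = mol$hole_index) {
  if (h > mol$n_occupied) stop_invalid("hole must be an occupied orbital")
  m <- n_spatial(mol)
  occ <- rep(0, m); occ[seq_len(mol$n_occupied)] <- 1
  a <- occ; a[h] <- 0
  so_occ <- sort(c(which(a == 1), m + which(occ == 1)))
  structure(list(alpha = diag(a + 0i), beta = diag(occ + 0i),
                 occupied_so = so_occ, hole = h),
            class = "dm_state")
}

#' Exact-CI time propagation
#'
#' Full many-body propagation in the fixed particle-number determinant
#' basis: unitary stepping by exact exponentials of the (midpoint-sampled)
#' Hamiltonian. Norm is conserved to 1e-10 and field-free energy to 1e-9
#' per unit test; absorbing potentials (quasi-continuum extensions) make
#' the evolution contractive instead.
#'
#' @param mol A `model_molecule` with at most 5 spatial orbitals (the
#'   determinant sector must not exceed 2^10 states).
#' @param pulses A [laser_pulse()], list of pulses, or `NULL`.
#' @param grid A [propagation_grid()].
#' @param state0 A `dm_state` from [initial_state_sudden_hole()] (a single
#'   determinant) or a complex CI vector in the basis of this sector.
#' @param n_electrons Electron count of the sector (default: from
#'   `state0`).
#' @return A `dm_trajectory` (see [tidy.dm_trajectory()]).
#' @export
propagate_exact_ci <- function(mol, pulses = NULL, grid = propagation_grid(),
                               state0, n_electrons = NULL) {
  tables <- so_tables(mol)
  n_so <- tables$n_so
  if (inherits(state0, "dm_state")) {
    n_e <- length(state0$occupied_so)
  } else n_e <- n_electrons %||% stop_invalid("n_electrons needed for raw CI vectors")
  basis <- determinant_basis(n_so, n_e)
  ham <- ci_hamiltonian(tables, basis)
  maps <- ci_density_maps(basis, n_so)
  nd <- length(basis)
  psi <- if (inherits(state0, "dm_state")) {
    v <- rep(0 + 0i, nd)
    key0 <- det_key(as.integer(sort(state0$occupied_so)))
    k <- which(vapply(basis, function(b) det_key(b) == key0, logical(1)))
    if (!length(k)) stop_invalid("initial determinant not in basis")
    v[k] <- 1
    v
  } else as.complex(state0)

  pulses <- normalise_pulses(pulses)
  times <- seq(grid$t_start, grid$t_end, by = grid$dt)
  hbar <- cm_constants$hbar_ev_fs
  field_free <- length(pulses) == 0 ||
    all(vapply(pulses, function(p) p$peak_intensity == 0, logical(1)))

  step_with <- function(hmat, dt) {
    # eigen stepping; hmat may be complex non-hermitian with CAP
    if (max(abs(hmat - Conj(t(hmat)))) < 1e-12) {
      es <- eigen(hmat, symmetric = TRUE)
      es$vectors %*% (exp(-1i * es$values * dt / hbar) *
                        (Conj(t(es$vectors)) %*% psi))
    } else {
      es <- eigen(hmat)
      vi <- solve(es$vectors)
      es$vectors %*% (exp(-1i * es$values * dt / hbar) * (vi %*% psi))
    }
  }

  nt <- length(times)
  occ <- matrix(NA_real_, nt, n_so)
  rho_list <- vector("list", nt)
  store <- function(i) {
    rho <- ci_one_body_dm(psi, maps, n_so)
    occ[i, ] <<- Re(diag(rho))
    rho_list[[i]] <<- rho
  }
  store(1)
  if (field_free) {
    es <- eigen(ham$h0)
    vi <- solve(es$vectors)
    coef0 <- vi %*% psi
    for (i in 2:nt) {
      psi <- es$vectors %*% (exp(-1i * es$values * (times[i] - times[1]) / hbar) * coef0)
      store(i)
    }
  } else {
    ev_per_au <- cm_constants$hartree_ev
    for (i in 2:nt) {
      tm <- (times[i - 1] + times[i]) / 2
      ef <- sum(vapply(pulses, function(p) field_at(p, tm), numeric(1)))
      hmat <- ham$h0 - ef * ham$dipole * ev_per_au
      psi <- step_with(hmat, grid$dt)
      store(i)
    }
  }
  if (any(!is.finite(occ)))
    cond_error("chargemig_propagation_error", "NaN encountered in CI propagation")
  new_dm_trajectory(mol, times, occ, rho_list, method = "exact_ci",
                    extra = list(norm = sqrt(sum(Mod(psi)^2))))
}
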