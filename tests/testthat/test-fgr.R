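test_that("Slater-Condon elements match the second-quantised oracle", {
  for (sd in 1:5) {
    mol <- make_random_toy(sd, m = 4, n_occupied = 2)
    occ0 <- chargemig:::neutral_occupation(mol) # spin-orbitals 1,2,5,6
    ms <- chargemig:::n_spatial(mol)
    h <- 1 # alpha hole
    occ_init <- setdiff(occ0, h)
    virt_so <- c(3, 4, ms + 3, ms + 4)
    pairs <- utils::combn(occ_init, 2)
    for (a in virt_so) {
      for (k in seq_len(ncol(pairs))) {
        i <- pairs[1, k]; j <- pairs[2, k]
        sc <- slater_condon_element(mol, h, i, j, a)
        det_i <- occ_init
        det_f <- sort(c(setdiff(occ_init, c(i, j)), h, a))
        bf <- chargemig:::second_quantised_element(mol, det_f, det_i)
        expect_equal(sc, bf, tolerance = 1e-12)
      }
    }
  }
})

test_that("Slater-Condon degenerate cases vanish", {
  mol <- make_random_toy(1, m = 4, n_occupied = 2)
  expect_equal(slater_condon_element(mol, 1, 2, 2, 3), 0)
  zero <- mol
  zero$two_electron <- array(0, dim(mol$two_electron))
  expect_equal(slater_condon_element(zero, 1, 2, 6, 3), 0)
  expect_error(slater_condon_element(mol, 3, 2, 6, 4),
               class = "chargemig_invalid") # h must be occupied
})

test_that("rates vanish without coupling and scale quadratically", {
  mol <- make_adenine_like_molecule(seed = 1, calibrate = FALSE)
  g0 <- shakeup_rate(set_coupling_scale(mol, 0))
  expect_equal(g0, 0)
  tab0 <- characteristic_times(set_coupling_scale(mol, 0))
  expect_true(all(is.infinite(tab0$tau_fs)))

  g1 <- shakeup_rate(mol)
  g2 <- shakeup_rate(set_coupling_scale(mol, 2 * mol$coupling_scale))
  expect_equal(g2 / g1, 4, tolerance = 1e-12)
})

test_that("vectorised rate equals the explicit Slater-Condon sum", {
  mol <- make_adenine_like_molecule(seed = 2, calibrate = FALSE)
  for (h in c(1, 2)) for (a in (mol$n_occupied + 1):chargemig:::n_spatial(mol)) {
    expect_equal(shakeup_rate(mol, h, a),
                 chargemig:::shakeup_rate_sc(mol, h, a), tolerance = 1e-12)
  }
  # ordered-pair convention doubles the distinct-pair rate
  expect_equal(shakeup_rate(mol, opts = fgr_options(pair_restriction = "all_ordered")),
               2 * shakeup_rate(mol), tolerance = 1e-12)
})

test_that("rates are invariant under relabeling degenerate orbitals", {
  mol <- make_random_toy(3, m = 4, n_occupied = 2)
  mol$orbital_energies <- c(-20, -20, -5, -2) # degenerate occupied pair
  g_before <- shakeup_rate(mol, hole = 1, virtual = 4)
  # swap the two degenerate occupied orbitals everywhere
  perm <- c(2, 1, 3, 4)
  mol2 <- mol
  mol2$two_electron <- mol$two_electron[perm, perm, perm, perm]
  mol2$orbital_energies <- mol$orbital_energies[perm]
  g_after <- shakeup_rate(mol2, hole = 2, virtual = 4)
  expect_equal(g_before, g_after, tolerance = 1e-12)
})

test_that("characteristic times table is sound", {
  mol <- make_adenine_like_molecule(seed = 1)
  tab <- characteristic_times(mol)
  expect_s3_class(tab, "shakeup_rates")
  expect_false(is.unsorted(tab$energy_ev))
  expect_true(all(tab$gamma_per_fs >= 0))
  ok <- tab$gamma_per_fs > 0
  expect_equal(tab$tau_fs[ok] * tab$gamma_per_fs[ok], rep(1, sum(ok)))
  expect_true(all(tab$photon_group >= 1))
  # single weighted hole: table equals the single-channel rate
  expect_equal(tab$gamma_per_fs[tab$is_special],
               shakeup_rate(mol), tolerance = 1e-12)
  by_hole <- attr(tab, "by_hole")
  expect_true(all(c("orbital", "hole", "weight", "gamma_per_fs") %in%
                    names(by_hole)))
  bad <- mol; bad$hole_weights <- bad$hole_weights * 0.5
  expect_error(characteristic_times(bad), class = "chargemig_invalid")
})

test_that("non-special virtuals of the default molecule relax within 1 fs", {
  tab <- characteristic_times(make_adenine_like_molecule(seed = 1))
  expect_true(all(tab$tau_fs[!tab$is_special] < 1))
  expect_equal(max(tab$tau_fs), tab$tau_fs[tab$is_special])
})

test_that("photon grouping follows the ceiling rule with boundary to lower", {
  expect_identical(photon_group(1.0), 1L)
  expect_identical(photon_group(3.0), 2L)
  expect_identical(photon_group(1.77), 1L)   # exact multiple: lower group
  expect_identical(photon_group(2 * 1.77), 2L)
  expect_identical(photon_group(c(0.5, 2, 4.5)), c(1L, 2L, 3L))
  expect_error(photon_group(-1), class = "chargemig_invalid")
  expect_error(photon_group(1, photon_energy = 0), class = "chargemig_invalid")
})

test_that("calibration succeeds across the broadening sweep", {
  mol <- make_adenine_like_molecule(seed = 1)
  for (eta in c(0.1, 0.2, 0.3, 0.4)) {
    recal <- calibrate_special_state(mol, target_tau = 2.5, eta = eta)
    tau <- chargemig:::special_tau(recal, fgr_options(broadening_eta = eta))
    expect_lt(abs(tau - 2.5) / 2.5, 0.15)
  }
})

test_that("golden-rule rates match exact-CI decay in the validity regime", {
  # weak coupling, absorbing special state of width 2*eta: the broadened
  # golden rule is the exact weak-coupling limit; survival is the decayed
  # norm of the many-body state
  ratios <- vapply(1:20, function(sd) {
    mol <- make_flux_toy(sd)
    gam <- shakeup_rate(mol, opts = fgr_options(broadening_eta = 0.2))
    st <- initial_state_sudden_hole(mol)
    ci <- propagate_exact_ci(mol, NULL, propagation_grid(0, 16, dt = 0.25), st)
    surv <- ci$n_particles / ci$n_particles[1]
    sel <- ci$times >= 6
    slope <- -stats::coef(stats::lm(log(surv[sel]) ~ ci$times[sel]))[[2]]
    gam / slope
  }, numeric(1))
  expect_true(all(abs(ratios - 1) < 0.2))
})
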