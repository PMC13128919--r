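test_that("s-only systems reproduce the conventional reference exactly", {
  st <- scf_solve(make_named_small("H2"), screening = no_screening())
  expect_true(st$converged)
  expect_equal(st$E_total, oracle$h2$E, tolerance = 1e-9)
  expect_equal(st$E_nuc, oracle$h2$E_nuc, tolerance = 1e-10)
  expect_equal(st$eps, oracle$h2$eps, tolerance = 1e-7)
  he <- scf_solve(make_named_small("He"), screening = no_screening())
  expect_equal(he$E_total, oracle$he$E, tolerance = 1e-9)
  h4 <- scf_solve(make_h_chain(4, oracle$h4$spacing_bohr),
                  screening = no_screening())
  expect_equal(h4$E_total, oracle$h4$E, tolerance = 1e-8)
})

test_that("water agrees with the conventional basis within the lobe budget", {
  st <- scf_solve(make_named_small("H2O"), screening = no_screening())
  expect_true(st$converged)
  expect_lt(abs(st$E_total - oracle$h2o$E), 5e-3)
  ## orbital energies carry the same budget
  expect_lt(orbital_energy_rmsd(st, oracle$h2o$eps), 5e-3)
})

test_that("converged states satisfy the SCF invariants", {
  st <- scf_solve(make_named_small("H2O"), screening = no_screening())
  expect_equal(sum(st$P * st$S), 10, tolerance = 1e-6)
  for (M in list(st$S, st$H, st$F, st$G, st$P)) {
    expect_lt(max(abs(M - t(M))), 1e-10)
  }
  ## idempotency P S P = 2 P
  expect_lt(max(abs(st$P %*% st$S %*% st$P - 2 * st$P)), 1e-5)
  ## commutation at convergence
  expect_lt(max(abs(st$F %*% st$P %*% st$S - st$S %*% st$P %*% st$F)), 1e-4)
  expect_error(scf_solve(molecular_system("H", matrix(0, 1, 3))),
               "odd electron")
})

test_that("energies are invariant under rigid rotation with co-rotated lobes", {
  w <- make_named_small("H2O")
  E0 <- scf_solve(w, screening = no_screening())$E_total
  th <- 0.7; ph <- 0.3
  Rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
               byrow = TRUE)
  Rx <- matrix(c(1, 0, 0, 0, cos(ph), -sin(ph), 0, sin(ph), cos(ph)), 3, 3,
               byrow = TRUE)
  R <- Rz %*% Rx
  wr <- set_positions(w, positions(w) %*% t(R))
  b <- build_basis(wr, axes = t(R))
  Er <- scf_solve(wr, basis = b, screening = no_screening())$E_total
  expect_equal(Er, E0, tolerance = 1e-8)
  ## translation invariance needs no axis bookkeeping
  wt <- set_positions(w, positions(w) + 5)
  expect_equal(scf_solve(wt, screening = no_screening())$E_total, E0,
               tolerance = 1e-9)
})

test_that("nuclear repulsion honors the smooth cut-off window", {
  h2 <- make_named_small("H2")
  expect_equal(nuclear_repulsion(h2, no_screening()), 1 / 1.4,
               tolerance = 1e-10)
  far <- molecular_system(c("H", "H"), rbind(c(0, 0, 0), c(12, 0, 0)))
  cfg <- screening_config(coulomb_lower_A = 8, coulomb_upper_A = 10)
  expect_equal(nuclear_repulsion(far, cfg), 0)
  mid <- molecular_system(c("H", "H"), rbind(c(0, 0, 0), c(9, 0, 0)))
  expect_equal(nuclear_repulsion(mid, cfg),
               0.5 / ang_to_bohr(9), tolerance = 1e-10)
  clash <- molecular_system(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 0)))
  expect_error(nuclear_repulsion(clash), "coincident")
})

test_that("the Fock assembly equals a dense reference contraction", {
  b <- build_basis(make_named_small("H2O"))
  tasks <- build_task_list(b, no_screening())
  eri <- compute_eris(tasks)
  one <- one_electron_matrices(b)
  ## P = 0 gives F = H
  z <- matrix(0, 7, 7)
  expect_equal(build_fock(z, one$H, tasks, eri)$F, one$H)
  ## dense 4-index tensor from the canonical list, then a brute-force
  ## double loop - the reference for the permutation bookkeeping
  n <- 7
  tens <- array(0, c(n, n, n, n))
  for (q in seq_along(eri)) {
    i <- tasks$fi[q]; j <- tasks$fj[q]; k <- tasks$fk[q]; l <- tasks$fl[q]
    for (p_ in list(c(i, j, k, l), c(j, i, k, l), c(i, j, l, k),
                    c(j, i, l, k), c(k, l, i, j), c(l, k, i, j),
                    c(k, l, j, i), c(l, k, j, i))) {
      tens[p_[1], p_[2], p_[3], p_[4]] <- eri[q]
    }
  }
  set.seed(42)
  A <- matrix(rnorm(n * n), n); P <- A + t(A)
  Gref <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    Gref[i, j] <- sum(P * (tens[i, j, , ] - 0.5 * tens[i, , j, ]))
  }
  expect_equal(build_fock(P, one$H, tasks, eri)$G, Gref, tolerance = 1e-12)
})

test_that("orbital-energy RMSD selects valence plus low virtual orbitals", {
  st <- scf_solve(make_named_small("H2O"), screening = no_screening())
  expect_equal(orbital_energy_rmsd(st, st$eps), 0)
  shifted <- st$eps + 0.001
  expect_equal(orbital_energy_rmsd(st, shifted), 0.001, tolerance = 1e-10)
})
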