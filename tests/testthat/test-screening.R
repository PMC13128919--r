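test_that("density relevance behaves like an absolute-overlap integral", {
  b <- build_basis(make_h_chain(2, spacing_bohr = ang_to_bohr(1) * 20))
  R <- relevance_matrix(b)
  ## normalized s function with itself integrates to ~1
  expect_equal(R[1, 1], 1, tolerance = 1e-6)
  ## two 1s functions 20 bohr apart are irrelevant
  b2 <- build_basis(make_h_chain(2, spacing_bohr = 20))
  expect_lt(relevance_matrix(b2)[1, 2], 1e-10)
  ## self-pairs always survive any sensible threshold
  bw <- build_basis(make_named_small("H2O"))
  expect_true(all(diag(relevance_matrix(bw)) > 0.9))
})

test_that("p-function self-relevance matches an independent evaluation", {
  bc <- build_basis(molecular_system("C", matrix(0, 1, 3)))
  R <- relevance_matrix(bc)
  ## independent oracle: the same quadratic-form integrals evaluated in
  ## plain R linear algebra (the engine uses packed 3x3 kernels in C++)
  ref_rel <- function(i, j) {
    idx_i <- (bc$rel_ptr[i] + 1):bc$rel_ptr[i + 1]
    idx_j <- (bc$rel_ptr[j] + 1):bc$rel_ptr[j + 1]
    unpackM <- function(a) {
      matrix(c(bc$rel_M[a, 1], bc$rel_M[a, 4], bc$rel_M[a, 5],
               bc$rel_M[a, 4], bc$rel_M[a, 2], bc$rel_M[a, 6],
               bc$rel_M[a, 5], bc$rel_M[a, 6], bc$rel_M[a, 3]), 3, 3)
    }
    acc <- 0
    for (a in idx_i) for (b in idx_j) {
      M1 <- unpackM(a); M2 <- unpackM(b)
      d <- bc$rel_center[a, ] - bc$rel_center[b, ]
      S <- M1 + M2
      quad <- drop(t(d) %*% M1 %*% solve(S) %*% M2 %*% d)
      acc <- acc + bc$rel_A[a] * bc$rel_A[b] *
        pi^1.5 / sqrt(det(S)) * exp(-quad)
    }
    acc
  }
  expect_equal(R[3, 3], ref_rel(3, 3), tolerance = 1e-10)
  expect_equal(R[1, 3], ref_rel(1, 3), tolerance = 1e-10)
  ## fit quality: the self-relevance approximates int |p|^2 = 1
  expect_equal(R[3, 3], 1, tolerance = 0.07)
})

test_that("coulomb distance is the midpoint distance in Angstrom", {
  p1 <- list(atoms = rbind(c(0, 0, 0), c(0, 0, 0)))
  p2 <- list(atoms = rbind(c(3, 4, 0), c(3, 4, 0)))
  expect_equal(coulomb_distance(p1, p1), 0)
  expect_equal(coulomb_distance(p1, p2), 5)
  expect_equal(coulomb_distance(p2, p1), 5)
  p3 <- list(atoms = rbind(c(0, 0, 0), c(6, 8, 0)))
  expect_equal(coulomb_distance(p1, p3), 5)
})

test_that("the switching function is a C1 bump from 1 to 0", {
  expect_equal(smooth_cutoff(8, 8, 10), 1)
  expect_equal(smooth_cutoff(10, 8, 10), 0)
  expect_equal(smooth_cutoff(9, 8, 10), 0.5)
  expect_equal(smooth_cutoff(c(0, 20), 8, 10), c(1, 0))
  h <- 1e-6
  expect_lt(abs(smooth_cutoff(8 + h, 8, 10) - smooth_cutoff(8, 8, 10)) / h,
            1e-4)
  expect_lt(abs(smooth_cutoff(10, 8, 10) - smooth_cutoff(10 - h, 8, 10)) / h,
            1e-4)
  x <- seq(8, 10, length.out = 100)
  expect_true(all(diff(smooth_cutoff(x, 8, 10)) <= 0))
})

test_that("task lists match brute force and are monotone in thresholds", {
  b <- build_basis(make_named_small("H2O"))
  ## no screening: exactly the unique-ERI count
  t0 <- build_task_list(b, no_screening())
  expect_equal(length(t0$p1), count_unique_eris(7))
  ## screened list equals the brute-force filter
  cfg <- screening_config(density_cutoff = 1e-4, coulomb_lower_A = 8,
                          coulomb_upper_A = 10)
  tk <- build_task_list(b, cfg)
  bf <- brute_force_tasks(b, cfg)
  made <- paste(tk$fi, tk$fj, tk$fk, tk$fl)
  ref <- paste(bf[, 1], bf[, 2], bf[, 3], bf[, 4])
  expect_setequal(made, ref)
  expect_equal(length(made), length(unique(made)))  # canonical dedup
  ## a larger mixed system, still within the brute-force regime
  bd <- build_basis(make_water_cluster(2, seed = 4))
  cfg2 <- screening_config(density_cutoff = 1e-3, coulomb_lower_A = 2,
                           coulomb_upper_A = 3)
  tk2 <- build_task_list(bd, cfg2)
  bf2 <- brute_force_tasks(bd, cfg2)
  expect_setequal(paste(tk2$fi, tk2$fj, tk2$fk, tk2$fl),
                  paste(bf2[, 1], bf2[, 2], bf2[, 3], bf2[, 4]))
  ## monotonicity: loosening a threshold never removes a task
  tk_loose <- build_task_list(bd, screening_config(density_cutoff = 1e-6,
                                                   coulomb_lower_A = 2,
                                                   coulomb_upper_A = 3))
  expect_true(all(paste(tk2$fi, tk2$fj, tk2$fk, tk2$fl) %in%
                    paste(tk_loose$fi, tk_loose$fj, tk_loose$fk,
                          tk_loose$fl)))
  ## weights are 1 inside the lower radius and in (0,1] elsewhere
  expect_true(all(tk2$w > 0 & tk2$w <= 1))
})

test_that("screened energies approach the unscreened limit monotonically", {
  trimer <- make_water_cluster(3, seed = 21)
  b <- build_basis(trimer)
  E0 <- scf_solve(trimer, basis = b, screening = no_screening())$E_total
  errs <- vapply(c(1e-3, 1e-4, 1e-6, 1e-8), function(tau) {
    cfg <- screening_config(density_cutoff = tau, coulomb_lower_A = 1e9,
                            coulomb_upper_A = Inf)
    abs(scf_solve(trimer, basis = b, screening = cfg)$E_total - E0)
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-12))
  expect_lt(errs[4], 1e-8)
})
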