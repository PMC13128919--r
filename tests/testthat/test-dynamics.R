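test_that("analytic gradients match central finite differences", {
  ## the defining contract: derivative of the implemented energy
  w <- make_named_small("H2O")
  scr <- no_screening()
  tight <- scf_config(rmsd_threshold = 1e-9)
  st <- scf_solve(w, screening = scr, scf = tight)
  g <- gradient(st)$gradient
  g_fd <- fd_gradient(w, scr, tight, step_bohr = 1e-4)
  expect_lt(max(abs(g - g_fd)), 1e-5)
  ## net force and net torque vanish on any geometry
  f <- gradient(st)$forces
  expect_lt(max(abs(colSums(f))), 1e-8)
  pos <- positions(w, "bohr")
  torque <- colSums(cbind(pos[, 2] * f[, 3] - pos[, 3] * f[, 2],
                          pos[, 3] * f[, 1] - pos[, 1] * f[, 3],
                          pos[, 1] * f[, 2] - pos[, 2] * f[, 1]))
  expect_lt(max(abs(torque)), 1e-8)
})

test_that("gradients differentiate the smooth cut-off region too", {
  ## two waters with the switching window cutting through their distance
  w <- make_named_small("H2O")
  p <- positions(w)
  dimer <- molecular_system(rep(w$atoms$element, 2),
                            rbind(p, sweep(p, 2, c(4.2, 0, 0), `+`)))
  scr <- screening_config(density_cutoff = 1e-6, coulomb_lower_A = 2.5,
                          coulomb_upper_A = 7)
  tight <- scf_config(rmsd_threshold = 1e-9)
  st <- scf_solve(dimer, screening = scr, scf = tight)
  g <- gradient(st)$gradient
  g_fd <- fd_gradient(dimer, scr, tight, step_bohr = 1e-4)
  expect_lt(max(abs(g - g_fd)), 1e-5)
})

test_that("well-separated cut-off radii keep switching forces bounded", {
  ## two-charge model: with r_cu >= 2.5 r_cl the force inside the window
  ## never exceeds the force just below the lower radius
  cfg <- screening_config(coulomb_lower_A = 3, coulomb_upper_A = 8)
  force_at <- function(d_A) {
    s <- molecular_system(c("H", "H"), rbind(c(0, 0, 0), c(d_A, 0, 0)))
    abs(lobehf:::.nuclear_gradient(s, cfg)[1, 1])
  }
  f_below <- force_at(2.99)
  window <- vapply(seq(3.05, 7.95, by = 0.1), force_at, numeric(1))
  expect_true(all(window <= f_below))
})

test_that("golden-section line search solves a quadratic quickly", {
  f <- function(t) (t - 0.3)^2 + 1
  expect_equal(golden_section(f, 1), 0.3, tolerance = 0.01)
  ## non-finite values shrink the interval instead of failing
  g <- function(t) if (t > 0.5) Inf else (t - 0.2)^2
  expect_equal(golden_section(g, 1), 0.2, tolerance = 0.02)
})

test_that("BFGS finds the H2 minimum-energy bond length", {
  h2 <- molecular_system(c("H", "H"),
                         rbind(c(0, 0, 0), c(0, 0, bohr_to_ang(1.6))))
  opt <- bfgs_optimize(h2, screening = no_screening(),
                       scf = scf_config(rmsd_threshold = 1e-8),
                       max_steps = 15, rms_threshold = 1e-5)
  r <- sqrt(sum(diff(positions(opt$system, "bohr"))^2))
  expect_lt(abs(bohr_to_ang(r) - bohr_to_ang(oracle$h2_eq_bohr)), 0.01)
  ## RMS force decreases by at least an order of magnitude
  expect_lt(tail(opt$log$rms_force, 1), opt$log$rms_force[1] / 10)
  ## at the optimum the residual force is small
  expect_lt(tail(opt$log$rms_force, 1), 1e-4)
})

test_that("MD conserves a stationary state and oscillates harmonically", {
  ## equilibrium H2 at rest stays put
  h2eq <- molecular_system(c("H", "H"),
                           rbind(c(0, 0, 0),
                                 c(0, 0, bohr_to_ang(oracle$h2_eq_bohr))))
  traj <- md_run(h2eq, dt_fs = 0.2, n_steps = 20, init_temperature_K = 0,
                 screening = no_screening())
  disp <- max(abs(traj$frames[[length(traj$frames)]]$xyz -
                    traj$frames[[1]]$xyz))
  expect_lt(disp, 1e-5)

  ## small stretch: period matches the harmonic estimate from the
  ## finite-difference Hessian of the gradient
  h <- 1e-3
  gr_at <- function(rb) {
    s <- molecular_system(c("H", "H"),
                          rbind(c(0, 0, 0), c(0, 0, bohr_to_ang(rb))))
    st <- scf_solve(s, screening = no_screening(),
                    scf = scf_config(rmsd_threshold = 1e-9))
    gradient(st)$gradient[2, 3]
  }
  k <- (gr_at(oracle$h2_eq_bohr + h) - gr_at(oracle$h2_eq_bohr - h)) / (2 * h)
  mu <- lobehf:::element_mass("H") * lobehf:::AMU_TO_AU_MASS / 2
  period_fs <- 2 * pi / sqrt(k / mu) * FS_PER_AU_TIME
  stretched <- molecular_system(
    c("H", "H"), rbind(c(0, 0, 0),
                       c(0, 0, bohr_to_ang(oracle$h2_eq_bohr + 0.05))))
  traj2 <- md_run(stretched, dt_fs = 0.15, n_steps = 100,
                  init_temperature_K = 0, screening = no_screening())
  bl <- vapply(traj2$frames, function(fr) abs(fr$xyz[2, 3] - fr$xyz[1, 3]),
               numeric(1))
  ## period from successive interior maxima of the bond length
  pk <- which(diff(sign(diff(bl))) < 0) + 1
  expect_gte(length(pk), 2)
  period_md <- mean(diff(pk)) * 0.15
  expect_lt(abs(period_md - period_fs) / period_fs, 0.05)
})

test_that("NVE drift shrinks quadratically with the time step", {
  stretched <- molecular_system(
    c("H", "H"), rbind(c(0, 0, 0),
                       c(0, 0, bohr_to_ang(oracle$h2_eq_bohr + 0.12))))
  drift <- function(dt) {
    md_run(stretched, dt_fs = dt, n_steps = round(6 / dt),
           init_temperature_K = 0,
           screening = no_screening())$drift_ha_per_atom_fs
  }
  d1 <- drift(0.4)
  d2 <- drift(0.1)  # dt halved twice
  expect_lt(d2, d1 / 5)
})
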