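## Analytic nuclear gradients of the screened Hartree-Fock energy,
## BFGS structure optimization with a golden-section line search in
## energy-only mode, and microcanonical (NVE) molecular dynamics.
##
## The gradient differentiates every retained term of the truncated
## energy, including the chain rule through the cubic switching function
## and the erf kernel, plus the energy-weighted density term for overlap
## derivatives. Task-list membership (a 0/1 decision) is not
## differentiated; the smooth switching makes the retained energy C1, and
## the list is rebuilt at every new geometry.

## one-electron + Pulay gradient, vectorized over primitive pairs
.one_electron_gradient <- function(state) {
  basis <- state$basis
  P <- state$P
  occ <- seq_len(state$n_occ)
  W <- 2 * state$C[, occ, drop = FALSE] %*%
    (state$eps[occ] * t(state$C[, occ, drop = FALSE]))
  np <- length(basis$prim_coef)
  natom <- nrow(basis$atom_pos)
  ia <- rep(seq_len(np), times = np)
  ib <- rep(seq_len(np), each = np)
  aa <- basis$prim_alpha[ia]; ab <- basis$prim_alpha[ib]
  p <- aa + ab
  mu <- aa * ab / p
  ca <- basis$prim_center[ia, , drop = FALSE]
  cb <- basis$prim_center[ib, , drop = FALSE]
  dxyz <- ca - cb
  d2 <- rowSums(dxyz^2)
  cc <- basis$prim_coef[ia] * basis$prim_coef[ib]
  K <- exp(-mu * d2)
  Sp <- cc * (pi / p)^1.5 * K
  fa <- basis$prim_fn[ia]; fb <- basis$prim_fn[ib]
  atom_of_prim <- basis$fn$atom[basis$prim_fn]
  Aa <- atom_of_prim[ia]; Ab <- atom_of_prim[ib]
  Pfac <- P[cbind(fa, fb)]
  Wfac <- W[cbind(fa, fb)]
  grad <- matrix(0, natom, 3)
  addg <- function(atom_idx, gmat) {
    gm <- rowsum(gmat, group = atom_idx)
    idx <- as.integer(rownames(gm))
    grad[idx, ] <<- grad[idx, , drop = FALSE] + gm
    invisible(NULL)
  }
  ## overlap derivative (Pulay term, weight -W)
  dS <- (-2 * mu * Sp) * dxyz          # d S / d r_a; d/d r_b is the negative
  addg(Aa, -Wfac * dS)
  addg(Ab, +Wfac * dS)
  ## kinetic derivative (weight P)
  dT <- (-2 * mu^2 * Sp * (5 - 2 * mu * d2)) * dxyz
  addg(Aa, Pfac * dT)
  addg(Ab, -Pfac * dT)
  ## nuclear attraction (weight P): attraction part per nucleus
  rp <- (aa * ca + ab * cb) / p
  Vbase <- cc * (2 * pi / p) * K
  for (C_at in seq_len(natom)) {
    rc <- rp - matrix(basis$atom_pos[C_at, ], np * np, 3, byrow = TRUE)
    R2 <- rowSums(rc^2)
    F0 <- f11_half(p * R2)
    F0d <- .f0_deriv(p * R2)
    Z <- basis$atom_z[C_at]
    ## exponential-factor part, acts on r_a/r_b antisymmetrically
    dVk <- (-Z * Vbase * F0) * (-2 * mu) * dxyz
    addg(Aa, Pfac * dVk)
    addg(Ab, -Pfac * dVk)
    ## kernel part through |r_p - r_C|^2
    com <- (-Z * Vbase * F0d * p * 2)
    addg(Aa, Pfac * (com * (aa / p)) * rc)
    addg(Ab, Pfac * (com * (ab / p)) * rc)
    ## force on the nucleus C itself
    gC <- colSums(Pfac * (-com) * rc)
    grad[C_at, ] <- grad[C_at, ] + gC
  }
  grad
}

.f0_deriv <- function(x) {
  out <- numeric(length(x))
  small <- x < 1e-8
  out[small] <- -1 / 3 + x[small] / 5 - x[small]^2 / 14
  xb <- x[!small]
  out[!small] <- (exp(-xb) - f11_half(xb)) / (2 * xb)
  out
}

.nuclear_gradient <- function(system, screening) {
  pos <- positions(system, "bohr")
  z <- system$atoms$z
  n <- nrow(pos)
  rcl <- ang_to_bohr(screening$coulomb_lower_A)
  rcu <- ang_to_bohr(screening$coulomb_upper_A)
  grad <- matrix(0, n, 3)
  if (n < 2) return(grad)
  for (a in 2:n) for (b in seq_len(a - 1)) {
    dv <- pos[a, ] - pos[b, ]
    d <- sqrt(sum(dv^2))
    w <- smooth_cutoff(d, rcl, rcu)
    if (w == 0) next
    dw <- 0
    if (d > rcl && d < rcu) {
      x <- (d - rcl) / (rcu - rcl)
      dw <- (6 * x^2 - 6 * x) / (rcu - rcl)
    }
    ## d/dRa [ w(d) ZaZb/d ] = (dw/dd * ZaZb/d - w ZaZb/d^2) * unit
    coefd <- dw * z[a] * z[b] / d - w * z[a] * z[b] / d^2
    g <- coefd * dv / d
    grad[a, ] <- grad[a, ] + g
    grad[b, ] <- grad[b, ] - g
  }
  grad
}

#' Analytic nuclear gradient and forces
#'
#' Exact derivative of the implemented (screened, smoothly truncated)
#' total energy at a converged SCF solution: Hellmann-Feynman plus Pulay
#' terms for the one-electron part, the full primitive-level derivative
#' of the two-electron task list including the switching-function chain
#' rule, and the switched nucleus-nucleus repulsion. The defining
#' contract is agreement with central finite differences of
#' [scf_solve()] energies.
#'
#' @param state a converged `scf_state`.
#' @return a `gradient_result`: `forces` (natom x 3, Ha/bohr, forces =
#'   -dE/dR) and `gradient` (dE/dR).
#' @export
gradient <- function(state) {
  stopifnot(inherits(state, "scf_state"))
  basis <- state$basis
  g1 <- .one_electron_gradient(state)
  tk <- state$tasks
  atom_of_prim0 <- basis$fn$atom[basis$prim_fn] - 1L
  g2 <- cpp_eri_gradient(state$P, tk$p1, tk$p2, tk$fi, tk$fj, tk$fk, tk$fl,
                         state$eri, tk$w, tk$pair_table,
                         basis$prim_alpha, basis$prim_center,
                         atom_of_prim0, tk$pair_center,
                         tk$pair_atom1, tk$pair_atom2,
                         tk$rcl, tk$rcu, nrow(basis$atom_pos))
  gn <- .nuclear_gradient(state$system, state$screening)
  g <- g1 + g2 + gn
  structure(list(gradient = g, forces = -g,
                 components = list(one_electron = g1, two_electron = g2,
                                   nuclear = gn)),
            class = "gradient_result")
}

## total energy and gradient at a geometry (bohr coordinates flattened)
.energy_at <- function(xb, system, screening, scf, with_grad = FALSE) {
  sys <- set_positions(system, bohr_to_ang(matrix(xb, ncol = 3)))
  st <- scf_solve(sys, screening = screening, scf = scf)
  if (!st$converged) stop("SCF not converged during optimization")
  if (with_grad) list(E = st$E_total, g = gradient(st)$gradient, state = st)
  else list(E = st$E_total, state = st)
}

#' Golden-section line search (energy-only)
#'
#' Minimizes f on [0, t_max] by bracketing with golden-section steps;
#' only function values are used (no gradients), mirroring the
#' energy-only mode of the SCF line search. Non-finite evaluations
#' shrink the interval.
#'
#' @param f scalar function.
#' @param t_max initial upper bound.
#' @param rel_tol relative interval tolerance.
#' @return the located minimizer (scalar).
#' @export
golden_section <- function(f, t_max, rel_tol = 1e-2) {
  gr <- (sqrt(5) - 1) / 2
  a <- 0; b <- t_max
  fs <- function(t) {
    v <- tryCatch(f(t), error = function(e) Inf)
    if (!is.finite(v)) Inf else v
  }
  c_ <- b - gr * (b - a); d_ <- a + gr * (b - a)
  fc <- fs(c_); fd <- fs(d_)
  while ((b - a) > rel_tol * t_max) {
    if (fc < fd) {
      b <- d_; d_ <- c_; fd <- fc
      c_ <- b - gr * (b - a); fc <- fs(c_)
    } else {
      a <- c_; c_ <- d_; fc <- fd
      d_ <- a + gr * (b - a); fd <- fs(d_)
    }
  }
  (a + b) / 2
}

#' BFGS structure optimization with golden-section line search
#'
#' Quasi-Newton optimization of the screened Hartree-Fock energy: BFGS
#' inverse-Hessian updates precondition the gradient, and the step
#' length along each search direction is chosen by an energy-only
#' golden-section line search. Terminates on an RMS-force threshold, a
#' plateau, or the step limit. For larger molecules the RMS force
#' typically improves by one to two orders of magnitude before the
#' algorithm plateaus.
#'
#' @param system starting [molecular_system()].
#' @param screening a [screening_config()]. For gradient work the upper
#'   Coulomb radius should be at least 2.5 times the lower one so that
#'   the switching region never produces forces larger than the
#'   unswitched interaction.
#' @param scf an [scf_config()].
#' @param max_steps maximum BFGS steps.
#' @param rms_threshold RMS-force (per component, Ha/bohr) convergence
#'   target.
#' @param step0 initial line-search bracket along the normalized BFGS
#'   direction, bohr.
#' @return an `optimization_log`: per-step energies and RMS forces, the
#'   final system and state.
#' @export
bfgs_optimize <- function(system, screening = screening_config(),
                          scf = scf_config(), max_steps = 30L,
                          rms_threshold = 1e-4, step0 = 0.5) {
  x <- as.numeric(positions(system, "bohr"))
  n <- length(x)
  cur <- .energy_at(x, system, screening, scf, with_grad = TRUE)
  g <- as.numeric(cur$g)
  Hinv <- diag(n)
  log <- data.frame(step = 0L, E = cur$E,
                    rms_force = sqrt(mean(g^2)))
  for (it in seq_len(max_steps)) {
    dir <- -as.numeric(Hinv %*% g)
    nd <- sqrt(sum(dir^2))
    if (nd < 1e-12) break
    dirn <- dir / nd
    f1 <- function(t) .energy_at(x + t * dirn, system, screening, scf)$E
    t_star <- golden_section(f1, step0)
    if (t_star < 1e-8) t_star <- min(step0 * 0.01, 1e-2)
    x_new <- x + t_star * dirn
    nxt <- .energy_at(x_new, system, screening, scf, with_grad = TRUE)
    g_new <- as.numeric(nxt$g)
    s <- x_new - x; yv <- g_new - g
    sy <- sum(s * yv)
    if (sy > 1e-12) {
      rho <- 1 / sy
      I <- diag(n)
      Hinv <- (I - rho * outer(s, yv)) %*% Hinv %*%
        (I - rho * outer(yv, s)) + rho * outer(s, s)
    }
    x <- x_new; g <- g_new; cur <- nxt
    log <- rbind(log, data.frame(step = it, E = cur$E,
                                 rms_force = sqrt(mean(g^2))))
    if (sqrt(mean(g^2)) < rms_threshold) break
  }
  final <- set_positions(system, bohr_to_ang(matrix(x, ncol = 3)))
  structure(list(log = log, system = final, state = cur$state),
            class = "optimization_log")
}

#' Microcanonical (NVE) molecular dynamics
#'
#' Velocity-Verlet integration of the screened Hartree-Fock forces with
#' Maxwell-Boltzmann initial velocities (center-of-mass motion removed).
#' The total-energy drift per atom and femtosecond is the standard
#' integrator diagnostic; it decreases quadratically with the time step.
#'
#' @param system starting [molecular_system()].
#' @param dt_fs time step in femtoseconds (e.g. 0.2).
#' @param n_steps number of MD steps.
#' @param init_temperature_K initial kinetic temperature; 0 starts at
#'   rest.
#' @param seed RNG seed for the initial velocities.
#' @param screening a [screening_config()].
#' @param scf an [scf_config()].
#' @return an `md_trajectory`: list of frames (coordinates in Angstrom,
#'   potential/kinetic/total energies in Ha, time in fs) plus the drift
#'   metric (Ha/atom/fs).
#' @export
md_run <- function(system, dt_fs = 0.2, n_steps = 50L,
                   init_temperature_K = 0, seed = 1L,
                   screening = screening_config(), scf = scf_config()) {
  stopifnot(dt_fs > 0, n_steps >= 1)
  dt <- dt_fs / FS_PER_AU_TIME
  mass <- element_mass(system$atoms$element) * AMU_TO_AU_MASS
  natom <- n_atoms(system)
  x <- positions(system, "bohr")
  v <- matrix(0, natom, 3)
  if (init_temperature_K > 0) {
    kT <- init_temperature_K * 3.166811563e-6  # Ha/K
    v <- with_seed(seed, matrix(stats::rnorm(3 * natom), natom, 3)) *
      sqrt(kT / mass)
  }
  v <- sweep(v, 2, colSums(v * mass) / sum(mass))  # remove COM motion
  ev <- .energy_at(as.numeric(x), system, screening, scf, with_grad = TRUE)
  f <- -ev$g / mass  # acceleration
  frames <- vector("list", n_steps + 1)
  kin <- 0.5 * sum(mass * rowSums(v^2))
  frames[[1]] <- list(step = 0L, time_fs = 0, xyz = bohr_to_ang(x),
                      E_pot = ev$E, E_kin = kin, E_tot = ev$E + kin)
  for (s in seq_len(n_steps)) {
    v_half <- v + 0.5 * dt * f
    x <- x + dt * v_half
    ev <- tryCatch(
      .energy_at(as.numeric(x), system, screening, scf, with_grad = TRUE),
      error = function(e) e)
    if (inherits(ev, "error")) {
      warning("SCF failure at MD step ", s, "; returning partial trajectory")
      frames <- frames[seq_len(s)]
      break
    }
    f <- -ev$g / mass
    v <- v_half + 0.5 * dt * f
    kin <- 0.5 * sum(mass * rowSums(v^2))
    frames[[s + 1]] <- list(step = s, time_fs = s * dt_fs,
                            xyz = bohr_to_ang(x), E_pot = ev$E,
                            E_kin = kin, E_tot = ev$E + kin)
  }
  frames <- frames[!vapply(frames, is.null, TRUE)]
  etot <- vapply(frames, `[[`, 0, "E_tot")
  tfs <- vapply(frames, `[[`, 0, "time_fs")
  drift <- if (length(etot) > 1) {
    abs(etot[length(etot)] - etot[1]) / natom / max(tfs)
  } else 0
  structure(list(frames = frames, drift_ha_per_atom_fs = drift,
                 dt_fs = dt_fs), class = "md_trajectory")
}
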