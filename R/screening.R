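## Two-tier ERI screening: density-relevance filtering of basis-function
## pairs, a distance-based Coulomb cut-off with smooth switching between
## a lower and an upper radius, and an optional combined
## relevance/distance test. The survivors form the weighted task list
## that drives all two-electron work.

#' Screening configuration
#'
#' @param density_cutoff relevance threshold tau_rho for density pairs; a
#'   pair (i, j) survives when the integral over |phi_i phi_j| is at
#'   least this value. 0 disables the tier. Default 1e-4, the standard
#'   ground-state parametrization; use 1e-6 for spectra.
#' @param coulomb_lower_A,coulomb_upper_A lower/upper Coulomb cut-off
#'   radii in Angstrom: interactions between density pairs closer than
#'   the lower radius are kept in full, beyond the upper radius they are
#'   dropped, and in between they are scaled by the switching function
#'   f(x) = 1 + 2x^3 - 3x^2. `Inf` disables the tier. Defaults 8 and 10.
#' @param final_relevance threshold for the combined test
#'   r(rho_ij) r(rho_kl) / d >= tau_f; 0 (default) disables it, since no
#'   standard value exists for this threshold.
#' @param d_floor_bohr distance floor in the combined test (coincident
#'   centers are always maximally relevant).
#' @return a `screening_config` object (distances are converted to bohr
#'   once, when the task list is built).
#' @export
screening_config <- function(density_cutoff = 1e-4, coulomb_lower_A = 8,
                             coulomb_upper_A = 10, final_relevance = 0,
                             d_floor_bohr = 0.1) {
  stopifnot(density_cutoff >= 0, final_relevance >= 0,
            coulomb_lower_A > 0, coulomb_upper_A > coulomb_lower_A)
  structure(list(density_cutoff = density_cutoff,
                 coulomb_lower_A = coulomb_lower_A,
                 coulomb_upper_A = coulomb_upper_A,
                 final_relevance = final_relevance,
                 d_floor_bohr = d_floor_bohr),
            class = "screening_config")
}

#' Screening configuration with all cut-offs disabled
#' @export
no_screening <- function() {
  screening_config(density_cutoff = 0, coulomb_lower_A = 1e9,
                   coulomb_upper_A = Inf, final_relevance = 0)
}

#' Density relevance of a basis-function pair
#'
#' The integral over the absolute value of the product phi_i phi_j,
#' evaluated analytically from the all-positive (per-lobe) Gaussian
#' representations. Self-pairs of normalized s functions give ~1; the
#' value decays exponentially with the center separation.
#'
#' @param i,j basis-function indices.
#' @param basis a `lobe_basis`.
#' @export
density_relevance <- function(i, j, basis) {
  relevance_matrix(basis)[i, j]
}

#' Full density-relevance matrix
#' @param basis a `lobe_basis`.
#' @return symmetric n_bf x n_bf matrix of relevance values.
#' @export
relevance_matrix <- function(basis) {
  cpp_relevance_matrix(basis$n_bf, basis$rel_A, basis$rel_M,
                       basis$rel_center, basis$rel_ptr)
}

#' Distance between two density pairs
#'
#' Each density is assigned the arithmetic mean of the positions of the
#' two atoms hosting its basis functions; the interaction distance is the
#' Euclidean distance between those means.
#'
#' @param pair1,pair2 lists with element `atoms`, a 2 x 3 matrix of the
#'   two host-atom positions (Angstrom).
#' @return distance in Angstrom.
#' @export
coulomb_distance <- function(pair1, pair2) {
  c1 <- colMeans(pair1$atoms)
  c2 <- colMeans(pair2$atoms)
  sqrt(sum((c1 - c2)^2))
}

#' Smooth Coulomb cut-off weight
#'
#' f(x) = 1 + 2x^3 - 3x^2 with x the position of the distance inside the
#' switching window; 1 below the lower radius, 0 above the upper radius,
#' with zero slope at both ends (C1 continuity).
#'
#' @param d distance(s), same unit as the radii.
#' @param r_cl,r_cu lower and upper cut-off radii.
#' @export
smooth_cutoff <- function(d, r_cl, r_cu) {
  stopifnot(r_cl < r_cu)
  x <- pmin(pmax((d - r_cl) / (r_cu - r_cl), 0), 1)
  ifelse(d <= r_cl, 1, ifelse(d >= r_cu, 0, 1 + 2 * x^3 - 3 * x^2))
}

#' Build the screened, weighted ERI task list
#'
#' Applies the two screening tiers: basis-function pairs survive when
#' their density relevance reaches the density cut-off; canonical pairs
#' of surviving pairs become tasks when their center distance is below
#' the upper Coulomb radius (and, if enabled, when the combined
#' relevance/distance test passes). Each task carries the smooth
#' switching weight of its distance.
#'
#' @param basis a `lobe_basis`.
#' @param config a [screening_config()].
#' @return a `task_list` object with the surviving pair table, the
#'   canonical quadruples (`fi`, `fj`, `fk`, `fl`), weights `w` and the
#'   primitive pair table used by the ERI engine.
#' @export
build_task_list <- function(basis, config = screening_config()) {
  R <- relevance_matrix(basis)
  n <- basis$n_bf
  ij <- which(lower.tri(R, diag = TRUE), arr.ind = TRUE)
  ## canonical pair order: i >= j, composite index ascending
  ord <- order(ij[, 1], ij[, 2])
  ij <- ij[ord, , drop = FALSE]
  pi_ <- ij[, 1]; pj_ <- ij[, 2]
  rel <- R[cbind(pi_, pj_)]
  keep <- rel >= config$density_cutoff
  pi_ <- pi_[keep]; pj_ <- pj_[keep]; rel <- rel[keep]
  a1 <- basis$fn$atom[pi_]; a2 <- basis$fn$atom[pj_]
  pc <- (basis$atom_pos[a1, , drop = FALSE] +
           basis$atom_pos[a2, , drop = FALSE]) / 2   # bohr
  rcl <- ang_to_bohr(config$coulomb_lower_A)
  rcu <- ang_to_bohr(config$coulomb_upper_A)
  tk <- cpp_build_tasks(pc, rel, rcl, rcu, config$final_relevance,
                        config$d_floor_bohr)
  pt <- cpp_pair_table(pi_, pj_, basis$prim_coef, basis$prim_alpha,
                       basis$prim_center, basis$fn_ptr, 1e-12)
  structure(list(
    n_bf = n, config = config,
    pair_i = pi_, pair_j = pj_, pair_rel = rel,
    pair_atom1 = a1, pair_atom2 = a2, pair_center = pc,
    p1 = tk$p1, p2 = tk$p2, w = tk$w,
    fi = pi_[tk$p1], fj = pj_[tk$p1], fk = pi_[tk$p2], fl = pj_[tk$p2],
    pair_table = pt, rcl = rcl, rcu = rcu
  ), class = "task_list")
}

#' @export
print.task_list <- function(x, ...) {
  cat(sprintf(
    "<task_list> %d basis functions: %d surviving pairs, %d ERI tasks (%.3g%% of unique)\n",
    x$n_bf, length(x$pair_i), length(x$p1),
    100 * length(x$p1) / count_unique_eris(x$n_bf)))
  invisible(x)
}

#' Evaluate the contracted ERIs of a task list
#' @param tasks a `task_list`.
#' @return numeric vector of unweighted ERI values (hartree), parallel to
#'   the tasks.
#' @export
compute_eris <- function(tasks) {
  cpp_eri_values(tasks$p1, tasks$p2, tasks$pair_table)
}
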