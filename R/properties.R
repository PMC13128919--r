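## Atomic energies (a Mulliken-style per-atom partition of the
## electronic energy restricted to valence functions and normalized by
## nuclear charge), the smoothing/rescaling protocol that maps them onto
## a structure-confidence score scale, and the binding-energy workflow.

#' Per-atom quantum energies
#'
#' E_a = (1/Z_a) sum over the atom's valence basis functions i and all
#' functions j of P_ij (H_ij + G_ij / 2). With `valence_only = FALSE`
#' and `normalize = FALSE` the per-atom values sum exactly to the
#' electronic energy (partition identity).
#'
#' @param state an `scf_state`, or a list with elements `P`, `H`, `G`
#'   and `basis` (e.g. assembled from a merged divide-and-conquer
#'   density).
#' @param valence_only restrict the outer sum to valence functions
#'   (default, the standard protocol).
#' @param normalize divide by the nuclear charge Z_a (default).
#' @return an `atomic_energy_profile` data.frame with columns `atom`,
#'   `element`, `z` and `raw` (hartree).
#' @export
atomic_energies <- function(state, valence_only = TRUE, normalize = TRUE) {
  basis <- state$basis
  M <- state$P * (state$H + 0.5 * state$G)
  fn_sum <- rowSums(M)
  keep <- if (valence_only) basis$fn$valence else rep(TRUE, basis$n_bf)
  raw <- vapply(seq_len(nrow(basis$atom_pos)), function(a) {
    idx <- which(basis$fn$atom == a & keep)
    s <- sum(fn_sum[idx])
    if (normalize) s / basis$atom_z[a] else s
  }, numeric(1))
  structure(data.frame(atom = seq_along(raw),
                       element = element_symbol_from_z(basis$atom_z),
                       z = basis$atom_z, raw = raw),
            class = c("atomic_energy_profile", "data.frame"))
}

#' Assemble the energy matrices for a merged divide-and-conquer density
#'
#' Builds the global core Hamiltonian and two-electron matrix for a
#' merged density matrix so that [atomic_energies()] can be evaluated on
#' divide-and-conquer results.
#'
#' @param merged a `merged_density` from [merge_densities()].
#' @param screening a [screening_config()] for the global two-electron
#'   assembly.
#' @return list with `P`, `H`, `G`, `basis`, usable as the `state`
#'   argument of [atomic_energies()].
#' @export
merged_energy_state <- function(merged, screening = screening_config()) {
  basis <- merged$basis
  one <- one_electron_matrices(basis)
  tasks <- build_task_list(basis, screening)
  eri <- compute_eris(tasks)
  gb <- build_fock(merged$P, one$H, tasks, eri)
  list(P = merged$P, H = one$H, G = gb$G, basis = basis)
}

#' Smoothing/rescaling configuration for atomic-energy scores
#'
#' @param window Savitzky-Golay window length along the atom chain; an
#'   even value is promoted to the next odd number (the default 150
#'   becomes 151).
#' @param order polynomial order of the filter.
#' @param scale multiplicative factor applied to the smoothed energies
#'   (default 15, the standard calibration onto the 0-100 confidence
#'   scale).
#' @param offset structure-specific additive offset; `NULL` selects the
#'   offset that matches the mean of `clip` bounds.
#' @param clip length-2 numeric bounds of the comparison score.
#' @export
energy_rescale_config <- function(window = 150L, order = 3L, scale = 15,
                                  offset = NULL, clip = c(0, 100)) {
  window <- as.integer(window)
  if (window %% 2L == 0L) window <- window + 1L
  stopifnot(window >= order + 2, length(clip) == 2)
  structure(list(window = window, order = as.integer(order), scale = scale,
                 offset = offset, clip = sort(clip)),
            class = "energy_rescale_config")
}

#' Smooth and rescale an atomic-energy profile
#'
#' Savitzky-Golay smoothing along the atom ordering (file/chain order)
#' followed by the affine map score = scale * smoothed + offset, clipped
#' to the configured bounds. A window longer than the chain is shrunk to
#' the largest valid odd length (recorded in the returned attributes).
#'
#' @param profile an `atomic_energy_profile` from [atomic_energies()].
#' @param cfg an [energy_rescale_config()].
#' @return the profile with added columns `smoothed` and `score`.
#' @export
smooth_and_rescale <- function(profile, cfg = energy_rescale_config()) {
  x <- profile$raw
  n <- length(x)
  win <- cfg$window
  if (win > n) {
    win <- max(cfg$order + 2L, n - (1L - n %% 2L))
    if (win %% 2L == 0L) win <- win - 1L
  }
  smoothed <- if (win > cfg$order + 1 && n >= win) {
    signal::sgolayfilt(x, p = cfg$order, n = win)
  } else x
  offset <- cfg$offset
  if (is.null(offset)) {
    offset <- mean(cfg$clip) - cfg$scale * mean(smoothed)
  }
  score <- pmin(pmax(cfg$scale * smoothed + offset, cfg$clip[1]),
                cfg$clip[2])
  profile$smoothed <- smoothed
  profile$score <- score
  attr(profile, "window_used") <- win
  attr(profile, "offset_used") <- offset
  profile
}

#' Extract a ligand binding site from a complex
#'
#' Returns three consistent systems: the capped complex part (ligand +
#' environment), the capped protein part (environment only) and the
#' ligand. The environment contains every atom within `radius_A` of any
#' ligand atom; bonds cut by the selection are repaired with cap
#' hydrogens via the divide-and-conquer capping rules.
#'
#' @param complex a [molecular_system()] (e.g. from [read_pdb()]).
#' @param ligand_selector integer atom indices of the ligand, or a
#'   residue name matched against the `res_name` metadata column.
#' @param radius_A environment radius (default 4).
#' @return list with `complex_part`, `protein_part`, `ligand`.
#' @export
extract_binding_site <- function(complex, ligand_selector, radius_A = 4) {
  lig <- if (is.numeric(ligand_selector)) {
    as.integer(ligand_selector)
  } else {
    which(complex$atoms$res_name == ligand_selector)
  }
  if (!length(lig)) stop("empty ligand selection")
  pos <- positions(complex)
  d2min <- rep(Inf, nrow(pos))
  for (a in lig) d2min <- pmin(d2min, rowSums(sweep(pos, 2, pos[a, ])^2))
  env <- setdiff(which(d2min <= radius_A^2), lig)
  bonds <- detect_bonds(complex)
  capped <- function(core) {
    cl <- .new_cluster(1L, core)
    cl <- cap_cut_bonds(cl, complex, bonds = bonds)
    cluster_system(cl, complex)$system
  }
  ## the ligand is a complete molecule: exclude its atoms from capping
  ## targets by construction (bonds internal to the selection stay whole)
  list(complex_part = capped(sort(c(lig, env))),
       protein_part = if (length(env)) capped(env) else NULL,
       ligand = subset_system(complex, lig, label = "ligand"))
}

#' Ligand binding energy by the supermolecular difference
#'
#' E_bind = E(complex part) - E(protein part) - E(ligand), converted to
#' kcal/mol. Sensitive to the Coulomb cut-off: quantitative binding
#' energies need a large or disabled cut-off window.
#'
#' @param complex_part,protein_part,ligand systems from
#'   [extract_binding_site()] (or any three consistent systems).
#' @param screening a [screening_config()].
#' @param scf an [scf_config()].
#' @return binding energy in kcal/mol (negative = attractive).
#' @export
binding_energy <- function(complex_part, protein_part, ligand,
                           screening = screening_config(),
                           scf = scf_config()) {
  e <- function(sys) {
    if (is.null(sys)) return(0)
    st <- scf_solve(sys, screening = screening, scf = scf)
    if (!st$converged) stop("SCF did not converge for ", sys$label)
    st$E_total
  }
  (e(complex_part) - e(protein_part) - e(ligand)) * KCAL_PER_HARTREE
}
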