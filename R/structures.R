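#' Molecular system container
#'
#' The universal structural input of the package: an ordered set of atoms
#' with element symbols and Cartesian positions in Angstrom, plus a net
#' charge. Everything downstream (basis construction, SCF, partitioning,
#' dynamics) consumes this class.
#'
#' @param element character vector of element symbols.
#' @param xyz numeric matrix (n x 3) of positions in Angstrom.
#' @param net_charge integer net charge of the system.
#' @param label free-text label.
#' @param is_cap_hydrogen logical vector flagging hydrogens introduced to
#'   cap cut bonds (divide-and-conquer); recycled.
#' @param source_id optional integer vector of original record indices
#'   (e.g. PDB atom serials).
#' @param box optional numeric length-3 vector of box extents (Angstrom).
#' @param meta optional data.frame of per-atom metadata (e.g. PDB residue
#'   names); must have one row per atom.
#' @return an object of class `molecular_system`.
#' @examples
#' molecular_system("H", matrix(0, 1, 3))
#' @export
molecular_system <- function(element, xyz, net_charge = 0L, label = "",
                             is_cap_hydrogen = FALSE, source_id = NULL,
                             box = NULL, meta = NULL) {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  n <- length(element)
  if (n < 1L) stop("a molecular system needs at least one atom")
  if (nrow(xyz) != n) stop("element and xyz disagree on atom count")
  if (!all(is.finite(xyz))) stop("non-finite atomic position")
  z <- element_z(element)
  atoms <- data.frame(
    element = element,
    z = z,
    x = xyz[, 1], y = xyz[, 2], z_coord = xyz[, 3],
    is_cap_hydrogen = rep_len(as.logical(is_cap_hydrogen), n),
    source_id = if (is.null(source_id)) NA_integer_ else as.integer(source_id),
    stringsAsFactors = FALSE
  )
  if (!is.null(meta)) {
    stopifnot(nrow(meta) == n)
    atoms <- cbind(atoms, meta)
  }
  ne <- sum(z) - net_charge
  if (ne < 0) stop("negative electron count")
  structure(list(atoms = atoms, net_charge = as.integer(net_charge),
                 box = box, label = label),
            class = "molecular_system")
}

#' @export
print.molecular_system <- function(x, ...) {
  comp <- table(x$atoms$element)
  cat(sprintf("<molecular_system> %s: %d atoms (%s), charge %+d, %d electrons\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              nrow(x$atoms),
              paste0(names(comp), comp, collapse = " "),
              x$net_charge, n_electrons(x)))
  invisible(x)
}

#' Number of atoms in a system
#' @param system a `molecular_system`.
#' @export
n_atoms <- function(system) nrow(system$atoms)

#' Electron count of a system
#' @param system a `molecular_system`.
#' @return sum of nuclear charges minus the net charge.
#' @export
n_electrons <- function(system) sum(system$atoms$z) - system$net_charge

#' Atomic positions as a matrix
#' @param system a `molecular_system`.
#' @param unit `"angstrom"` (default, the storage unit) or `"bohr"`.
#' @return numeric n x 3 matrix.
#' @export
positions <- function(system, unit = c("angstrom", "bohr")) {
  unit <- match.arg(unit)
  m <- cbind(system$atoms$x, system$atoms$y, system$atoms$z_coord)
  if (unit == "bohr") m <- ang_to_bohr(m)
  m
}

#' Replace atomic positions
#' @param system a `molecular_system`.
#' @param xyz numeric n x 3 matrix in Angstrom.
#' @export
set_positions <- function(system, xyz) {
  stopifnot(nrow(xyz) == n_atoms(system))
  system$atoms$x <- xyz[, 1]
  system$atoms$y <- xyz[, 2]
  system$atoms$z_coord <- xyz[, 3]
  system
}

#' Extract a subset of atoms as a new system
#' @param system a `molecular_system`.
#' @param idx integer atom indices (kept in the given order).
#' @param net_charge net charge of the subsystem (default 0).
#' @param label label of the subsystem.
#' @export
subset_system <- function(system, idx, net_charge = 0L, label = system$label) {
  atoms <- system$atoms[idx, , drop = FALSE]
  extra <- setdiff(names(atoms),
                   c("element", "z", "x", "y", "z_coord",
                     "is_cap_hydrogen", "source_id"))
  molecular_system(atoms$element, cbind(atoms$x, atoms$y, atoms$z_coord),
                   net_charge = net_charge, label = label,
                   is_cap_hydrogen = atoms$is_cap_hydrogen,
                   source_id = atoms$source_id,
                   meta = if (length(extra)) atoms[extra] else NULL)
}

#' Uniform volumetric scalar field (electron density grid)
#'
#' @param origin numeric length-3, grid origin in bohr.
#' @param spacing scalar grid spacing in bohr.
#' @param shape integer length-3, number of points along x, y, z.
#' @param values numeric array of dim `shape` (electrons/bohr^3).
#' @return an object of class `density_grid`.
#' @export
density_grid <- function(origin, spacing, shape, values) {
  shape <- as.integer(shape)
  stopifnot(length(origin) == 3, length(shape) == 3, all(shape > 0),
            spacing > 0)
  values <- array(as.numeric(values), dim = shape)
  if (!all(is.finite(values))) stop("non-finite grid values")
  structure(list(origin = as.numeric(origin), spacing = as.numeric(spacing),
                 shape = shape, values = values),
            class = "density_grid")
}

#' Integrate a density grid (trapezoid-equivalent Riemann sum)
#' @param grid a `density_grid`.
#' @return total number of electrons represented on the grid.
#' @export
integrate_grid <- function(grid) sum(grid$values) * grid$spacing^3

#' Absorption spectrum container
#'
#' @param energies strictly ascending photon energies in eV.
#' @param intensities absorption intensities (arbitrary units).
#' @return an object of class `absorption_spectrum`.
#' @export
absorption_spectrum <- function(energies, intensities) {
  stopifnot(length(energies) == length(intensities))
  if (length(energies) > 1 && any(diff(energies) <= 0)) {
    stop("energies must be strictly ascending")
  }
  if (!all(is.finite(intensities))) stop("non-finite intensities")
  structure(list(energies = as.numeric(energies),
                 intensities = as.numeric(intensities)),
            class = "absorption_spectrum")
}
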