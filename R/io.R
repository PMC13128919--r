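## Readers/writers for the plain-text formats the tool touches:
## XYZ, PDB (wwPDB v3.3 ATOM/HETATM subset), Gaussian cube, and
## two-column spectrum files. Files are Angstrom; cube files are bohr
## (the format's own convention).

#' Read an XYZ file
#'
#' Standard XYZ: atom-count line, comment line, then `element x y z`
#' records in Angstrom. For multi-frame files only the first frame is read
#' (see [read_xyz_frames()]).
#'
#' @param path file path.
#' @param net_charge net charge to assign (XYZ carries none); default 0.
#' @return a [molecular_system()].
#' @export
read_xyz <- function(path, net_charge = 0L) {
  lines <- readLines(path)
  if (length(lines) < 1) stop("empty XYZ file: ", path)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 1) stop("malformed atom-count line in ", path, " (line 1)")
  if (length(lines) < n + 2) {
    stop("XYZ file ", path, " declares ", n, " atoms but has only ",
         max(0L, length(lines) - 2L), " atom records")
  }
  rec <- lines[3:(n + 2)]
  toks <- strsplit(trimws(rec), "\\s+")
  bad <- which(vapply(toks, length, 1L) < 4)
  if (length(bad)) stop("malformed atom record at line ", bad[1] + 2, " of ", path)
  el <- vapply(toks, `[[`, "", 1)
  known <- el %in% .element_table$symbol
  if (!all(known)) {
    stop("unknown element symbol '", el[!known][1], "' at line ",
         which(!known)[1] + 2, " of ", path)
  }
  xyz <- t(vapply(toks, function(t) as.numeric(t[2:4]), numeric(3)))
  if (anyNA(xyz)) stop("non-numeric coordinate in ", path)
  molecular_system(el, xyz, net_charge = net_charge,
                   label = trimws(lines[2]))
}

#' Read all frames of a multi-frame XYZ file
#' @param path file path.
#' @return a list of [molecular_system()] objects.
#' @export
read_xyz_frames <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i <= length(lines) && nzchar(trimws(lines[i]))) {
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) break
    tmp <- tempfile(fileext = ".xyz")
    writeLines(lines[i:(i + n + 1)], tmp)
    frames[[length(frames) + 1L]] <- read_xyz(tmp)
    unlink(tmp)
    i <- i + n + 2L
  }
  frames
}

#' Write an XYZ file
#' @param system a [molecular_system()].
#' @param path output path.
#' @param comment comment line (defaults to the system label).
#' @param append append as an additional frame (multi-frame XYZ).
#' @export
write_xyz <- function(system, path, comment = system$label, append = FALSE) {
  xyz <- positions(system)
  rec <- sprintf("%-3s %18.12f %18.12f %18.12f",
                 system$atoms$element, xyz[, 1], xyz[, 2], xyz[, 3])
  con <- file(path, open = if (append) "a" else "w")
  on.exit(close(con))
  writeLines(c(as.character(n_atoms(system)), comment, rec), con)
  invisible(path)
}

#' Read a PDB file (ATOM/HETATM subset, wwPDB v3.3 columns)
#'
#' Positions are taken in Angstrom. Alternate locations are resolved to the
#' highest occupancy (first record on ties); only the first MODEL of a
#' multi-model file is used. The element is taken from columns 77-78 and
#' falls back to an atom-name heuristic when that field is blank.
#'
#' @param path file path.
#' @param keep_waters keep HETATM water records (residue HOH/WAT)?
#' @param net_charge net charge to assign; default 0.
#' @return a [molecular_system()] whose per-atom metadata records
#'   `atom_name`, `res_name`, `res_seq` and `chain`.
#' @export
read_pdb <- function(path, keep_waters = TRUE, net_charge = 0L) {
  lines <- readLines(path)
  endmdl <- grep("^ENDMDL", lines)
  if (length(endmdl)) lines <- lines[seq_len(endmdl[1] - 1L)]
  rec <- lines[grepl("^(ATOM  |HETATM)", lines)]
  if (!length(rec)) stop("no ATOM/HETATM records in ", path)
  field <- function(a, b) trimws(substr(rec, a, b))
  atom_name <- field(13, 16)
  altloc <- field(17, 17)
  res_name <- field(18, 20)
  chain <- field(22, 22)
  res_seq <- suppressWarnings(as.integer(field(23, 26)))
  x <- as.numeric(field(31, 38)); y <- as.numeric(field(39, 46))
  zc <- as.numeric(field(47, 54))
  occ <- suppressWarnings(as.numeric(field(55, 60)))
  occ[is.na(occ)] <- 1
  el <- field(77, 78)
  serial <- suppressWarnings(as.integer(field(7, 11)))
  ## element fallback: first alphabetic character(s) of the atom name
  guess <- sub("^[0-9]*", "", atom_name)
  guess <- sub("[0-9'].*$", "", guess)
  guess <- paste0(substr(guess, 1, 1), tolower(substr(guess, 2, 2)))
  guess <- ifelse(guess %in% .element_table$symbol, guess, substr(guess, 1, 1))
  el <- ifelse(nzchar(el),
               paste0(substr(el, 1, 1), tolower(substr(el, 2, 2))),
               guess)
  el <- ifelse(el %in% .element_table$symbol, el, substr(el, 1, 1))

  keep <- rep(TRUE, length(rec))
  if (!keep_waters) keep <- keep & !(res_name %in% c("HOH", "WAT", "TIP", "SOL"))
  ## altloc resolution: per (chain, res_seq, atom_name) keep the highest
  ## occupancy, first on tie
  key <- paste(chain, res_seq, res_name, atom_name, sep = "|")
  has_alt <- nzchar(altloc)
  if (any(has_alt)) {
    ord <- order(key, -occ, seq_along(rec))
    dup <- duplicated(key[ord])
    drop_idx <- ord[dup]
    keep[drop_idx] <- FALSE
  }
  idx <- which(keep)
  if (!length(idx)) stop("no atoms retained from ", path)
  molecular_system(el[idx], cbind(x, y, zc)[idx, , drop = FALSE],
                   net_charge = net_charge,
                   label = basename(path), source_id = serial[idx],
                   meta = data.frame(atom_name = atom_name[idx],
                                     res_name = res_name[idx],
                                     res_seq = res_seq[idx],
                                     chain = chain[idx],
                                     stringsAsFactors = FALSE))
}

#' Write a Gaussian cube file
#'
#' Gaussian cube dialect with a positive atom count (no orbital block):
#' two comment lines, origin/axes in bohr, atom block (Z, charge,
#' position in bohr), then values in x-outer/z-inner order.
#'
#' @param grid a [density_grid()] (origin/spacing in bohr).
#' @param system a [molecular_system()] or `NULL` for an empty atom block.
#' @param path output path.
#' @export
write_cube <- function(grid, system, path) {
  natom <- if (is.null(system)) 0L else n_atoms(system)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("lobehf electron density", "all values in atomic units"), con)
  writeLines(sprintf("%5d %11.6f %11.6f %11.6f", natom,
                     grid$origin[1], grid$origin[2], grid$origin[3]), con)
  for (k in 1:3) {
    ax <- c(0, 0, 0); ax[k] <- grid$spacing
    writeLines(sprintf("%5d %11.6f %11.6f %11.6f", grid$shape[k],
                       ax[1], ax[2], ax[3]), con)
  }
  if (natom > 0) {
    pb <- positions(system, "bohr")
    writeLines(sprintf("%5d %11.6f %11.6f %11.6f %11.6f", system$atoms$z,
                       as.numeric(system$atoms$z), pb[, 1], pb[, 2], pb[, 3]),
               con)
  }
  v <- grid$values
  for (i in seq_len(grid$shape[1])) {
    for (j in seq_len(grid$shape[2])) {
      row <- v[i, j, ]
      for (s in seq(1, length(row), by = 6)) {
        writeLines(paste(sprintf("%13.5E", row[s:min(s + 5, length(row))]),
                         collapse = " "), con)
      }
    }
  }
  invisible(path)
}

#' Read a Gaussian cube file
#' @param path file path.
#' @return a list with elements `grid` (a [density_grid()]) and `system`
#'   (a [molecular_system()] or `NULL` when the atom block is empty).
#' @export
read_cube <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[3:6]), "\\s+")
  natom <- as.integer(hdr[[1]][1])
  origin <- as.numeric(hdr[[1]][2:4])
  shape <- vapply(hdr[2:4], function(h) as.integer(h[1]), 1L)
  spacing <- as.numeric(hdr[[2]][2])
  system <- NULL
  if (natom > 0) {
    at <- strsplit(trimws(lines[7:(6 + natom)]), "\\s+")
    z <- vapply(at, function(a) as.integer(a[1]), 1L)
    xyz <- t(vapply(at, function(a) as.numeric(a[3:5]), numeric(3)))
    system <- molecular_system(element_symbol_from_z(z), bohr_to_ang(xyz))
  }
  vals <- as.numeric(unlist(strsplit(trimws(lines[(7 + natom):length(lines)]),
                                     "\\s+")))
  stopifnot(length(vals) == prod(shape))
  values <- aperm(array(vals, dim = rev(shape)), 3:1)
  list(grid = density_grid(origin, spacing, shape, values), system = system)
}

#' Write a spectrum as two-column text
#' @param spec an [absorption_spectrum()].
#' @param path output path.
#' @export
write_spectrum <- function(spec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("energy_eV\tintensity_arb", con)
  if (length(spec$energies)) {
    writeLines(sprintf("%.12g\t%.12g", spec$energies, spec$intensities), con)
  }
  invisible(path)
}

#' Read a two-column spectrum file
#' @param path file path.
#' @return an [absorption_spectrum()].
#' @export
read_spectrum <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  absorption_spectrum(d[[1]], d[[2]])
}
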