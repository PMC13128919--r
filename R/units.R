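#' @useDynLib lobehf, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

## Unit conversions. All quantum-mechanical internals are atomic units
## (bohr, hartree, a.u. time); structure files and user-facing geometry
## parameters are in Angstrom. The Angstrom<->bohr constant is applied
## exactly once, at the boundary where a structure enters the quantum layer
## (basis construction / screening-config conversion).
BOHR_PER_ANGSTROM <- 1.8897259886

#' Physical constants
#'
#' Conversion constants used at the input/output boundary: `HARTREE_EV`
#' (eV per hartree), `KCAL_PER_HARTREE` (kcal/mol per hartree) and
#' `FS_PER_AU_TIME` (femtoseconds per atomic time unit).
#' @name constants
NULL

#' @rdname constants
#' @export
HARTREE_EV <- 27.211386245988
#' @rdname constants
#' @export
KCAL_PER_HARTREE <- 627.509
#' @rdname constants
#' @export
FS_PER_AU_TIME <- 0.02418884254
AMU_TO_AU_MASS <- 1822.888486209

#' Angstrom/bohr conversion
#' @param x numeric values to convert.
#' @return converted values (1 Angstrom = 1.8897259886 bohr).
#' @export
ang_to_bohr <- function(x) x * BOHR_PER_ANGSTROM

#' @rdname ang_to_bohr
#' @export
bohr_to_ang <- function(x) x / BOHR_PER_ANGSTROM

## Element table: symbol, nuclear charge, single-bond covalent radius
## (Cordero-style, Angstrom), atomic mass (amu).
.element_table <- data.frame(
  symbol = c("H", "He", "C", "N", "O", "P", "S"),
  z      = c(1L,  2L,   6L,  7L,  8L,  15L, 16L),
  rcov   = c(0.31, 0.28, 0.76, 0.71, 0.66, 1.07, 1.05),
  mass   = c(1.008, 4.0026, 12.011, 14.007, 15.999, 30.974, 32.06),
  stringsAsFactors = FALSE
)

#' Nuclear charge for an element symbol
#'
#' @param element character vector of element symbols (case-sensitive,
#'   e.g. `"C"`, `"He"`).
#' @return integer vector of nuclear charges.
#' @examples
#' element_z(c("H", "O"))
#' @export
element_z <- function(element) {
  idx <- match(element, .element_table$symbol)
  if (anyNA(idx)) {
    stop("unsupported element symbol(s): ",
         paste(unique(element[is.na(idx)]), collapse = ", "))
  }
  .element_table$z[idx]
}

element_symbol_from_z <- function(z) {
  idx <- match(as.integer(z), .element_table$z)
  if (anyNA(idx)) stop("unsupported nuclear charge(s): ",
                       paste(unique(z[is.na(idx)]), collapse = ", "))
  .element_table$symbol[idx]
}

element_rcov <- function(element) {
  .element_table$rcov[match(element, .element_table$symbol)]
}

element_mass <- function(element) {
  .element_table$mass[match(element, .element_table$symbol)]
}

## Typical X-H bond lengths (Angstrom) used for cap-hydrogen placement.
.xh_bond_length <- c(C = 1.09, N = 1.01, O = 0.96, S = 1.34, P = 1.42, H = 0.74)

## Run an expression with a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}
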