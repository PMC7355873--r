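#' Physical constants and unit conversions
#'
#' Internal working units are Hartree atomic units throughout (hbar = 1):
#' lengths in bohr, masses in electron masses, energies in hartree.  User-facing
#' reports use the units customary in the isotope-shift literature: angstrom
#' (and milli-/micro-angstrom) for lengths, cm^-1 for harmonic wavenumbers, amu
#' for masses, ppm for shielding surfaces and ppb for isotope shifts.
#'
#' @format A named list with elements `amu_to_me` (1 amu in electron masses),
#'   `bohr_to_angstrom`, `hartree_to_cm1`.
#' @examples
#' vib_constants$bohr_to_angstrom
#' @export
vib_constants <- list(
  amu_to_me        = 1822.888486209,
  bohr_to_angstrom = 0.529177210903,
  hartree_to_cm1   = 219474.6313632
)

#' @rdname vib_constants
#' @param x numeric vector of harmonic frequencies in atomic units (hartree).
#' @return `au_to_cm1()`: frequencies in cm^-1.
#' @export
au_to_cm1 <- function(x) x * vib_constants$hartree_to_cm1

#' @rdname vib_constants
#' @return `cm1_to_au()`: frequencies in hartree.
#' @export
cm1_to_au <- function(x) x / vib_constants$hartree_to_cm1

#' @rdname vib_constants
#' @return `bohr_to_ang()` / `ang_to_bohr()`: lengths converted between bohr
#'   and angstrom.
#' @export
bohr_to_ang <- function(x) x * vib_constants$bohr_to_angstrom

#' @rdname vib_constants
#' @export
ang_to_bohr <- function(x) x / vib_constants$bohr_to_angstrom

# masses: amu -> atomic units (electron masses)
amu_to_au <- function(m) m * vib_constants$amu_to_me
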