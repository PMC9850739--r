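## Physical constants and element tables. All unit policy lives here:
## lengths in Angstrom, angles in degrees, stored SCF energies in Hartree,
## every fitted/reported energy in kJ/mol.

#' Molar Hartree in kJ/mol
#'
#' The single place the Hartree -> kJ/mol conversion constant is pinned.
#'
#' @format A length-one numeric.
#' @export
HARTREE_KJ_PER_MOL <- 2625.499639479826

## Coulomb prefactor f in E = f * q_i q_j / r, with q in elementary charges,
## r in Angstrom, E in kJ/mol (CODATA-consistent value used across MD codes).
COULOMB_KJ_ANG_E2 <- 138.935458

## Element symbols indexed by atomic number (enough for main-group organics
## and the transition rows that show up in scan logs).
.ELEMENTS <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
  "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar", "K", "Ca",
  "Sc", "Ti", "V", "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn",
  "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr", "Y", "Zr",
  "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd",
  "Pm", "Sm", "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb",
  "Lu", "Hf", "Ta", "W", "Re", "Os", "Ir", "Pt", "Au", "Hg",
  "Tl", "Pb", "Bi", "Po", "At", "Rn"
)

elementSymbol <- function(z) {
  z <- as.integer(z)
  if (any(is.na(z)) || any(z < 1L) || any(z > length(.ELEMENTS)))
    pesStop("dialect", "atomic number outside supported element table")
  .ELEMENTS[z]
}

isElementSymbol <- function(sym) sym %in% .ELEMENTS

## Condition helper: all package errors carry class "evbscan_<kind>_error"
## so callers can branch on the failure mode.
pesStop <- function(kind, ..., call. = FALSE) {
  msg <- paste0(...)
  stop(structure(
    class = c(paste0("evbscan_", kind, "_error"), "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

deg2rad <- function(x) x * (pi / 180)
rad2deg <- function(x) x * (180 / pi)
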