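# Shared chemical constants and lookup tables.

#' Amyloid-beta (1-40) sequence
#'
#' One-letter sequence of the 40-residue amyloid-beta peptide analysed by the
#' pipeline, N- to C-terminus.
#'
#' @format Character scalar of 40 letters.
#' @export
AB40_SEQUENCE <- "DAEFRHDSGYEVHHQKLVFFAEDVGSNKGAIIGLMVGGVV"

# Boltzmann constant in kcal/(mol K); the native free-energy unit is kT.
KB_KCAL <- 0.0019872

# average atomic masses (amu)
.ELEMENT_MASS <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999,
  S = 32.06, P = 30.974, NA_ = 22.990, CL = 35.45, K = 39.098
)

.AA_THREE <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
  E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
  M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
  Y = "TYR", V = "VAL"
)
.AA_ONE <- stats::setNames(names(.AA_THREE), .AA_THREE)

# side-chain masses (amu): residue average mass minus the backbone unit
.SIDECHAIN_MASS <- c(
  A = 15.03, R = 100.14, N = 58.06, D = 59.04, C = 47.10, Q = 72.09,
  E = 73.07, G = 1.01, H = 81.10, I = 57.11, L = 57.11, K = 72.13,
  M = 75.15, F = 91.13, P = 41.07, S = 31.03, T = 45.06, W = 130.17,
  Y = 107.13, V = 43.09
)

.PEPTIDE_RESNAMES <- unname(.AA_THREE)
.WATER_RESNAMES <- c("TIP3", "SOL", "HOH", "WAT", "TIP3P")
.ION_RESNAMES <- c("SOD", "CLA", "POT", "NA", "CL", "K", "MG", "CA2")

#' Infer an atom's element from its PDB-style name
#'
#' Leading digits are stripped; the first remaining letter decides the
#' element, with two-letter ion names (NA, CL) recognised for ion residues.
#'
#' @param name Atom name(s).
#' @param residue_name Residue name(s), used to disambiguate ions.
#' @return Character vector of element symbols.
#' @keywords internal
infer_element <- function(name, residue_name = NULL) {
  stripped <- sub("^[0-9]+", "", name)
  first <- toupper(substr(stripped, 1L, 1L))
  if (!is.null(residue_name)) {
    ion <- toupper(residue_name) %in% .ION_RESNAMES
    first[ion & toupper(stripped) %in% c("NA", "SOD")] <- "NA_"
    first[ion & toupper(stripped) %in% c("CL", "CLA")] <- "CL"
    first[ion & toupper(stripped) %in% c("K", "POT")] <- "K"
  }
  bad <- !first %in% names(.ELEMENT_MASS)
  if (any(bad)) {
    stop("cannot infer element for atom name(s): ",
         paste(unique(name[bad]), collapse = ", "))
  }
  first
}

element_mass <- function(element) {
  unname(.ELEMENT_MASS[element])
}

#' Map residue names to coarse system groups
#'
#' @param residue_name Character vector of residue names.
#' @return Factor-like character vector over
#'   `peptide, lipid_POPC, lipid_POPS, lipid_CHOL, water, ion`.
#' @keywords internal
infer_group <- function(residue_name) {
  rn <- toupper(residue_name)
  out <- character(length(rn))
  out[rn %in% .PEPTIDE_RESNAMES] <- "peptide"
  out[rn == "POPC"] <- "lipid_POPC"
  out[rn == "POPS"] <- "lipid_POPS"
  out[rn %in% c("CHOL", "CHL1")] <- "lipid_CHOL"
  out[rn %in% .WATER_RESNAMES] <- "water"
  out[rn %in% .ION_RESNAMES] <- "ion"
  if (any(out == "")) {
    stop("unknown residue name(s) for group inference: ",
         paste(unique(residue_name[out == ""]), collapse = ", "))
  }
  out
}

GROUP_LEVELS <- c("peptide", "lipid_POPC", "lipid_POPS", "lipid_CHOL",
                  "water", "ion")
LIPID_GROUPS <- c("lipid_POPC", "lipid_POPS", "lipid_CHOL")
SS_CLASSES <- c("E", "B", "H", "G", "I", "T", "C")
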