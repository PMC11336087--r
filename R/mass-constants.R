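#' Elemental isotope data and amino-acid mass constants
#'
#' All peptide mass arithmetic in the package is derived from a single table
#' of IUPAC monoisotopic atomic masses and isotope abundances for the five
#' elements occurring in unmodified peptides (C, H, N, O, S). Residue masses
#' are the usual "residue" convention: the amino acid minus one water, so a
#' linear peptide is the residue sum plus one water and a head-to-tail cyclic
#' peptide is the residue sum alone.
#'
#' @section Conventions:
#' * monoisotopic atomic masses: C 12 (exact), H 1.0078250319,
#'   N 14.0030740052, O 15.9949146221, S 31.97207069.
#' * each disulfide bond removes two hydrogens (cystine oxidation).
#' * MALDI ions are treated as singly protonated; proton mass 1.007276466.
#'
#' @name mass-constants
NULL

# isotope masses (Da) and fractional abundances, lightest first
.ISOTOPES <- list(
  C = list(mass = c(12.0, 13.0033548378),
           abundance = c(0.9893, 0.0107)),
  H = list(mass = c(1.0078250319, 2.0141017779),
           abundance = c(0.999885, 0.000115)),
  N = list(mass = c(14.0030740052, 15.0001088984),
           abundance = c(0.99636, 0.00364)),
  O = list(mass = c(15.9949146221, 16.9991315, 17.9991604),
           abundance = c(0.99757, 0.00038, 0.00205)),
  S = list(mass = c(31.97207069, 32.9714585, 33.96786683, 35.96708088),
           abundance = c(0.9499, 0.0075, 0.0425, 0.0001))
)

# average atomic masses (IUPAC conventional)
.AVG_ATOMIC <- c(C = 12.011, H = 1.008, N = 14.007, O = 15.999, S = 32.06)

.ELEMENTS <- c("C", "H", "N", "O", "S")

# residue elemental formulas (amino acid minus water), columns C H N O S
.RESIDUE_FORMULA <- local({
  m <- rbind(
    G = c(2, 3, 1, 1, 0),  A = c(3, 5, 1, 1, 0),  S = c(3, 5, 1, 2, 0),
    P = c(5, 7, 1, 1, 0),  V = c(5, 9, 1, 1, 0),  T = c(4, 7, 1, 2, 0),
    C = c(3, 5, 1, 1, 1),  L = c(6, 11, 1, 1, 0), I = c(6, 11, 1, 1, 0),
    N = c(4, 6, 2, 2, 0),  D = c(4, 5, 1, 3, 0),  Q = c(5, 8, 2, 2, 0),
    K = c(6, 12, 2, 1, 0), E = c(5, 7, 1, 3, 0),  M = c(5, 9, 1, 1, 1),
    H = c(6, 7, 3, 1, 0),  F = c(9, 9, 1, 1, 0),  R = c(6, 12, 4, 1, 0),
    Y = c(9, 9, 1, 2, 0),  W = c(11, 10, 2, 1, 0)
  )
  colnames(m) <- .ELEMENTS
  m
})

#' Amino-acid and small-molecule mass constants
#'
#' Returns the table of constants behind every mass computed by the package:
#' per-residue monoisotopic and average masses, water and hydrogen in both
#' conventions, and the proton mass used for the singly-protonated MALDI
#' charge convention.
#'
#' @return A list of class `mass_constants` with elements `residue_mono`,
#'   `residue_avg` (named numeric vectors over the 20 standard letters),
#'   `water_mono`, `water_avg`, `hydrogen_mono`, `hydrogen_avg` and `proton`,
#'   all in Da.
#' @examples
#' mc <- mass_constants()
#' mc$residue_mono[["G"]] + mc$water_mono  # free glycine, monoisotopic
#' @export
mass_constants <- function() {
  mono_atomic <- vapply(.ISOTOPES, function(x) x$mass[1], numeric(1))
  residue_mono <- drop(.RESIDUE_FORMULA %*% mono_atomic[.ELEMENTS])
  residue_avg <- drop(.RESIDUE_FORMULA %*% .AVG_ATOMIC[.ELEMENTS])
  structure(list(
    residue_mono = residue_mono,
    residue_avg = residue_avg,
    water_mono = 2 * mono_atomic[["H"]] + mono_atomic[["O"]],
    water_avg = 2 * .AVG_ATOMIC[["H"]] + .AVG_ATOMIC[["O"]],
    hydrogen_mono = mono_atomic[["H"]],
    hydrogen_avg = .AVG_ATOMIC[["H"]],
    proton = 1.007276466
  ), class = "mass_constants")
}

#' @export
print.mass_constants <- function(x, ...) {
  cat("<mass_constants> 20 residues; water_mono =",
      format(x$water_mono, digits = 9), "Da; proton =",
      format(x$proton, digits = 9), "Da\n")
  invisible(x)
}

#' The 20-letter amino-acid alphabet used throughout the package
#' @return Character vector of the 20 standard one-letter codes.
#' @export
amino_acid_alphabet <- function() rownames(.RESIDUE_FORMULA)
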