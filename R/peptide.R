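#' Peptide sequences with topology and oxidation state
#'
#' A `peptide_sequence` bundles a residue string with the two attributes that
#' change its mass: backbone topology (linear or head-to-tail cyclic) and the
#' number of intramolecular disulfide bonds. The cyclotide convention is
#' cyclic topology with three disulfides and exactly six cysteines.
#'
#' @param residues Single string over the 20 standard one-letter codes.
#' @param topology `"linear"` or `"cyclic"`.
#' @param disulfides Non-negative integer count of S-S bonds; at most
#'   `floor(n_cys / 2)`.
#' @return An object of class `peptide_sequence`.
#' @examples
#' kalata_s <- peptide_sequence("GLPVCGETCVGGTCNTPGCSCSWPVCTRN", "cyclic", 3)
#' peptide_mass(kalata_s)
#' @export
peptide_sequence <- function(residues, topology = c("linear", "cyclic"),
                             disulfides = 0L) {
  stopifnot(is.character(residues), length(residues) == 1L)
  topology <- match.arg(topology)
  residues <- toupper(residues)
  if (nchar(residues) == 0L) stop("peptide sequence must be non-empty")
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% amino_acid_alphabet())
  if (length(bad)) {
    stop(sprintf("invalid residue '%s' at position %d", chars[bad[1]], bad[1]))
  }
  disulfides <- as.integer(disulfides)
  if (is.na(disulfides) || disulfides < 0L) {
    stop("disulfides must be a non-negative integer")
  }
  n_cys <- sum(chars == "C")
  if (2L * disulfides > n_cys) {
    stop(sprintf("%d disulfide bond(s) require %d cysteines but only %d present",
                 disulfides, 2L * disulfides, n_cys))
  }
  structure(list(residues = residues, topology = topology,
                 disulfides = disulfides),
            class = "peptide_sequence")
}

#' Cyclotide constructor: cyclic, three disulfides
#'
#' Convenience wrapper for the cyclotide convention (head-to-tail cyclic
#' backbone, cystine knot of three disulfides).
#' @param residues Residue string; a warning is raised when the cysteine
#'   count differs from six.
#' @return A `peptide_sequence`.
#' @export
cyclotide <- function(residues) {
  n_cys <- lengths(regmatches(residues, gregexpr("C", toupper(residues))))
  if (n_cys != 6L) {
    warning(sprintf("cyclotide with %d cysteines (expected 6)", n_cys))
  }
  peptide_sequence(residues, "cyclic", 3L)
}

#' @export
print.peptide_sequence <- function(x, ...) {
  cat(sprintf("<peptide_sequence> %s, %d S-S, %d aa\n  %s\n",
              x$topology, x$disulfides, nchar(x$residues), x$residues))
  invisible(x)
}

as_peptide <- function(x) {
  if (inherits(x, "peptide_sequence")) x else cyclotide(x)
}

#' Peptide mass
#'
#' Mass of a peptide given its topology and disulfide count:
#' \deqn{M = \sum_i m_{res}(a_i) + [topology = linear]\, m_{H_2O}
#'          - 2\, n_{SS}\, m_H}
#' A head-to-tail cyclic backbone forms one extra amide bond and therefore
#' omits the terminal water; each disulfide bond removes two hydrogens.
#'
#' @param seq A `peptide_sequence` (or a string, taken as a cyclotide).
#' @param mode `"monoisotopic"` or `"average"`.
#' @param constants A [mass_constants()] list.
#' @return Mass in Da.
#' @examples
#' peptide_mass(peptide_sequence("G", "linear", 0))  # free glycine, 75.032
#' peptide_mass(cyclotide("GVPICGETCTLGTCYTAGCSCSWPVCTRN"))  # 2957.17
#' @export
peptide_mass <- function(seq, mode = c("monoisotopic", "average"),
                         constants = mass_constants()) {
  seq <- as_peptide(seq)
  mode <- match.arg(mode)
  chars <- strsplit(seq$residues, "", fixed = TRUE)[[1]]
  if (mode == "monoisotopic") {
    m <- sum(constants$residue_mono[chars]) +
      if (seq$topology == "linear") constants$water_mono else 0
    m - 2 * seq$disulfides * constants$hydrogen_mono
  } else {
    m <- sum(constants$residue_avg[chars]) +
      if (seq$topology == "linear") constants$water_avg else 0
    m - 2 * seq$disulfides * constants$hydrogen_avg
  }
}

#' Elemental composition of a peptide
#'
#' Atom counts over C, H, N, O, S for the intact molecule, honouring
#' topology (cyclic backbones lack the terminal water) and disulfide
#' oxidation (-2 H per bond).
#'
#' @inheritParams peptide_mass
#' @return Named integer vector `c(C=, H=, N=, O=, S=)`.
#' @export
elemental_composition <- function(seq) {
  seq <- as_peptide(seq)
  chars <- strsplit(seq$residues, "", fixed = TRUE)[[1]]
  comp <- colSums(.RESIDUE_FORMULA[chars, , drop = FALSE])
  if (seq$topology == "linear") comp <- comp + c(C = 0, H = 2, N = 0, O = 1, S = 0)
  comp <- comp - c(C = 0, H = 2 * seq$disulfides, N = 0, O = 0, S = 0)
  storage.mode(comp) <- "integer"
  comp
}

# distribution of one element's n atoms over neutron offsets 0..k_max,
# tracked as abundance a[k] and abundance-weighted mass m[k];
# exponentiation by squaring of the single-atom distribution
.element_power <- function(iso, n, k_max) {
  # single-atom: offset of isotope i = round(mass_i - mass_1)
  offs <- round(iso$mass - iso$mass[1])
  a1 <- numeric(k_max + 1L)
  m1 <- numeric(k_max + 1L)
  keep <- offs <= k_max
  a1[offs[keep] + 1L] <- iso$abundance[keep]
  m1[offs[keep] + 1L] <- iso$abundance[keep] * iso$mass[keep]
  conv <- function(x, y) {
    # convolve abundance (a) and first-moment (m) pairs, truncated at k_max
    a <- numeric(k_max + 1L); m <- numeric(k_max + 1L)
    for (i in seq_len(k_max + 1L)) {
      if (x$a[i] == 0 && x$m[i] == 0) next
      j <- seq_len(k_max + 2L - i)
      a[i + j - 1L] <- a[i + j - 1L] + x$a[i] * y$a[j]
      m[i + j - 1L] <- m[i + j - 1L] + x$a[i] * y$m[j] + x$m[i] * y$a[j]
    }
    list(a = a, m = m)
  }
  acc <- NULL
  base <- list(a = a1, m = m1)
  while (n > 0L) {
    if (n %% 2L == 1L) acc <- if (is.null(acc)) base else conv(acc, base)
    n <- n %/% 2L
    if (n > 0L) base <- conv(base, base)
  }
  if (is.null(acc)) {
    a <- numeric(k_max + 1L); a[1] <- 1
    acc <- list(a = a, m = numeric(k_max + 1L))
  }
  acc
}

#' Predicted isotope envelope of a singly protonated peptide
#'
#' Convolves the per-element isotope distributions over the peptide's
#' elemental composition to produce isotopologue abundances, reported as
#' \[M+H\]+ m/z values (charge 1). The envelope is truncated once the
#' cumulative abundance reaches `coverage` and renormalised to sum to one.
#'
#' @inheritParams peptide_mass
#' @param coverage Cumulative abundance at which the envelope is truncated.
#' @return An object of class `isotope_envelope`: list with `mz_values`
#'   (increasing, spaced ~1.0033 Da), `intensities` (sum to 1) and
#'   `monoisotopic_index` (always 1; the lightest isotopologue).
#' @export
predict_envelope <- function(seq, constants = mass_constants(),
                             coverage = 0.999) {
  seq <- as_peptide(seq)
  comp <- elemental_composition(seq)
  k_max <- 14L
  acc <- NULL
  for (el in .ELEMENTS) {
    if (comp[[el]] == 0L) next
    d <- .element_power(.ISOTOPES[[el]], comp[[el]], k_max)
    acc <- if (is.null(acc)) d else {
      a <- numeric(k_max + 1L); m <- numeric(k_max + 1L)
      for (i in seq_len(k_max + 1L)) {
        if (acc$a[i] == 0 && acc$m[i] == 0) next
        j <- seq_len(k_max + 2L - i)
        a[i + j - 1L] <- a[i + j - 1L] + acc$a[i] * d$a[j]
        m[i + j - 1L] <- m[i + j - 1L] + acc$a[i] * d$m[j] + acc$m[i] * d$a[j]
      }
      list(a = a, m = m)
    }
  }
  ab <- acc$a
  n_trunc <- which(cumsum(ab) / sum(ab) >= coverage)[1]
  idx <- seq_len(n_trunc)
  intens <- ab[idx] / sum(ab[idx])
  # peak positions follow the standard uniform 13C-12C spacing convention;
  # the exact monoisotopic mass anchors the envelope
  mono <- peptide_mass(seq, "monoisotopic", constants)
  spacing <- .ISOTOPES$C$mass[2] - .ISOTOPES$C$mass[1]
  structure(list(
    mz_values = mono + (idx - 1L) * spacing + constants$proton,
    intensities = intens,
    monoisotopic_index = 1L
  ), class = "isotope_envelope")
}

#' @export
print.isotope_envelope <- function(x, ...) {
  cat(sprintf("<isotope_envelope> %d isotopologues, mono m/z %.4f\n",
              length(x$mz_values), x$mz_values[x$monoisotopic_index]))
  invisible(x)
}
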