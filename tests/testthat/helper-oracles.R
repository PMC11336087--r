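# Independent oracles and shared fixtures for the test suite.

ref_table <- viwe_reference()

# complete reference entries with the canonical six cysteines
ref6 <- ref_table[ref_table$complete &
                    vapply(ref_table$sequence, function(s) {
                      sum(strsplit(s, "")[[1]] == "C") == 6L
                    }, logical(1)), ]

# pick n reference peptides whose masses are pairwise > min_sep apart
pick_separated <- function(n, min_sep = 8) {
  o <- order(ref6$calculated_mw)
  sel <- integer()
  for (i in o) {
    if (!length(sel) ||
        all(abs(ref6$calculated_mw[i] - ref6$calculated_mw[sel]) > min_sep)) {
      sel <- c(sel, i)
    }
  }
  ref6[sel[round(seq(1, length(sel), length.out = n))], ]
}

# ---- motif oracle: translate a compiled pattern to a regex and find all
# (start, end) matches by brute force over start positions and wildcard
# repeat counts, using R's own regex engine --------------------------------
regex_motif_matches <- function(protein, pattern) {
  if (!inherits(pattern, "motif_pattern")) pattern <- compile_motif(pattern)
  els <- unclass(pattern)
  aa <- paste(amino_acid_alphabet(), collapse = "")
  piece <- function(el, k) {
    base <- if (is.null(el$residues)) paste0("[", aa, "]")
            else paste0("[", paste(el$residues, collapse = ""), "]")
    if (k == 0L) "" else paste0(base, "{", k, "}")
  }
  # enumerate every combination of repeat counts; find all (overlapping)
  # occurrences of each fixed-length realisation with a lookahead regex
  grids <- lapply(els, function(el) el$min:el$max)
  combos <- expand.grid(grids)
  out <- NULL
  for (ci in seq_len(nrow(combos))) {
    rx <- paste0(mapply(piece, els, unlist(combos[ci, ])), collapse = "")
    len <- sum(unlist(combos[ci, ]))
    if (len == 0L) next
    m <- gregexpr(paste0("(?=", rx, ")"), protein, perl = TRUE)[[1]]
    starts <- m[m > 0L]
    if (length(starts)) out <- rbind(out, cbind(starts, starts + len - 1L))
  }
  if (is.null(out)) return(data.frame(start = integer(), end = integer()))
  out <- unique(data.frame(start = out[, 1], end = out[, 2]))
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ---- Smith-Waterman oracle: quadratic DP, affine gaps (open 11, extend 1),
# BLOSUM62 ------------------------------------------------------------------
sw_score_oracle <- function(a, b, gap_open = 11, gap_ext = 1) {
  m62 <- local({
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    e$BLOSUM62
  })
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  M <- Ix <- Iy <- matrix(-Inf, n + 1L, m + 1L)
  M[1, ] <- 0; M[, 1] <- 0
  best <- 0
  for (i in 2:(n + 1L)) {
    for (j in 2:(m + 1L)) {
      s <- m62[av[i - 1L], bv[j - 1L]]
      Ix[i, j] <- max(M[i - 1L, j] - gap_open - gap_ext,
                      Ix[i - 1L, j] - gap_ext)
      Iy[i, j] <- max(M[i, j - 1L] - gap_open - gap_ext,
                      Iy[i, j - 1L] - gap_ext)
      M[i, j] <- max(0, s + max(M[i - 1L, j - 1L], Ix[i - 1L, j - 1L],
                                Iy[i - 1L, j - 1L]))
      best <- max(best, M[i, j], Ix[i, j], Iy[i, j])
    }
  }
  best
}

# random protein string over the full alphabet
random_protein <- function(len) {
  paste(sample(amino_acid_alphabet(), len, replace = TRUE), collapse = "")
}

# random motif pattern over a small element vocabulary
random_pattern <- function() {
  n_el <- sample(3:6, 1)
  els <- vapply(seq_len(n_el), function(i) {
    kind <- sample(c("fixed", "set", "wild"), 1,
                   prob = c(0.5, 0.3, 0.2))
    if (kind == "fixed") sample(amino_acid_alphabet(), 1)
    else if (kind == "set") {
      paste0("[", paste(sample(amino_acid_alphabet(), sample(2:3, 1)),
                        collapse = ""), "]")
    } else {
      lo <- sample(0:1, 1)
      paste0("x(", lo, ",", lo + sample(0:2, 1), ")")
    }
  }, character(1))
  paste(els, collapse = "-")
}

# embed a mature domain in a precursor-like protein with fixed flanking
# regions free of boundary-confusable residues near the junctions
embed_domain <- function(domain, lead = "MAKLTVLFAVLLLFAA",
                         tail = "LPALEAEKL") {
  paste0(lead, domain, tail)
}

# quick cyclic oxidised mass for a sequence string
cyc_mass <- function(s) {
  n_cys <- nchar(s) - nchar(gsub("C", "", s))
  peptide_mass(peptide_sequence(s, "cyclic", min(3L, n_cys %/% 2L)))
}
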