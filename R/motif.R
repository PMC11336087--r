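#' PROSITE-style motif patterns
#'
#' Cyclotide mining uses a fuzzy PROSITE-style pattern over amino-acid
#' positions. The supported syntax covers single fixed residues (`C`),
#' alternative sets (`[ES]`), and bounded wildcard repeats (`x(0,1)`,
#' `x(2)`, or bare `x`), with positions joined by `-`. Matching is
#' case-insensitive; the translation artefacts `X` (unknown residue) and
#' `*` (stop) never match any element, wildcards included.
#'
#' The loop-6/loop-1 pattern used for bracelet-type cyclotides is available
#' as [cyclotide_motif()].
#'
#' @name motif
NULL

#' Default cyclotide detection pattern
#'
#' The bracelet-type loop pattern spanning cysteines I-III:
#' `C-x(0,1)-[ES]-S-C-[AV]-[MFYW]-I-[PS]-x(0,1)-C`.
#' @return Compiled `motif_pattern`.
#' @export
cyclotide_motif <- function() {
  compile_motif("C-x(0,1)-[ES]-S-C-[AV]-[MFYW]-I-[PS]-x(0,1)-C")
}

#' Compile a PROSITE-style pattern
#'
#' @param pattern_text Pattern string, e.g. `"C-x(0,1)-[ES]-S-C"`.
#' @return A `motif_pattern`: list of elements, each with `residues`
#'   (character vector, or `NULL` for a wildcard), `min` and `max` repeat
#'   counts; attributes `min_span`/`max_span` give the total length bounds
#'   and `source_text` the input. Malformed syntax raises an error naming
#'   the character offset.
#' @examples
#' p <- compile_motif("C-x(0,1)-C")
#' attr(p, "min_span"); attr(p, "max_span")
#' @export
compile_motif <- function(pattern_text) {
  stopifnot(is.character(pattern_text), length(pattern_text) == 1L)
  txt <- toupper(gsub("[.> <]", "", pattern_text))
  chars <- strsplit(txt, "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (n == 0L) stop("empty motif pattern")
  alpha <- amino_acid_alphabet()
  elements <- list()
  i <- 1L
  parse_repeat <- function(i) {
    # chars[i] == "(": read (n) or (n,m); returns list(min, max, next_i)
    j <- i + 1L
    digits1 <- ""
    while (j <= n && grepl("[0-9]", chars[j])) {
      digits1 <- paste0(digits1, chars[j]); j <- j + 1L
    }
    if (digits1 == "") stop(sprintf("malformed repeat at offset %d", i))
    if (j <= n && chars[j] == ",") {
      j <- j + 1L
      digits2 <- ""
      while (j <= n && grepl("[0-9]", chars[j])) {
        digits2 <- paste0(digits2, chars[j]); j <- j + 1L
      }
      if (digits2 == "") stop(sprintf("malformed repeat at offset %d", j))
    } else digits2 <- digits1
    if (j > n || chars[j] != ")") {
      stop(sprintf("unclosed repeat parenthesis at offset %d", i))
    }
    lo <- as.integer(digits1); hi <- as.integer(digits2)
    if (hi < lo) stop(sprintf("repeat maximum below minimum at offset %d", i))
    list(min = lo, max = hi, next_i = j + 1L)
  }
  while (i <= n) {
    ch <- chars[i]
    if (ch == "-") { i <- i + 1L; next }
    if (ch == "[") {
      j <- i + 1L
      set <- character()
      while (j <= n && chars[j] != "]") {
        if (!chars[j] %in% alpha) {
          stop(sprintf("invalid residue '%s' in set at offset %d", chars[j], j))
        }
        set <- c(set, chars[j]); j <- j + 1L
      }
      if (j > n) stop(sprintf("unclosed '[' at offset %d", i))
      if (!length(set)) stop(sprintf("empty residue set at offset %d", i))
      el <- list(residues = unique(set), min = 1L, max = 1L)
      i <- j + 1L
    } else if (ch == "X") {
      el <- list(residues = NULL, min = 1L, max = 1L)
      i <- i + 1L
    } else if (ch %in% alpha) {
      el <- list(residues = ch, min = 1L, max = 1L)
      i <- i + 1L
    } else {
      stop(sprintf("unexpected character '%s' at offset %d", ch, i))
    }
    if (i <= n && chars[i] == "(") {
      rep <- parse_repeat(i)
      el$min <- rep$min; el$max <- rep$max
      i <- rep$next_i
    }
    elements[[length(elements) + 1L]] <- el
  }
  if (!length(elements)) stop("pattern contains no elements")
  structure(elements,
            class = "motif_pattern",
            source_text = pattern_text,
            min_span = sum(vapply(elements, `[[`, integer(1), "min")),
            max_span = sum(vapply(elements, `[[`, integer(1), "max")))
}

#' Render a compiled pattern back to PROSITE-style text
#' @param x A `motif_pattern`.
#' @param ... Unused.
#' @return Pattern string equivalent (in match behaviour) to the source.
#' @method format motif_pattern
#' @export
format.motif_pattern <- function(x, ...) {
  parts <- vapply(unclass(x), function(el) {
    base <- if (is.null(el$residues)) "x"
            else if (length(el$residues) == 1L) el$residues
            else paste0("[", paste(el$residues, collapse = ""), "]")
    if (el$min == 1L && el$max == 1L) base
    else if (el$min == el$max) sprintf("%s(%d)", base, el$min)
    else sprintf("%s(%d,%d)", base, el$min, el$max)
  }, character(1))
  paste(parts, collapse = "-")
}

#' @export
print.motif_pattern <- function(x, ...) {
  cat("<motif_pattern>", format(x), "\n")
  cat(sprintf("  %d elements, span %d-%d\n", length(x),
              attr(x, "min_span"), attr(x, "max_span")))
  invisible(x)
}

#' Scan a protein for all motif occurrences
#'
#' Exhaustive fuzzy matcher: every wildcard repeat count is enumerated, so
#' overlapping occurrences and alternative spans from the same start are all
#' reported. `X` and `*` in the protein never match.
#'
#' @param protein Protein string (may contain `*` stops and `X`).
#' @param pattern A `motif_pattern` or pattern text.
#' @return Data frame with 1-based inclusive `start`, `end` columns, sorted
#'   by start then end; zero rows when nothing matches.
#' @examples
#' motif_scan("CCAC", compile_motif("C-x(0,1)-C"))
#' @export
motif_scan <- function(protein, pattern) {
  if (!inherits(pattern, "motif_pattern")) pattern <- compile_motif(pattern)
  protein <- toupper(protein)
  chars <- strsplit(protein, "", fixed = TRUE)[[1]]
  np <- length(chars)
  alpha <- amino_acid_alphabet()
  is_aa <- chars %in% alpha
  elements <- unclass(pattern)
  ne <- length(elements)
  # matches_at[[e]][p]: TRUE if one unit of element e matches position p
  unit_ok <- lapply(elements, function(el) {
    if (is.null(el$residues)) is_aa else is_aa & chars %in% el$residues
  })
  out_start <- integer(); out_end <- integer()
  min_span <- attr(pattern, "min_span")
  if (np >= min_span && np > 0L) {
    # ends[[e]] after processing element e = set of next positions
    for (s in seq_len(np - min_span + 1L)) {
      frontier <- s  # candidate next positions (1-based index of next char)
      for (e in seq_len(ne)) {
        el <- elements[[e]]
        nxt <- integer()
        for (p in frontier) {
          q <- p
          # consume min units
          ok <- TRUE
          if (el$min > 0L) {
            for (k in seq_len(el$min)) {
              if (q > np || !unit_ok[[e]][q]) { ok <- FALSE; break }
              q <- q + 1L
            }
          }
          if (!ok) next
          nxt <- c(nxt, q)
          if (el$max > el$min) {
            for (k in seq_len(el$max - el$min)) {
              if (q > np || !unit_ok[[e]][q]) break
              q <- q + 1L
              nxt <- c(nxt, q)
            }
          }
        }
        frontier <- unique(nxt)
        if (!length(frontier)) break
      }
      if (length(frontier)) {
        out_start <- c(out_start, rep.int(s, length(frontier)))
        out_end <- c(out_end, frontier - 1L)
      }
    }
  }
  res <- unique(data.frame(start = out_start, end = out_end))
  res <- res[order(res$start, res$end), , drop = FALSE]
  rownames(res) <- NULL
  res
}
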