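#' Transcriptome mining for cyclotide precursors
#'
#' [mine_cyclotides()] scans assembled contigs in all six reading frames for
#' cyclotide mature domains, using the union of two detectors: the fuzzy
#' loop motif ([cyclotide_motif()]) and Smith-Waterman local similarity
#' against a reference database (BLOSUM62, gap open 11 / extend 1). Anchors
#' from both detectors are merged, expanded to the six-cysteine mature
#' domain, deduplicated, checked against the cyclotide loop architecture,
#' and named: known sequences keep their reference names, novel ones are
#' numbered by increasing calculated mass under a species prefix.
#'
#' @name mining
NULL

#' Six-frame translation of a contig
#'
#' Standard genetic code; the trailing partial codon is dropped, stop codons
#' render as `*`, codons containing `N` translate to `X`, and the reverse
#' frames translate the reverse complement.
#'
#' @param nucleotides Contig sequence over `A,C,G,T,N` (length >= 3).
#' @return Named character vector of proteins for frames
#'   `+1,+2,+3,-1,-2,-3`.
#' @export
six_frame_translate <- function(nucleotides) {
  stopifnot(is.character(nucleotides), length(nucleotides) == 1L)
  nt <- toupper(nucleotides)
  chars <- strsplit(nt, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% c("A", "C", "G", "T", "N"))
  if (length(bad)) {
    stop(sprintf("invalid nucleotide '%s' at position %d", chars[bad[1]], bad[1]))
  }
  if (nchar(nt) < 3L) stop("contig shorter than one codon")
  rev <- .revcomp(nt)
  code <- .codon_to_aa()
  tr <- function(s, off) {
    len <- nchar(s) - off
    len <- len - len %% 3L
    if (len < 3L) return("")
    starts <- seq.int(off + 1L, off + len, by = 3L)
    aa <- code[substring(s, starts, starts + 2L)]
    aa[is.na(aa)] <- "X"  # codons containing N
    paste(aa, collapse = "")
  }
  c(`+1` = tr(nt, 0L), `+2` = tr(nt, 1L), `+3` = tr(nt, 2L),
    `-1` = tr(rev, 0L), `-2` = tr(rev, 1L), `-3` = tr(rev, 2L))
}

.revcomp <- function(nt) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", nt), "", fixed = TRUE)[[1]]),
        collapse = "")
}

.codon_to_aa <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- Biostrings::GENETIC_CODE
    cache
  }
})

#' Smith-Waterman similarity search against a reference database
#'
#' Local alignment of every reference mature domain against a protein,
#' BLOSUM62 with gap open 11 / extend 1 (the short cyclotide domains make
#' exact Smith-Waterman affordable in place of a heuristic search). Hits
#' with score >= `min_score` are merged into maximal intervals, each
#' annotated with its best-scoring reference.
#'
#' @param protein Protein string.
#' @param refs Data frame with `name` and `sequence` columns.
#' @param min_score Minimum alignment score to report.
#' @return Data frame `start`, `end` (1-based inclusive maximal merged
#'   interval on the protein), `best_reference`, `score`, `identity`
#'   (percent identity of the best local alignment), and `best_start`,
#'   `best_end` (the best-scoring reference's own alignment interval, used
#'   as the extraction anchor).
#' @export
similarity_search <- function(protein, refs, min_score = 50) {
  stopifnot(nrow(refs) > 0)
  empty <- data.frame(start = integer(), end = integer(),
                      best_reference = character(), score = numeric(),
                      identity = numeric(), best_start = integer(),
                      best_end = integer())
  if (!nzchar(protein)) return(empty)
  pats <- Biostrings::AAStringSet(stats::setNames(refs$sequence, refs$name))
  al <- Biostrings::pairwiseAlignment(
    pats, Biostrings::AAString(protein), type = "local",
    substitutionMatrix = .blosum62(), gapOpening = 11, gapExtension = 1)
  sc <- Biostrings::score(al)
  keep <- which(sc >= min_score)
  if (!length(keep)) return(empty)
  sub <- Biostrings::subject(al)
  hits <- data.frame(
    start = Biostrings::start(sub)[keep],
    end = Biostrings::end(sub)[keep],
    best_reference = refs$name[keep],
    score = sc[keep],
    identity = Biostrings::pid(al)[keep])
  hits$best_start <- hits$start
  hits$best_end <- hits$end
  # merge overlapping intervals, keep best-scoring annotation per interval
  hits <- hits[order(hits$start, hits$end), , drop = FALSE]
  merged <- hits[1, , drop = FALSE]
  if (nrow(hits) > 1L) for (i in 2:nrow(hits)) {
    last <- nrow(merged)
    if (hits$start[i] <= merged$end[last]) {
      merged$end[last] <- max(merged$end[last], hits$end[i])
      if (hits$score[i] > merged$score[last]) {
        merged[last, c("best_reference", "score", "identity",
                       "best_start", "best_end")] <-
          hits[i, c("best_reference", "score", "identity",
                    "best_start", "best_end")]
      }
    } else merged <- rbind(merged, hits[i, ])
  }
  rownames(merged) <- NULL
  merged
}

.blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

# loop-length plausibility envelope for a six-cysteine cyclotide domain,
# derived from the packaged reference set with one residue of slack per loop
.LOOP_BOUNDS <- list(l1 = c(2L, 4L), l2 = c(3L, 6L), l3 = c(3L, 8L),
                     l4 = c(1L, 2L), l5 = c(3L, 6L))

#' Check cyclotide loop architecture
#'
#' A six-cysteine domain is plausible when its five inter-cysteine loop
#' lengths fall inside the envelope spanned by the reference cyclotides
#' (with one residue of slack per loop). Used to reject composition-matched
#' decoys that carry six cysteines in a scrambled arrangement.
#'
#' @param sequence Mature-domain candidate.
#' @param partial Allow truncated domains: the observed inter-cysteine gaps
#'   must then match some contiguous run of the loop-bound list (covers
#'   domains cut at either end before all six cysteines).
#' @return `TRUE`/`FALSE`.
#' @export
plausible_loops <- function(sequence, partial = FALSE) {
  cys <- gregexpr("C", toupper(sequence), fixed = TRUE)[[1]]
  if (cys[1] == -1L) return(FALSE)
  gaps <- if (length(cys) > 1L) diff(cys) - 1L else integer(0)
  fits <- function(g, bounds) {
    all(vapply(seq_along(g), function(i) {
      b <- bounds[[i]]
      g[i] >= b[1] && g[i] <= b[2]
    }, logical(1)))
  }
  if (!partial) {
    return(length(cys) == 6L && fits(gaps, .LOOP_BOUNDS))
  }
  if (length(cys) > 6L) return(FALSE)
  if (!length(gaps)) return(TRUE)
  m <- length(gaps)
  any(vapply(seq_len(5L - m + 1L), function(j) {
    fits(gaps, .LOOP_BOUNDS[j:(j + m - 1L)])
  }, logical(1)))
}

#' Expand a detection anchor to the mature cyclotide domain
#'
#' Expands an anchor interval (from motif or similarity search) to the
#' minimal window holding six cysteines, then fixes the boundaries: the
#' domain starts at the conserved Gly/Ser-rich N-terminus (1-5 residues
#' before cysteine I; the anchor start is kept when it already sits on a
#' G/S in that window) and ends at the Asn/Asp cyclisation residue (the
#' last N/D within 5 residues after cysteine VI). When fewer than six
#' cysteines are available before a stop, the longest prefix is returned
#' and flagged incomplete.
#'
#' @param protein Protein string (one translated frame).
#' @param anchor_start,anchor_end 1-based inclusive anchor interval.
#' @return List: `sequence`, `start`, `end` (1-based inclusive), `complete`.
#' @export
extract_mature_domain <- function(protein, anchor_start, anchor_end) {
  protein <- toupper(protein)
  np <- nchar(protein)
  stopifnot(anchor_start >= 1L, anchor_end <= np, anchor_start <= anchor_end)
  chars <- strsplit(protein, "", fixed = TRUE)[[1]]
  # restrict to the stop-free segment containing the anchor
  stops <- which(chars == "*")
  seg_start <- max(c(0L, stops[stops < anchor_start])) + 1L
  seg_end <- min(c(np + 1L, stops[stops > anchor_end])) - 1L
  cys <- seg_start - 1L + which(chars[seg_start:seg_end] == "C")
  incomplete_prefix <- function(from) {
    to <- seg_end
    list(sequence = substr(protein, from, to), start = from, end = to,
         complete = FALSE)
  }
  if (length(cys) < 6L) {
    return(incomplete_prefix(max(seg_start, anchor_start)))
  }
  # choose the 6-cysteine window whose cysteines sit inside the anchor
  # (ties broken by interval overlap, then by the earlier window)
  n_win <- length(cys) - 5L
  n_inside <- vapply(seq_len(n_win), function(i) {
    sum(cys[i:(i + 5L)] >= anchor_start & cys[i:(i + 5L)] <= anchor_end)
  }, integer(1))
  overlap <- vapply(seq_len(n_win), function(i) {
    max(0L, min(cys[i + 5L], anchor_end) - max(cys[i], anchor_start) + 1L)
  }, integer(1))
  w <- order(-n_inside, -overlap)[1]
  c1 <- cys[w]; c6 <- cys[w + 5L]
  # N-terminal boundary: G/S within 5 residues before cysteine I
  lead_lo <- max(seg_start, c1 - 5L)
  start <- NA_integer_
  if (anchor_start >= lead_lo && anchor_start < c1 &&
      chars[anchor_start] %in% c("G", "S")) {
    start <- anchor_start
  } else if (c1 > seg_start) {
    win <- lead_lo:(c1 - 1L)
    gs <- win[chars[win] %in% c("G", "S")]
    if (length(gs)) start <- gs[1]
  }
  if (is.na(start)) {
    if (c1 == seg_start) return(incomplete_prefix(seg_start))
    start <- max(seg_start, c1 - 3L)
    complete_start <- FALSE
  } else complete_start <- TRUE
  # C-terminal boundary: last N/D within 5 residues after cysteine VI
  tail_hi <- min(seg_end, c6 + 5L)
  end <- NA_integer_
  if (anchor_end > c6 && anchor_end <= tail_hi &&
      chars[anchor_end] %in% c("N", "D")) {
    end <- anchor_end
  } else if (c6 < seg_end) {
    win <- (c6 + 1L):tail_hi
    nd <- win[chars[win] %in% c("N", "D")]
    if (length(nd)) end <- nd[length(nd)]
  }
  if (is.na(end)) {
    end <- min(seg_end, c6 + 3L)
    complete_end <- FALSE
  } else complete_end <- TRUE
  list(sequence = substr(protein, start, end), start = start, end = end,
       complete = complete_start && complete_end)
}

#' Deduplicate, classify novelty and name cyclotide hits
#'
#' Hits with identical mature sequences collapse to one. A hit is novel iff
#' its mature sequence matches no reference sequence exactly; known hits
#' take the reference name, novel hits are numbered `<prefix> 1..k` in
#' order of increasing calculated mass.
#'
#' @param hits Data frame of hits with `mature_sequence` and
#'   `calculated_mw` columns.
#' @param refs Reference data frame (`name`, `sequence`).
#' @param species_prefix Short species code used for novel names.
#' @return The hits with `novel` and `name` columns, novel ones ordered by
#'   mass within the numbering.
#' @export
classify_and_name <- function(hits, refs, species_prefix = "syn") {
  if (!nrow(hits)) {
    hits$novel <- logical(0); hits$name <- character(0)
    return(hits)
  }
  hits <- hits[!duplicated(hits$mature_sequence), , drop = FALSE]
  idx <- match(hits$mature_sequence, refs$sequence)
  hits$novel <- is.na(idx)
  hits$name <- ifelse(hits$novel, NA_character_, refs$name[idx])
  novel_rows <- which(hits$novel)
  if (length(novel_rows)) {
    ord <- novel_rows[order(hits$calculated_mw[novel_rows])]
    hits$name[ord] <- paste(species_prefix, seq_along(ord))
  }
  rownames(hits) <- NULL
  hits
}

#' Match calculated cyclotide masses to observed masses
#'
#' Each observed mass is assigned to the nearest hit within `tolerance`;
#' when several hits tie for nearest (in particular isobaric I/L isomers),
#' every tied pairing is reported with `ambiguous = TRUE` rather than
#' silently picking one.
#'
#' @param hits Data frame with `name` and `calculated_mw` columns.
#' @param observed_masses Numeric vector of neutral monoisotopic masses (Da).
#' @param tolerance Maximum |calculated - observed| in Da.
#' @return Data frame `observed_mass`, `name`, `calculated_mw`, `delta`,
#'   `ambiguous`.
#' @export
match_masses <- function(hits, observed_masses, tolerance = 0.05) {
  stopifnot(tolerance > 0)
  out <- lapply(observed_masses, function(m) {
    d <- abs(hits$calculated_mw - m)
    within <- which(d <= tolerance)
    if (!length(within)) return(NULL)
    best <- min(d[within])
    tied <- within[d[within] <= best + 1e-9]
    data.frame(observed_mass = m, name = hits$name[tied],
               calculated_mw = hits$calculated_mw[tied],
               delta = hits$calculated_mw[tied] - m,
               ambiguous = length(tied) > 1L)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(observed_mass = numeric(), name = character(),
                      calculated_mw = numeric(), delta = numeric(),
                      ambiguous = logical())
  }
  rownames(out) <- NULL
  out
}

#' Mine contigs for cyclotide mature domains
#'
#' Full mining stage: six-frame translation, per-segment motif and
#' similarity detection, anchor merging, mature-domain extraction, loop
#' architecture filtering, deduplication and naming.
#'
#' @param contigs Named character vector of nucleotide contigs (see
#'   [read_contigs()]).
#' @param refs Reference database data frame (`name`, `sequence`); defaults
#'   to the packaged table.
#' @param motif Compiled detection pattern.
#' @param min_score Smith-Waterman score threshold.
#' @param min_segment Minimum stop-free segment length (residues) to scan.
#' @param species_prefix Prefix for novel hit names.
#' @param require_plausible_loops Drop hits whose inter-cysteine loop
#'   lengths fall outside the reference envelope (guards against scrambled
#'   decoys; incomplete hits are checked against a sliding partial fit).
#' @param min_cys_incomplete Minimum cysteine count for an incomplete hit
#'   to be reported; fragments with fewer cysteines carry too little of the
#'   cystine knot to count as cyclotide evidence.
#' @param min_score_incomplete Similarity-only incomplete hits (no motif
#'   match, boundaries not corroborated) must reach this alignment score;
#'   truncated precursors of genuine cyclotides align to their homologues
#'   far above it, while chance alignments of scrambled sequences sit near
#'   the reporting threshold.
#' @return Data frame of hits: `contig_id`, `frame`, `start`, `end`
#'   (interval of the mature domain in the translated frame),
#'   `mature_sequence`, `detection` (`motif`, `similarity` or `both`),
#'   `best_reference`, `score`, `identity`, `complete`, `calculated_mw`,
#'   `novel`, `name`.
#' @export
mine_cyclotides <- function(contigs, refs = viwe_reference(),
                            motif = cyclotide_motif(), min_score = 50,
                            min_segment = 25L, species_prefix = "syn",
                            require_plausible_loops = TRUE,
                            min_cys_incomplete = 4L,
                            min_score_incomplete = 80) {
  rows <- list()
  for (cid in names(contigs)) {
    frames <- six_frame_translate(contigs[[cid]])
    for (fr in names(frames)) {
      prot <- frames[[fr]]
      if (!nzchar(prot)) next
      segs <- .stop_free_segments(prot, min_segment)
      for (k in seq_len(nrow(segs))) {
        seg_seq <- substr(prot, segs$start[k], segs$end[k])
        # a cyclotide domain needs cysteines; skip cysteine-poor segments
        if (nchar(seg_seq) - nchar(gsub("C", "", seg_seq)) < 3L) next
        anchors <- .detect_anchors(seg_seq, refs, motif, min_score)
        if (!nrow(anchors)) next
        for (a in seq_len(nrow(anchors))) {
          dom <- extract_mature_domain(seg_seq, anchors$anchor_start[a],
                                       anchors$anchor_end[a])
          n_cys <- sum(strsplit(dom$sequence, "")[[1]] == "C")
          if (n_cys < 2L) next
          pep <- peptide_sequence(dom$sequence, "cyclic",
                                  min(3L, n_cys %/% 2L))
          rows[[length(rows) + 1L]] <- data.frame(
            contig_id = cid, frame = fr,
            start = segs$start[k] + dom$start - 1L,
            end = segs$start[k] + dom$end - 1L,
            mature_sequence = dom$sequence,
            detection = anchors$detection[a],
            best_reference = anchors$best_reference[a],
            score = anchors$score[a], identity = anchors$identity[a],
            complete = dom$complete,
            calculated_mw = peptide_mass(pep))
        }
      }
    }
  }
  hits <- if (length(rows)) do.call(rbind, rows) else data.frame(
    contig_id = character(), frame = character(), start = integer(),
    end = integer(), mature_sequence = character(), detection = character(),
    best_reference = character(), score = numeric(), identity = numeric(),
    complete = logical(), calculated_mw = numeric())
  if (nrow(hits)) {
    n_cys <- nchar(hits$mature_sequence) -
      nchar(gsub("C", "", hits$mature_sequence))
    strong <- hits$detection != "similarity" |
      (!is.na(hits$score) & hits$score >= min_score_incomplete)
    hits <- hits[hits$complete |
                   (n_cys >= min_cys_incomplete & strong), , drop = FALSE]
  }
  if (require_plausible_loops && nrow(hits)) {
    ok <- vapply(seq_len(nrow(hits)), function(i) {
      plausible_loops(hits$mature_sequence[i], partial = !hits$complete[i])
    }, logical(1))
    hits <- hits[ok, , drop = FALSE]
  }
  classify_and_name(hits, refs, species_prefix)
}

.stop_free_segments <- function(protein, min_segment) {
  chars <- strsplit(protein, "", fixed = TRUE)[[1]]
  runs <- rle(chars != "*")
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values & runs$lengths >= min_segment
  data.frame(start = starts[keep], end = ends[keep])
}

# union of motif and similarity detections on one stop-free segment;
# overlapping detections merge into one anchor (detection provenance kept).
# The extraction anchor (anchor_start/anchor_end) is the most informative
# interval in the group: the best similarity alignment when present (its
# boundaries track the reference domain), otherwise the motif interval.
.detect_anchors <- function(seg_seq, refs, motif, min_score) {
  mo <- motif_scan(seg_seq, motif)
  sim <- similarity_search(seg_seq, refs, min_score)
  anchors <- rbind(
    if (nrow(mo)) data.frame(start = mo$start, end = mo$end,
                             detection = "motif",
                             best_reference = NA_character_,
                             score = NA_real_, identity = NA_real_,
                             anchor_start = mo$start, anchor_end = mo$end),
    if (nrow(sim)) data.frame(start = sim$start, end = sim$end,
                              detection = "similarity",
                              best_reference = sim$best_reference,
                              score = sim$score, identity = sim$identity,
                              anchor_start = sim$best_start,
                              anchor_end = sim$best_end))
  if (is.null(anchors) || !nrow(anchors)) {
    return(data.frame(start = integer(), end = integer(),
                      detection = character(), best_reference = character(),
                      score = numeric(), identity = numeric(),
                      anchor_start = integer(), anchor_end = integer()))
  }
  anchors <- anchors[order(anchors$start, anchors$end), , drop = FALSE]
  merged <- anchors[1, , drop = FALSE]
  if (nrow(anchors) > 1L) for (i in 2:nrow(anchors)) {
    last <- nrow(merged)
    if (anchors$start[i] <= merged$end[last]) {
      merged$end[last] <- max(merged$end[last], anchors$end[i])
      if (anchors$detection[i] != merged$detection[last]) {
        merged$detection[last] <- "both"
      }
      if (!is.na(anchors$score[i]) &&
          (is.na(merged$score[last]) || anchors$score[i] > merged$score[last])) {
        merged[last, c("best_reference", "score", "identity",
                       "anchor_start", "anchor_end")] <-
          anchors[i, c("best_reference", "score", "identity",
                       "anchor_start", "anchor_end")]
      }
    } else merged <- rbind(merged, anchors[i, ])
  }
  rownames(merged) <- NULL
  merged
}
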