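test_that("six-frame translation follows the standard code", {
  expect_identical(six_frame_translate("ATGGGT")[["+1"]], "MG")
  fr <- six_frame_translate("ATGGCGTAATTTGGG")
  expect_match(fr[["+1"]], "\\*")  # stop rendered as *
  # N-containing codons translate to X
  expect_identical(six_frame_translate("ATGNNN")[["+1"]], "MX")
  # reverse frames = forward frames of the reverse complement
  set.seed(20)
  nt <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
              collapse = "")
  rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", nt), "")[[1]]),
              collapse = "")
  expect_identical(six_frame_translate(nt)[["-1"]],
                   six_frame_translate(rc)[["+1"]])
  expect_error(six_frame_translate("ATGU"), "U.*position 4")
})

test_that("translation agrees with the Biostrings oracle on random contigs", {
  set.seed(21)
  for (k in 1:5) {
    nt <- paste(sample(c("A", "C", "G", "T"), 3 * sample(40:100, 1),
                       replace = TRUE), collapse = "")
    mine <- six_frame_translate(nt)
    fwd <- Biostrings::DNAString(nt)
    rev <- Biostrings::reverseComplement(fwd)
    for (off in 0:2) {
      len <- nchar(nt) - off
      len <- len - len %% 3
      oracle_f <- as.character(Biostrings::translate(
        Biostrings::subseq(fwd, off + 1, width = len), no.init.codon = TRUE))
      oracle_r <- as.character(Biostrings::translate(
        Biostrings::subseq(rev, off + 1, width = len), no.init.codon = TRUE))
      expect_identical(mine[[paste0("+", off + 1)]], oracle_f)
      expect_identical(mine[[paste0("-", off + 1)]], oracle_r)
    }
  }
})

test_that("similarity search scores match a dynamic-programming oracle", {
  refs <- ref6[c(1, 30, 60), c("name", "sequence")]
  subject <- embed_domain(ref6$sequence[30])
  hits <- similarity_search(subject, refs, min_score = 30)
  expect_gt(nrow(hits), 0)
  best <- hits[which.max(hits$score), ]
  expect_equal(best$identity, 100)
  oracle <- max(vapply(refs$sequence, sw_score_oracle, numeric(1),
                       b = subject))
  expect_equal(best$score, oracle)
  # a scrambled decoy with identical composition scores strictly lower
  set.seed(8)
  decoy <- paste(sample(strsplit(ref6$sequence[30], "")[[1]]), collapse = "")
  decoy_hits <- similarity_search(embed_domain(decoy), refs, min_score = 0)
  expect_lt(max(decoy_hits$score), best$score)
})

test_that("self-hits align full length at 100% identity", {
  refs <- ref6[1:10, c("name", "sequence")]
  hits <- similarity_search(ref6$sequence[4], refs, min_score = 50)
  top <- hits[which.max(hits$score), ]
  expect_equal(top$identity, 100)
  expect_identical(top$best_reference, ref6$name[4])
  expect_identical(c(top$best_start, top$best_end),
                   c(1L, nchar(ref6$sequence[4])))
})

test_that("mature domains are recovered exactly from precursor context", {
  # every complete six-cysteine reference sequence, planted in a fixed
  # precursor context, comes back verbatim and ends in Asn/Asp
  for (i in seq_len(nrow(ref6))) {
    dom <- ref6$sequence[i]
    prot <- embed_domain(dom)
    a_start <- 17L  # domain position in the fixed lead
    res <- extract_mature_domain(prot, a_start, a_start + nchar(dom) - 1L)
    expect_identical(res$sequence, dom, info = ref6$name[i])
    expect_true(res$complete)
    expect_match(substring(dom, nchar(dom)), "[ND]")
  }
})

test_that("cysteine-poor anchors flag incomplete domains", {
  prot <- embed_domain("GIPCGESCVWIPCLTS")  # only 3 Cys then tail
  res <- extract_mature_domain(prot, 17L, 30L)
  expect_false(res$complete)
  # anchor inside a stop-bounded fragment
  prot2 <- "MAAA*GIPCGESCVWIPC*AAAA"
  res2 <- extract_mature_domain(prot2, 6L, 18L)
  expect_false(res2$complete)
})

test_that("hits deduplicate and novel names follow ascending mass", {
  hits <- data.frame(
    mature_sequence = c("GAAC", "GAAC", "GCCN", "GWWN"),
    calculated_mw = c(300, 300, 350, 500))
  refs <- data.frame(name = "known_pep", sequence = "GCCN")
  out <- classify_and_name(hits, refs, species_prefix = "tst")
  expect_identical(nrow(out), 3L)
  expect_identical(out$name[out$mature_sequence == "GCCN"], "known_pep")
  expect_false(out$novel[out$mature_sequence == "GCCN"])
  novel <- out[out$novel, ]
  expect_identical(novel$name[order(novel$calculated_mw)],
                   c("tst 1", "tst 2"))
  # the reference set against itself yields zero novel sequences
  self <- classify_and_name(
    data.frame(mature_sequence = ref_table$sequence,
               calculated_mw = ref_table$calculated_mw),
    ref_table)
  expect_identical(sum(self$novel), 0L)
})

test_that("mass matching pairs nearest hits and reports ties", {
  hits <- ref_table[, c("name", "calculated_mw")]
  m <- match_masses(hits, 2957.17, tolerance = 0.05)
  expect_identical(m$name, "varv peptide F")
  expect_false(any(m$ambiguous))
  expect_identical(nrow(match_masses(hits, 5000, tolerance = 0.05)), 0L)
  # isobaric I/L pair: both reported, flagged ambiguous
  iso <- match_masses(hits, cyc_mass("GIPCGESCVWIPCITSAIGCSCKSKVCYRN"),
                      tolerance = 0.05)
  expect_setequal(iso$name, c("vitri A", "CyO3"))
  expect_true(all(iso$ambiguous))
})

test_that("scrambled-domain plausibility is rejected, references accepted", {
  expect_true(all(vapply(ref6$sequence, plausible_loops, logical(1))))
  set.seed(31)
  rejected <- vapply(1:50, function(i) {
    !plausible_loops(paste(sample(strsplit(ref6$sequence[i %% 90 + 1],
                                           "")[[1]]), collapse = ""))
  }, logical(1))
  expect_gt(mean(rejected), 0.9)
})

test_that("mining output is internally consistent", {
  cfg <- sim_config(seed = 77, n_contigs = 30, n_planted = 6)
  tx <- gen_transcriptome(cfg)
  hits <- mine_cyclotides(tx$contigs)
  # every mature sequence is a literal substring of its translated frame
  for (i in seq_len(nrow(hits))) {
    prot <- six_frame_translate(tx$contigs[[hits$contig_id[i]]])[[hits$frame[i]]]
    expect_identical(substr(prot, hits$start[i], hits$end[i]),
                     hits$mature_sequence[i])
  }
  # novel naming is a bijection onto 1..k, non-decreasing in mass
  novel <- hits[hits$novel, ]
  if (nrow(novel)) {
    nums <- as.integer(sub("^syn ", "", novel$name))
    expect_setequal(nums, seq_len(nrow(novel)))
    expect_true(all(diff(novel$calculated_mw[order(nums)]) >= 0))
  }
  # planted domains recovered as complete hits
  planted <- tx$truth$mature_sequence[tx$truth$planted]
  expect_true(all(planted %in% hits$mature_sequence[hits$complete]))
})
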