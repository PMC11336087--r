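Package: cyclomine
Title: Cyclotide Discovery, MALDI-MS Quantification and Treatment Response Calling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for cyclotide (head-to-tail cyclic, cystine-knot plant
    peptide) science. Mines assembled transcriptome contigs for cyclotide
    precursors by PROSITE-style motif search and Smith-Waterman similarity
    against a reference database, extracts and names mature domains, and
    computes monoisotopic or average masses of cyclic triple-disulfide
    peptides including full isotope envelopes. Quantifies cyclotides from
    pixelated MALDI spot spectra as mean intensity per pixel per spot, with
    monoisotopic assignment, envelope-overlap and dilution-linearity
    acceptance filters, and classifies treatment-induced up/down-regulation
    with one-way and repeated-measures ANOVA followed by Tukey's HSD.
    Includes a synthetic-data generator covering every pipeline input, and
    ships a reference table of 100 Viola cyclotide sequences with their
    published molecular weights.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    emmeans,
    mzR,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
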