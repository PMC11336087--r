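---
title: "Mining, quantifying and testing cyclotides: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining, quantifying and testing cyclotides: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyclomine)
```

Cyclotides are head-to-tail cyclic plant peptides of roughly 28–37
residues whose six cysteines form a cyclic cystine knot (three disulfide
bonds). `cyclomine` implements the computational side of a cyclotide
study on metal-treated *Viola* cell suspensions: discovering cyclotide
sequences in assembled transcriptome contigs, computing their masses,
quantifying them from MALDI-imaged extract spots, and classifying which
peptides respond to a treatment. This vignette explains the models and
the design choices; the README shows the worked example.

## Mass chemistry

A peptide's mass is assembled from residue masses (amino acid minus
water):

$$M = \sum_i m_{\mathrm{res}}(a_i) \;+\; [\text{linear}]\; m_{H_2O}
      \;-\; 2\, n_{SS}\, m_H .$$

A head-to-tail cyclic backbone forms one extra amide bond and therefore
omits the terminal water; each disulfide bond removes two hydrogens. For
the cyclotide convention (cyclic, three disulfides) the difference from
the linear reduced chain is exactly one water plus six hydrogens,
24.0575 Da — a closed-form identity the test suite asserts for every
sequence.

Constants are IUPAC monoisotopic atomic masses (C 12 exact,
H 1.0078250319, N 14.0030740052, O 15.9949146221, S 31.97207069) and
conventional average masses; the proton mass 1.007276466 Da converts
between neutral masses and the singly protonated \[M+H\]$^+$ ions that
MALDI produces for peptides of this size. The packaged reference table
of 100 *V. lutea* ssp. *westfalica* cyclotides reproduces its published
molecular weights to within 0.07 Da under these constants; the published
values sit systematically ~0.055 Da below the standard convention (their
exact constants are not stated), so the golden-suite tolerance is
±0.1 Da rather than a guess at the original convention.

Isotope envelopes are computed exactly by convolving per-element isotope
distributions over the molecule's elemental composition (exponentiation
by squaring over neutron-count bins), truncated at 99.9% cumulative
abundance and renormalised. Peak positions use the uniform
$^{13}$C–$^{12}$C spacing convention (1.00336 Da) anchored at the exact
monoisotopic mass: for sulfur-rich peptides the true abundance-weighted
bin centres drift a few mDa below this for higher isotopologues, but the
uniform convention matches how deisotoping tools (including this
package's envelope grouping) treat spacing.

## Motif search

The mining motif
`C-x(0,1)-[ES]-S-C-[AV]-[MFYW]-I-[PS]-x(0,1)-C` covers the
loop-1/loop-2 region between cysteines I and III and preferentially
matches bracelet-type cyclotides. The matcher is a small fuzzy-pattern
engine rather than a regular-expression translation: wildcard repeat
counts are enumerated exhaustively so that *every* distinct match
interval is reported, including multiple spans from the same start
(a lazy or greedy regex reports only one). Matching is
case-insensitive; `X` (unknown residue) and `*` (stop) never match any
element, wildcards included. Tests compare the engine against an
independent regex-oracle (one anchored lookahead per fixed-length
realisation of the pattern) on thousands of random strings.

## Similarity search and mature-domain extraction

Reference similarity uses exact Smith–Waterman local alignment
(BLOSUM62, gap open 11, gap extend 1) of every reference mature domain
against each translated segment — affordable because cyclotide domains
are short, and free of heuristic-seeding blind spots. The default
reporting threshold is a raw score of 50; self-hits of reference
domains score 170–200, while scrambled composition-matched decoys top
out near 47.

Translated frames are split at stop codons and segments of at least 25
residues containing at least three cysteines are scanned by both
detectors. Overlapping detections merge into one anchor with provenance
(`motif`, `similarity` or `both`); the extraction anchor inside a merged
group is the best similarity alignment's own interval when present
(its boundaries track the reference domain), otherwise the motif
interval.

Mature-domain boundaries are not derivable from first principles, so
extraction uses a heuristic regression-tested against all complete
reference sequences planted in precursor context:

* expand the anchor to the six-cysteine window whose cysteines lie
  inside the anchor (ties broken by interval overlap, then earlier);
* start at the anchor start when it already sits on a Gly/Ser within
  five residues of cysteine I (every complete reference entry starts
  with G or S), otherwise the most upstream G/S in that window;
* end at the anchor end when it sits on Asn/Asp within five residues
  after cysteine VI (every complete reference entry ends in N or D),
  otherwise the last N/D in that window.

Hits with fewer than six cysteines before a stop are flagged
incomplete. Two plausibility guards reject scrambled sequences that
happen to carry six cysteines: the five inter-cysteine loop lengths
must fall inside the envelope spanned by the reference set (with one
residue of slack per loop — loop 1 is almost invariant at three
residues and loop 4 at one, which makes this a sharp filter), and
incomplete similarity-only hits must either match the motif or align at
score ≥ 80 and carry at least four cysteines, since they lack the
completeness corroboration. Novelty is exact string identity against
the reference set; near-identity is reported as percent identity, not
novelty. Novel hits are numbered by ascending calculated mass under a
species prefix, mirroring field practice.

## MALDI spot quantification

The quantity of interest is the **mean intensity per pixel per spot**:
each dried extract spot is imaged as ~70 pixels at 250 µm resolution,
pixels are averaged (after linear-interpolation resampling onto a
common grid when grids differ; 0.005 Da spacing by default, an
FTICR-scale choice), and an ion's per-spot quantity is the trapezoidal
integral of the average spectrum over its monoisotopic centroid
± 0.1 Da. Because the average is already per pixel, no further
normalisation is applied — the metric is deliberately the raw
mean intensity per pixel, with arbitrary units.

Ion acceptance applies three rules:

* **mass window** — the neutral monoisotopic mass (centroid minus one
  proton; charge state is fixed at +1) must lie in 2.8–3.8 kDa;
* **non-overlap** — no member peak of the ion's envelope within 0.2 Da
  of a member of another *credible* envelope (at least three member
  peaks; one- or two-peak chains at the noise floor are chance
  alignments). Both parties of an overlap are rejected. Overlap status
  is judged on peaks detected at a fixed sensitivity (SNR 3) rather
  than the reporting threshold — interfering ions exist in the average
  spectrum regardless of how strictly the panel is filtered — which
  also keeps the accepted set monotone in `snr_min`;
* **dilution linearity** — a least-squares fit of intensity against
  relative concentration (1/dilution factor) over the serial dilution
  series must give $R^2 \ge 0.9$ with positive slope, in at least one
  species' series. Fewer than three levels leaves the flag
  indeterminate and the ion excluded.

Peak picking thresholds local maxima at baseline + 3× a robust noise
level (MAD of the signal-free region; the baseline is estimated because
detector intensities are non-negative, which lifts the quiet-region
median above zero) and centroids by intensity-weighted mean over the
FWHM region. Envelope grouping attaches each peak to the open envelope
with the smallest residual from an integer multiple of 1.00335 Da
(±0.02 Da, up to twelve isotopologues), which disentangles interleaved
envelopes of near-isobaric peptides; a chain splits where intensity
rises by more than 50% after having fallen (valley-then-rise cannot
arise from a single peptide envelope in this window), and while a chain
is still rising a new member may be at most 2.5× the previous one
(A+1/A stays below ~1.9 up to 3.8 kDa). Accepted panel ions must show
at least two envelope members, because a genuine monoisotopic ion above
the noise floor in this mass range is always accompanied by its A+1
peak.

None of the numerical defaults (SNR 3, $R^2$ 0.9, three dilution
levels, 0.2 Da overlap radius, 0.1 Da integration radius) comes from a
published value; each is a documented, overridable parameter chosen at
magnitudes standard for FTICR peptidomics. The mass-match tolerance
between calculated and observed masses defaults to 0.05 Da,
FTICR-grade accuracy; isobaric matches (I/L isomers) are reported as
ambiguous pairs rather than silently resolved.

## Treatment statistics

The design is one control cell (no metal, harvested at 72 h alongside
the treated cultures) plus Zn and Pb at 200 and 2000 µM, sampled at
24 h and 72 h, with three biological replicates — 27 spots per species.
Two contrast families are computed per ion:

* **family A, control vs 72 h** — one-way ANOVA across the five 72-h
  groups followed by Tukey's HSD; the four treated-vs-control contrasts
  are read off with their adjusted p-values.
* **family B, 24 h vs 72 h** — repeated-measures ANOVA with the
  biological replicate as subject (an interpretation: the replicate is
  the only plausible pairing unit), model
  `y ~ cell*time + Error(subject)`, followed by Tukey on the
  time-within-cell contrasts using the within-subject mean square and
  the studentized range over all cell-by-time means. With two time
  levels sphericity is trivially satisfied. This family-wide
  adjustment is deliberately conservative for the eight within-cell
  contrasts (the test suite verifies the contrast machinery against
  emmeans and measures the realised family error rate).

A call is `up`/`down` only when the adjusted p-value is ≤ 0.05 and the
mean difference has the matching sign. Analyses are per ion with no
cross-ion multiplicity correction — matching how such panels are
conventionally reported — with an optional Benjamini–Hochberg flag.
Raw intensities are analysed by default (log10 available); calls are
invariant under global intensity rescaling. Degenerate inputs
(all groups exact ties) return a no-call verdict rather than dividing
by zero.

Under the null with three replicates, the fraction of ions with any
significant Tukey pair is calibrated at the nominal 5% (checked against
the binomial 99% interval over 2000 simulated ions), and a planted
4-fold change with 20% CV is detected with power above 0.8 in both
families.

## The synthetic-data generator

Every pipeline input can be generated with exact ground truth:

* **transcriptomes** — each planted contig carries a precursor ORF
  (start codon, 20–40 random pro-region codons, the back-translated
  mature domain with uniform synonymous-codon choice, 10–25 C-terminal
  codons, stop) at a random offset and strand inside random UTRs. Decoy
  contigs embed a shuffled mature domain — same residue composition —
  re-shuffled until its motif match is verifiably broken. Default
  scale: 20 planted among 200 decoys.
* **spots** — each pixel spectrum is the sum over ions of abundance ×
  a lognormal per-pixel factor (CV 20%) × the predicted isotope
  envelope rendered as Gaussians (FWHM 0.025 Da), plus additive
  baseline noise truncated at zero. ~70 pixels per spot; dilution spots
  scale abundances by 1/dilution factor over the 1–2–4–8 series.
* **designs and intensities** — the full 27-spot factorial with planted
  per-ion log2 fold changes and 20% replicate CV, bypassing spectrum
  rendering where only the statistics are under test.

All generators are bit-reproducible under a fixed seed and restore the
caller's RNG state. The noise model is deliberately simple: no detector
saturation, mass drift, chemical background, or spatial structure
across pixels. Passing tests therefore demonstrate correctness of the
averaging, filtering and testing logic under the stated model — not
robustness to instrument artefacts real spectra may carry.

Problem sizes in the test suite are chosen to exercise the stated study
conditions at desk scale: the mining check runs the full 20-planted /
200-decoy transcriptome; quantification uses 70-pixel spots over the
full window with a 10-ion panel and 12 quantification spots; the null
calibration uses 2000 simulated ions and the power checks 300
replicate experiments per family.

## Known limitations

* Boundary extraction is a heuristic; on genuinely novel precursors
  whose termini deviate from the G/S-start, N/D-end convention it will
  misplace boundaries (and either flag the hit incomplete or report a
  shifted domain).
* The loop-plausibility envelope is derived from one species' reference
  set; unusually long-looped cyclotides from other lineages could be
  rejected at the defaults (the filter can be disabled).
* Quantification assumes singly charged ions and does not deconvolve
  multiple charge states or apply post-translational modifications
  other than cyclisation and disulfides.
* The overlap rule operates on whole envelopes, one reading of
  "not overlapping" (the monoisotopic-peaks-only reading is stricter);
  peptides more than ~0.2 Da but less than one spacing apart interleave
  without being flagged, and their integration windows may still touch
  at extreme peak widths.
* The repeated-measures subject pairing and the per-metal pooling of
  the one-way family are interpretations of an under-specified
  analysis description; both are isolated behind small functions and
  easy to revisit.
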