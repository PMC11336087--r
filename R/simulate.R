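#' Synthetic study generator
#'
#' Generates every input the pipeline consumes, with exact ground truth:
#' transcriptomes carrying cyclotide precursors among composition-matched
#' decoys, pixelated MALDI spots built from predicted isotope envelopes,
#' serial-dilution series, and the full metal-treatment design (control at
#' 72 h plus Zn/Pb at 200/2000 uM sampled at 24 h and 72 h, three
#' biological replicates - 27 spots per species).
#'
#' @name synthetic-data
NULL

# run code under a fixed seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Simulation configuration
#'
#' Defaults encode the emulated study conditions: ~70 imaging pixels per
#' spot, a 4-step serial dilution, three biological replicates per
#' treatment cell, peptide envelopes in the 2.8-3.8 kDa window, and 20%
#' multiplicative pixel/replicate variation.
#'
#' @param seed Integer seed; fixed seed gives bit-identical outputs.
#' @param n_contigs Total contigs in a synthetic transcriptome.
#' @param n_planted Number of contigs carrying genuine precursors.
#' @param planted_sequences Mature domains to plant; defaults to a sample
#'   of the packaged reference set restricted to complete six-cysteine
#'   domains.
#' @param decoy_policy `"composition_matched"` (shuffled mature domains
#'   with the motif verifiably broken, embedded like real precursors) or
#'   `"random"` (plain random contigs).
#' @param pixels_per_spot Imaging pixels per spot.
#' @param mz_range Acquisition m/z range (Da).
#' @param grid_step Acquisition grid spacing (Da).
#' @param peak_fwhm Peak full width at half maximum (Da).
#' @param baseline_sd Additive baseline noise s.d. (arbitrary units).
#' @param pixel_cv Multiplicative lognormal CV per pixel.
#' @param replicate_cv Multiplicative lognormal CV per biological replicate.
#' @param dilution_factors Serial dilution factors.
#' @param baseline_intensity Mean abundance scale of a planted ion.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_contigs = 220L, n_planted = 20L,
                       planted_sequences = NULL,
                       decoy_policy = c("composition_matched", "random"),
                       pixels_per_spot = 70L, mz_range = c(2750, 3850),
                       grid_step = 0.005, peak_fwhm = 0.025,
                       baseline_sd = 1, pixel_cv = 0.2,
                       replicate_cv = 0.2,
                       dilution_factors = c(1, 2, 4, 8),
                       baseline_intensity = 100) {
  decoy_policy <- match.arg(decoy_policy)
  structure(list(seed = as.integer(seed), n_contigs = as.integer(n_contigs),
                 n_planted = as.integer(n_planted),
                 planted_sequences = planted_sequences,
                 decoy_policy = decoy_policy,
                 pixels_per_spot = as.integer(pixels_per_spot),
                 mz_range = mz_range, grid_step = grid_step,
                 peak_fwhm = peak_fwhm, baseline_sd = baseline_sd,
                 pixel_cv = pixel_cv, replicate_cv = replicate_cv,
                 dilution_factors = dilution_factors,
                 baseline_intensity = baseline_intensity),
            class = "sim_config")
}

.codon_table <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      gc <- Biostrings::GENETIC_CODE
      cache <<- split(names(gc), unname(gc))
    }
    cache
  }
})

.back_translate <- function(protein) {
  tab <- .codon_table()
  chars <- strsplit(protein, "", fixed = TRUE)[[1]]
  paste(vapply(chars, function(a) {
    codons <- tab[[a]]
    codons[sample.int(length(codons), 1L)]
  }, character(1)), collapse = "")
}

.random_codons <- function(n) {
  sense <- setdiff(names(Biostrings::GENETIC_CODE),
                   c("TAA", "TAG", "TGA"))
  paste(sense[sample.int(length(sense), n, replace = TRUE)], collapse = "")
}

.random_nt <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.shuffle_broken_motif <- function(sequence, motif, max_tries = 100L) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  for (i in seq_len(max_tries)) {
    cand <- paste(sample(chars), collapse = "")
    if (nrow(motif_scan(cand, motif)) == 0L) return(cand)
  }
  stop("could not break motif by shuffling: ", sequence)
}

#' Generate a synthetic transcriptome with planted precursors
#'
#' Each planted contig carries a precursor open reading frame: start codon,
#' random pro-region codons, the back-translated mature domain, random
#' C-terminal codons and a stop, embedded at a random offset on a random
#' strand within random UTR sequence. Decoy contigs (all remaining ones
#' under the `composition_matched` policy) carry the same construction
#' around a shuffled mature domain whose motif match is verifiably broken.
#'
#' @param cfg A [sim_config()].
#' @param refs Reference table supplying default planted sequences.
#' @return List: `contigs` (named character vector), `truth` (data frame
#'   `contig_id`, `frame`, `mature_sequence`, `planted` - `FALSE` rows are
#'   decoys).
#' @export
gen_transcriptome <- function(cfg, refs = viwe_reference()) {
  motif <- cyclotide_motif()
  planted <- cfg$planted_sequences
  with_seed(cfg$seed, {
    if (is.null(planted)) {
      pool <- refs$sequence[refs$complete &
        vapply(refs$sequence, function(s) {
          sum(strsplit(s, "")[[1]] == "C") == 6L
        }, logical(1))]
      planted <- sample(pool, cfg$n_planted)
    }
    stopifnot(length(planted) <= cfg$n_contigs)
    n_decoy <- cfg$n_contigs - length(planted)
    decoy_src <- if (n_decoy > 0 && cfg$decoy_policy == "composition_matched") {
      sample(setdiff(refs$sequence[refs$complete], planted), n_decoy,
             replace = n_decoy > length(setdiff(refs$sequence[refs$complete],
                                                planted)))
    } else character(0)
    embed <- function(domain) {
      orf <- paste0("ATG", .random_codons(sample(20:40, 1L)),
                    .back_translate(domain),
                    .random_codons(sample(10:25, 1L)),
                    sample(c("TAA", "TAG", "TGA"), 1L))
      utr5 <- .random_nt(sample(30:120, 1L))
      utr3 <- .random_nt(sample(30:120, 1L))
      fwd <- paste0(utr5, orf, utr3)
      strand <- sample(c("+", "-"), 1L)
      nt <- if (strand == "+") fwd else
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(fwd)))
      off <- nchar(utr5) %% 3L
      frame <- paste0(strand, off + 1L)
      list(nt = nt, frame = frame)
    }
    contigs <- character(cfg$n_contigs)
    truth <- vector("list", cfg$n_contigs)
    ids <- sprintf("contig_%03d", seq_len(cfg$n_contigs))
    slots <- sample(cfg$n_contigs)  # random placement of planted contigs
    planted_slots <- slots[seq_along(planted)]
    decoy_slots <- setdiff(seq_len(cfg$n_contigs), planted_slots)
    for (i in seq_along(planted)) {
      e <- embed(planted[i])
      s <- planted_slots[i]
      contigs[s] <- e$nt
      truth[[s]] <- data.frame(contig_id = ids[s], frame = e$frame,
                               mature_sequence = planted[i], planted = TRUE)
    }
    for (i in seq_along(decoy_slots)) {
      s <- decoy_slots[i]
      if (cfg$decoy_policy == "composition_matched") {
        dec <- .shuffle_broken_motif(decoy_src[i], motif)
        e <- embed(dec)
        contigs[s] <- e$nt
        truth[[s]] <- data.frame(contig_id = ids[s], frame = e$frame,
                                 mature_sequence = dec, planted = FALSE)
      } else {
        contigs[s] <- .random_nt(sample(300:600, 1L))
        truth[[s]] <- data.frame(contig_id = ids[s], frame = NA_character_,
                                 mature_sequence = NA_character_,
                                 planted = FALSE)
      }
    }
    list(contigs = stats::setNames(contigs, ids),
         truth = do.call(rbind, truth))
  })
}

# sparse Gaussian peak templates on the acquisition grid for a set of ions
.ion_templates <- function(sequences, cfg, constants = mass_constants()) {
  grid <- seq(cfg$mz_range[1], cfg$mz_range[2], by = cfg$grid_step)
  sd <- cfg$peak_fwhm / (2 * sqrt(2 * log(2)))
  tmpl <- lapply(sequences, function(s) {
    env <- predict_envelope(cyclotide(s), constants)
    idx <- integer(); val <- numeric()
    for (k in seq_along(env$mz_values)) {
      mu <- env$mz_values[k]
      lo <- max(1L, ceiling((mu - 5 * sd - grid[1]) / cfg$grid_step) + 1L)
      hi <- min(length(grid), floor((mu + 5 * sd - grid[1]) /
                                      cfg$grid_step) + 1L)
      if (lo > hi) next
      ii <- lo:hi
      idx <- c(idx, ii)
      val <- c(val, env$intensities[k] *
                 exp(-((grid[ii] - mu)^2) / (2 * sd^2)))
    }
    agg <- tapply(val, idx, sum)
    list(idx = as.integer(names(agg)), val = as.numeric(agg),
         mono_mz = env$mz_values[1])
  })
  list(grid = grid, templates = tmpl)
}

.render_pixel <- function(tm, amounts, cfg) {
  y <- if (cfg$baseline_sd > 0) {
    stats::rnorm(length(tm$grid), 0, cfg$baseline_sd)
  } else numeric(length(tm$grid))
  sig <- cfg$pixel_cv
  for (i in seq_along(tm$templates)) {
    if (amounts[i] <= 0) next
    fac <- if (sig > 0) {
      s2 <- log(1 + sig^2)
      stats::rlnorm(1, meanlog = -s2 / 2, sdlog = sqrt(s2))
    } else 1
    t <- tm$templates[[i]]
    y[t$idx] <- y[t$idx] + amounts[i] * fac * t$val
  }
  pmax(y, 0)
}

#' Generate pixelated MALDI spots for known ion abundances
#'
#' Every pixel spectrum is the sum over ions of abundance times a lognormal
#' per-pixel factor times the ion's isotope envelope rendered as Gaussian
#' peaks, plus additive baseline noise, truncated at zero. All planted ions
#' obey the charge-1 convention: the first envelope peak sits at the
#' peptide's monoisotopic mass plus one proton.
#'
#' @param cfg A [sim_config()].
#' @param sequences Character vector of peptide sequences defining the ions
#'   (rows of `abundances`).
#' @param abundances Matrix, ions x spots, of true per-spot abundances.
#' @param metadata Optional list (length = spots) of metadata lists.
#' @param average_only Return memory-light `average_spectrum` objects
#'   (pixels averaged on the fly) instead of full `spot_dataset`s.
#' @return List of `spot_dataset` or `average_spectrum` objects, one per
#'   column of `abundances`; either carries the spot metadata. The ion
#'   templates' monoisotopic m/z values are attached as attribute
#'   `mono_mz`.
#' @export
gen_spots <- function(cfg, sequences, abundances, metadata = NULL,
                      average_only = FALSE) {
  stopifnot(is.matrix(abundances), nrow(abundances) == length(sequences),
            all(abundances >= 0))
  tm <- .ion_templates(sequences, cfg)
  n_spots <- ncol(abundances)
  spot_ids <- colnames(abundances)
  if (is.null(spot_ids)) spot_ids <- sprintf("spot_%02d", seq_len(n_spots))
  out <- with_seed(cfg$seed + 1L, {
    lapply(seq_len(n_spots), function(j) {
      meta <- if (is.null(metadata)) list() else metadata[[j]]
      if (average_only) {
        total <- numeric(length(tm$grid))
        for (p in seq_len(cfg$pixels_per_spot)) {
          total <- total + .render_pixel(tm, abundances[, j], cfg)
        }
        a <- structure(list(mz = tm$grid,
                            intensity = total / cfg$pixels_per_spot,
                            pixel_count = cfg$pixels_per_spot),
                       class = "average_spectrum")
        attr(a, "metadata") <- meta
        attr(a, "spot_id") <- spot_ids[j]
        a
      } else {
        pixels <- lapply(seq_len(cfg$pixels_per_spot), function(p) {
          list(mz = tm$grid, intensity = .render_pixel(tm, abundances[, j],
                                                       cfg))
        })
        spot_dataset(spot_ids[j], pixels, meta)
      }
    })
  })
  attr(out, "mono_mz") <- vapply(tm$templates, `[[`, numeric(1), "mono_mz")
  out
}

#' Generate the metal-treatment design
#'
#' Full factorial: one control cell (no metal, 72 h) plus Zn and Pb at 200
#' and 2000 uM, each sampled at 24 h and 72 h, with three biological
#' replicates - 27 spots per species.
#'
#' @param cfg A [sim_config()] (only the seed is used here).
#' @param species Species/genotype label.
#' @param n_replicates Biological replicates per cell.
#' @return A [treatment_design()].
#' @export
gen_design <- function(cfg, species = "synthetic", n_replicates = 3L) {
  cells <- rbind(data.frame(metal = "none", dose = 0, time_h = 72),
                 expand.grid(metal = c("Zn", "Pb"), dose = c(200, 2000),
                             time_h = c(24, 72),
                             stringsAsFactors = FALSE))
  d <- do.call(rbind, lapply(seq_len(n_replicates), function(r) {
    cbind(cells, replicate = r)
  }))
  d$species <- species
  d$spot_id <- sprintf("%s_%s%s_%dh_r%d", species,
                       ifelse(d$metal == "none", "ctl", d$metal),
                       ifelse(d$metal == "none", "", d$dose),
                       d$time_h, d$replicate)
  treatment_design(d$spot_id, d$species, d$metal, d$dose, d$time_h,
                   d$replicate)
}

#' Simulate per-ion spot intensities under a planted effect model
#'
#' Produces the intensity matrix the statistics stage consumes, bypassing
#' spectrum rendering: each value is the ion's baseline times `2^lfc` for
#' its design cell times a lognormal replicate factor.
#'
#' @param cfg A [sim_config()].
#' @param design A [treatment_design()].
#' @param n_ions Number of ions.
#' @param effects `NULL` (null model) or a data frame with columns `ion`
#'   (index), `metal`, `dose`, `time_h`, `lfc` giving planted log2 fold
#'   changes relative to control for matching design cells.
#' @param seed_offset Added to `cfg$seed` (lets callers draw independent
#'   replicate datasets).
#' @return List: `intensity` (matrix ions x spots, dimnames set), `truth`
#'   (data frame `ion`, `group`, `call_A`, `call_B` - the planted
#'   regulation calls).
#' @export
gen_ion_intensities <- function(cfg, design, n_ions, effects = NULL,
                                seed_offset = 2L) {
  lfc <- array(0, dim = c(n_ions, nrow(design)))
  if (!is.null(effects)) {
    for (k in seq_len(nrow(effects))) {
      sel <- design$metal == effects$metal[k] &
        design$dose == effects$dose[k] & design$time_h == effects$time_h[k]
      lfc[effects$ion[k], sel] <- effects$lfc[k]
    }
  }
  intens <- with_seed(cfg$seed + seed_offset, {
    s2 <- log(1 + cfg$replicate_cv^2)
    noise <- matrix(stats::rlnorm(n_ions * nrow(design),
                                  meanlog = -s2 / 2, sdlog = sqrt(s2)),
                    n_ions, nrow(design))
    cfg$baseline_intensity * 2^lfc * noise
  })
  dimnames(intens) <- list(sprintf("ion_%03d", seq_len(n_ions)),
                           design$spot_id)
  cells <- unique(design[design$metal != "none", c("metal", "dose")])
  truth <- do.call(rbind, lapply(seq_len(n_ions), function(i) {
    do.call(rbind, lapply(seq_len(nrow(cells)), function(c) {
      sel72 <- design$metal == cells$metal[c] & design$dose == cells$dose[c]
      l72 <- unique(lfc[i, sel72 & design$time_h == 72])
      l24 <- unique(lfc[i, sel72 & design$time_h == 24])
      data.frame(ion = rownames(intens)[i],
                 group = .group_label(cells$metal[c], cells$dose[c]),
                 call_A = if (l72 > 0) "up" else if (l72 < 0) "down"
                          else "none",
                 call_B = if (l72 > l24) "up" else if (l72 < l24) "down"
                          else "none")
    }))
  }))
  list(intensity = intens, truth = truth)
}
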