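#' End-to-end pipeline with run manifest
#'
#' Orchestrates simulate -> mine -> quant -> stats over plain files, so any
#' stage can also be re-run by hand on its inputs. A `manifest.json` records
#' the configuration snapshot, input checksums, package version, seed and
#' per-stage row counts; deterministic stages reproduce identical outputs
#' from an identical manifest.
#'
#' @param config Named list (or path to a JSON file) with entries:
#'   `seed`, optional `contigs` (FASTA path; when absent a synthetic
#'   transcriptome is generated), optional `refs` (CSV/FASTA path;
#'   default packaged table), optional `spectra` (text dialect path) and
#'   `design` (CSV path) - when absent a synthetic experiment is
#'   generated - plus optional filter settings `min_score`, `snr_min`,
#'   `r2_min`, `window` (length 2), `alpha`.
#' @param out_dir Output directory (created if needed); receives
#'   `hits.csv`, `panel.csv`, `regulation.csv`, `manifest.json`.
#' @return The manifest, invisibly. On a stage failure the completed
#'   stages' outputs and a manifest marking the failure point are left in
#'   `out_dir`, and the error is re-raised.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  defaults <- list(seed = 1L, min_score = 50, snr_min = 3, r2_min = 0.9,
                   window = c(2800, 3800), alpha = 0.05)
  filled <- setdiff(names(defaults), names(config))
  config <- utils::modifyList(defaults, config)
  if (length(filled)) {
    message("defaults filled for unset config keys: ",
            paste(filled, collapse = ", "))
  }
  # pre-flight: every named input must exist before any stage runs
  for (key in c("contigs", "refs", "spectra", "design")) {
    if (!is.null(config[[key]]) && !file.exists(config[[key]])) {
      stop("input file for '", key, "' not found: ", config[[key]])
    }
  }
  if (!is.null(config$contigs)) read_contigs(config$contigs)  # validate early
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    tool = "cyclomine",
    version = as.character(utils::packageVersion("cyclomine")),
    seed = config$seed,
    config = config,
    inputs = list(), stages = list(), failed_stage = NULL)
  for (key in c("contigs", "refs", "spectra", "design")) {
    if (!is.null(config[[key]])) {
      manifest$inputs[[key]] <- list(
        path = config[[key]],
        md5 = unname(tools::md5sum(config[[key]])))
    }
  }
  write_manifest <- function() {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         null = "null")
  }
  run_stage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e) {
      manifest$failed_stage <<- name
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      write_manifest()
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- list(status = "ok", rows = res$rows)
    res$value
  }
  cfg <- sim_config(seed = config$seed)
  # --- mine ---------------------------------------------------------------
  hits <- run_stage("mine", function() {
    refs <- if (!is.null(config$refs)) read_reference_db(config$refs)
            else viwe_reference()
    if (is.null(refs$complete)) refs$complete <- TRUE
    contigs <- if (!is.null(config$contigs)) read_contigs(config$contigs)
               else gen_transcriptome(cfg, refs)$contigs
    h <- mine_cyclotides(contigs, refs, min_score = config$min_score)
    utils::write.csv(h, file.path(out_dir, "hits.csv"), row.names = FALSE)
    list(value = h, rows = nrow(h))
  })
  # --- quant --------------------------------------------------------------
  panel <- run_stage("quant", function() {
    if (!is.null(config$spectra)) {
      meta <- if (!is.null(config$design)) {
        utils::read.csv(config$design, stringsAsFactors = FALSE)
      } else NULL
      spots <- read_spots_text(config$spectra, meta)
      design <- treatment_design(meta$spot_id, meta$species, meta$metal,
                                 meta$dose, meta$time_h, meta$replicate)
    } else {
      sim <- .default_quant_simulation(cfg)
      spots <- sim$spots
      design <- sim$design
    }
    p <- build_panel(spots, window = config$window,
                     snr_min = config$snr_min, r2_min = config$r2_min)
    out <- cbind(p$ions[p$ions$accepted, c("mz", "neutral_mass"),
                        drop = FALSE], as.data.frame(p$intensity))
    utils::write.csv(out, file.path(out_dir, "panel.csv"),
                     row.names = FALSE)
    list(value = list(panel = p, design = design),
         rows = sum(p$ions$accepted))
  })
  # --- stats --------------------------------------------------------------
  run_stage("stats", function() {
    design <- panel$design
    p <- panel$panel
    keep <- design$spot_id %in% colnames(p$intensity)
    reg <- regulation_matrix(p, design[keep, , drop = FALSE],
                             alpha = config$alpha)
    utils::write.csv(as.data.frame(reg),
                     file.path(out_dir, "regulation.csv"),
                     row.names = FALSE)
    list(value = reg, rows = nrow(reg))
  })
  write_manifest()
  invisible(manifest)
}

# small default synthetic experiment for pipeline smoke runs: six
# well-separated reference cyclotides quantified over the full 27-spot
# design plus a dilution series
.default_quant_simulation <- function(cfg) {
  refs <- viwe_reference()
  comp <- refs[refs$complete & refs$calculated_mw > 2850 &
                 refs$calculated_mw < 3420, ]
  comp <- comp[order(comp$calculated_mw), ]
  sel <- integer()
  for (i in seq_len(nrow(comp))) {
    if (!length(sel) ||
        all(abs(comp$calculated_mw[i] - comp$calculated_mw[sel]) > 10)) {
      sel <- c(sel, i)
    }
  }
  seqs <- comp$sequence[sel[round(seq(1, length(sel), length.out = 6))]]
  design <- gen_design(cfg)
  small <- cfg
  small$pixels_per_spot <- 16L
  small$baseline_sd <- 0.5
  small$mz_range <- c(2800, 3500)
  eff <- data.frame(ion = c(1, 2), metal = "Zn", dose = 2000, time_h = 72,
                    lfc = 2)
  sim <- gen_ion_intensities(small, design, length(seqs), eff)
  dil_ab <- outer(rep(small$baseline_intensity, length(seqs)),
                  1 / small$dilution_factors)
  colnames(dil_ab) <- sprintf("dil_%d", small$dilution_factors)
  dil_meta <- lapply(small$dilution_factors, function(f) {
    list(series = "dilution", species = "synthetic", dilution_factor = f)
  })
  meta <- lapply(seq_len(nrow(design)), function(i) {
    as.list(design[i, c("species", "metal", "dose", "time_h", "replicate")])
  })
  spots <- c(gen_spots(small, seqs, sim$intensity, meta,
                       average_only = TRUE),
             gen_spots(small, seqs, dil_ab, dil_meta, average_only = TRUE))
  list(spots = spots, design = design)
}
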