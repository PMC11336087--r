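#' Packaged Viola cyclotide reference table
#'
#' The 100 cyclotide mature-domain sequences described from *V. lutea* ssp.
#' *westfalica* callus transcriptome (16 previously known, 84 novel "viwe"
#' peptides), with their published monoisotopic molecular weights. Serves as
#' the default Cybase-style reference database for mining and mass matching.
#'
#' @param constants [mass_constants()] used for the `calculated_mw` column.
#' @return Data frame: `name`, `sequence`, `printed_mw` (published value,
#'   Da), `complete` (logical; `FALSE` for N-terminally truncated entries),
#'   `calculated_mw` (cyclic, oxidised monoisotopic mass computed by
#'   [peptide_mass()] with `min(3, floor(n_cys/2))` disulfides).
#' @export
viwe_reference <- function(constants = mass_constants()) {
  path <- system.file("extdata", "viwe_cyclotides.csv", package = "cyclomine",
                      mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab$calculated_mw <- vapply(tab$sequence, function(s) {
    n_cys <- nchar(s) - nchar(gsub("C", "", s))
    peptide_mass(peptide_sequence(s, "cyclic", min(3L, n_cys %/% 2L)),
                 constants = constants)
  }, numeric(1), USE.NAMES = FALSE)
  tab
}

#' Read a cyclotide reference database
#'
#' Accepts either a CSV with columns `name,sequence[,mass]` or a FASTA of
#' mature peptide sequences (masses then computed from the sequences).
#'
#' @param path File path (`.csv` or FASTA).
#' @return Data frame with `name`, `sequence`, `mass` columns.
#' @export
read_reference_db <- function(path) {
  if (!file.exists(path)) stop("reference database not found: ", path)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("name", "sequence") %in% names(tab))) {
      stop("reference CSV needs 'name' and 'sequence' columns: ", path)
    }
    if (is.null(tab$mass)) {
      if (!is.null(tab$printed_mw)) tab$mass <- tab$printed_mw
      else tab$mass <- vapply(tab$sequence, function(s) {
        n_cys <- nchar(s) - nchar(gsub("C", "", s))
        peptide_mass(peptide_sequence(s, "cyclic", min(3L, n_cys %/% 2L)))
      }, numeric(1), USE.NAMES = FALSE)
    }
    tab[c("name", "sequence", "mass")]
  } else {
    aa <- Biostrings::readAAStringSet(path)
    data.frame(name = names(aa), sequence = as.character(aa),
               mass = vapply(as.character(aa), function(s) {
                 n_cys <- nchar(s) - nchar(gsub("C", "", s))
                 peptide_mass(peptide_sequence(s, "cyclic",
                                               min(3L, n_cys %/% 2L)))
               }, numeric(1), USE.NAMES = FALSE),
               row.names = NULL)
  }
}

#' Write peptide sequences as FASTA
#' @param x Data frame with `name` and `sequence` columns.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_peptides_fasta <- function(x, path) {
  aa <- Biostrings::AAStringSet(stats::setNames(x$sequence, x$name))
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' Read contigs from a FASTA file
#' @param path FASTA file of assembled nucleotide contigs.
#' @return Named character vector of uppercase nucleotide sequences.
#' @export
read_contigs <- function(path) {
  if (!file.exists(path)) stop("contig FASTA not found: ", path)
  dna <- tryCatch(Biostrings::readDNAStringSet(path),
                  error = function(e) stop("malformed contig FASTA '", path,
                                           "': ", conditionMessage(e)))
  if (!length(dna)) stop("contig FASTA is empty: ", path)
  if (anyDuplicated(names(dna))) stop("duplicate contig ids in ", path)
  stats::setNames(toupper(as.character(dna)), names(dna))
}

#' Write spot spectra in the plain-text pixel dialect
#'
#' One line per pixel: `spot_id<TAB>pixel_id<TAB>mz:intensity;mz:intensity;...`
#' Only non-zero intensities are written, which keeps files compact for
#' sparse synthetic spectra.
#'
#' @param spots List of `spot_dataset` objects.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_spots_text <- function(spots, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (sp in spots) {
    for (j in seq_along(sp$pixels)) {
      px <- sp$pixels[[j]]
      keep <- px$intensity != 0
      pairs <- paste(format(px$mz[keep], trim = TRUE, digits = 10),
                     format(px$intensity[keep], trim = TRUE, digits = 8),
                     sep = ":")
      writeLines(paste(sp$spot_id, j, paste(pairs, collapse = ";"),
                       sep = "\t"), con)
    }
  }
  invisible(path)
}

#' Read spot spectra from the plain-text pixel dialect
#' @param path File written by [write_spots_text()] (or equivalent).
#' @param metadata Optional data frame keyed by `spot_id` whose remaining
#'   columns become spot metadata.
#' @return List of `spot_dataset` objects.
#' @export
read_spots_text <- function(path, metadata = NULL) {
  if (!file.exists(path)) stop("spectra file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 3L)
  if (length(bad)) stop("malformed spectra line ", bad[1], " in ", path)
  spot_ids <- vapply(parts, `[[`, character(1), 1L)
  out <- list()
  for (sid in unique(spot_ids)) {
    rows <- parts[spot_ids == sid]
    pixels <- lapply(rows, function(p) {
      if (!nzchar(p[[3]])) return(list(mz = numeric(), intensity = numeric()))
      kv <- strsplit(strsplit(p[[3]], ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
      mz <- as.numeric(vapply(kv, `[[`, character(1), 1L))
      it <- as.numeric(vapply(kv, `[[`, character(1), 2L))
      o <- order(mz)
      list(mz = mz[o], intensity = it[o])
    })
    meta <- list()
    if (!is.null(metadata)) {
      row <- metadata[metadata$spot_id == sid, , drop = FALSE]
      if (nrow(row) == 1L) meta <- as.list(row[setdiff(names(row), "spot_id")])
    }
    out[[sid]] <- spot_dataset(sid, pixels, meta)
  }
  out
}

#' Write spot spectra as mzML files
#'
#' Minimal uncompressed 64-bit mzML (one file per spot, one spectrum per
#' pixel), readable by any mzML parser.
#'
#' @param spots List of `spot_dataset` objects.
#' @param dir Output directory; files are named `<spot_id>.mzML`.
#' @return Character vector of file paths, invisibly.
#' @export
write_spots_mzml <- function(spots, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  enc <- function(x) {
    jsonlite::base64_enc(writeBin(as.numeric(x), raw(), size = 8,
                                  endian = "little"))
  }
  arr <- function(x, acc, name) {
    b <- enc(x)
    paste0('<binaryDataArray encodedLength="', nchar(b), '">\n',
           '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>\n',
           '<cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>\n',
           '<cvParam cvRef="MS" accession="', acc, '" name="', name,
           '" value=""/>\n<binary>', b, '</binary>\n</binaryDataArray>')
  }
  paths <- character(length(spots))
  for (k in seq_along(spots)) {
    sp <- spots[[k]]
    specs <- vapply(seq_along(sp$pixels), function(i) {
      px <- sp$pixels[[i]]
      paste0('<spectrum index="', i - 1L, '" id="scan=', i,
             '" defaultArrayLength="', length(px$mz), '">\n',
             '<cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="1"/>\n',
             '<cvParam cvRef="MS" accession="MS:1000294" name="mass spectrum" value=""/>\n',
             '<binaryDataArrayList count="2">\n',
             arr(px$mz, "MS:1000514", "m/z array"), "\n",
             arr(px$intensity, "MS:1000515", "intensity array"),
             "\n</binaryDataArrayList>\n</spectrum>")
    }, character(1))
    xml <- paste0('<?xml version="1.0" encoding="utf-8"?>\n',
                  '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">\n',
                  '<cvList count="1"><cv id="MS" fullName="PSI-MS" URI="http://psidev.info"/></cvList>\n',
                  '<fileDescription><fileContent>\n',
                  '<cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum" value=""/>\n',
                  '</fileContent></fileDescription>\n',
                  '<run id="', sp$spot_id, '">\n',
                  '<spectrumList count="', length(sp$pixels), '">\n',
                  paste(specs, collapse = "\n"),
                  '\n</spectrumList>\n</run>\n</mzML>')
    paths[k] <- file.path(dir, paste0(sp$spot_id, ".mzML"))
    writeLines(xml, paths[k])
  }
  invisible(paths)
}

#' Read spot spectra from mzML files
#'
#' Each mzML file holds the pixel spectra of one spot (one spectrum per
#' imaging pixel). Requires the `mzR` package.
#'
#' @param paths Character vector of mzML files; spot ids default to the file
#'   names without extension.
#' @param metadata Optional metadata data frame keyed by `spot_id`.
#' @return List of `spot_dataset` objects.
#' @export
read_spots_mzml <- function(paths, metadata = NULL) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    stop("reading mzML requires the 'mzR' package")
  }
  out <- list()
  for (path in paths) {
    sid <- sub("\\.mzml$", "", basename(path), ignore.case = TRUE)
    h <- mzR::openMSfile(path)
    n <- mzR::runInfo(h)$scanCount
    pixels <- lapply(seq_len(n), function(i) {
      pk <- mzR::peaks(h, i)
      list(mz = pk[, 1], intensity = pk[, 2])
    })
    mzR::close(h)
    meta <- list()
    if (!is.null(metadata)) {
      row <- metadata[metadata$spot_id == sid, , drop = FALSE]
      if (nrow(row) == 1L) meta <- as.list(row[setdiff(names(row), "spot_id")])
    }
    out[[sid]] <- spot_dataset(sid, pixels, meta)
  }
  out
}
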