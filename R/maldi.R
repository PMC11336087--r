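#' MALDI spot quantification
#'
#' A spot is one dried extract droplet imaged as ~70 pixels; the package's
#' quantity of interest is the mean intensity per pixel per spot at each
#' accepted monoisotopic ion. Ions are accepted when (i) their neutral mass
#' lies in the 2.8-3.8 kDa cyclotide window, (ii) their isotope envelope
#' does not overlap another envelope in the average spectrum, and (iii)
#' their signal is linear in extract concentration across a dilution
#' series.
#'
#' @name maldi
NULL

#' Spot dataset constructor
#'
#' @param spot_id Spot identifier.
#' @param pixels List of pixel spectra, each `list(mz =, intensity =)` with
#'   strictly increasing `mz` and equal lengths.
#' @param metadata Named list (species, treatment, dose, time, replicate,
#'   dilution_factor, ...).
#' @return Object of class `spot_dataset`.
#' @export
spot_dataset <- function(spot_id, pixels, metadata = list()) {
  stopifnot(length(pixels) >= 1L)
  for (i in seq_along(pixels)) {
    px <- pixels[[i]]
    if (length(px$mz) != length(px$intensity)) {
      stop(sprintf("pixel %d: mz/intensity length mismatch", i))
    }
    if (is.unsorted(px$mz, strictly = TRUE)) {
      stop(sprintf("pixel %d: mz must be strictly increasing", i))
    }
    if (any(px$intensity < 0)) {
      stop(sprintf("pixel %d: negative intensity", i))
    }
  }
  structure(list(spot_id = spot_id, pixels = pixels, metadata = metadata),
            class = "spot_dataset")
}

#' @export
print.spot_dataset <- function(x, ...) {
  cat(sprintf("<spot_dataset> '%s': %d pixels\n", x$spot_id,
              length(x$pixels)))
  invisible(x)
}

#' Average spectrum of a spot
#'
#' Resamples every pixel onto a common m/z grid by linear interpolation and
#' takes the arithmetic mean across pixels — the per-pixel average the
#' downstream quantity ("mean intensity per pixel per spot") is read from.
#' When all pixels already share one grid the mean is taken directly.
#'
#' @param spot A `spot_dataset`.
#' @param grid_step Resampling grid spacing in Da (ignored when pixels
#'   share a grid).
#' @return Object of class `average_spectrum`: `mz`, `intensity` (mean per
#'   pixel), `pixel_count`.
#' @export
average_spot <- function(spot, grid_step = 0.005) {
  stopifnot(inherits(spot, "spot_dataset"))
  px <- spot$pixels
  if (!length(px)) stop("empty spot")
  first_mz <- px[[1]]$mz
  shared <- all(vapply(px, function(p) {
    length(p$mz) == length(first_mz) && all(p$mz == first_mz)
  }, logical(1)))
  if (shared) {
    total <- Reduce(`+`, lapply(px, `[[`, "intensity"))
    return(structure(list(mz = first_mz, intensity = total / length(px),
                          pixel_count = length(px)),
                     class = "average_spectrum"))
  }
  lo <- min(vapply(px, function(p) p$mz[1], numeric(1)))
  hi <- max(vapply(px, function(p) p$mz[length(p$mz)], numeric(1)))
  grid <- seq(lo, hi, by = grid_step)
  total <- numeric(length(grid))
  for (p in px) {
    total <- total + stats::approx(p$mz, p$intensity, xout = grid,
                                   yleft = 0, yright = 0)$y
  }
  structure(list(mz = grid, intensity = total / length(px),
                 pixel_count = length(px)),
            class = "average_spectrum")
}

#' @export
print.average_spectrum <- function(x, ...) {
  cat(sprintf("<average_spectrum> %d points, %d pixels, m/z %.2f-%.2f\n",
              length(x$mz), x$pixel_count, min(x$mz), max(x$mz)))
  invisible(x)
}

#' Peak picking on an average spectrum
#'
#' Local maxima above `snr_min` times a robust noise level (median absolute
#' deviation of the signal-free points) are centroided by intensity-weighted
#' mean over the peak's FWHM region. Only centroids whose neutral mass
#' (m/z minus one proton) lies inside `window` are returned.
#'
#' @param avg An `average_spectrum`.
#' @param window Neutral-mass acceptance window in Da.
#' @param snr_min Signal-to-noise threshold.
#' @param constants [mass_constants()] (for the proton mass).
#' @return Data frame `mz` (centroid), `neutral_mass`, `height`, `snr`,
#'   sorted by `mz`.
#' @export
pick_peaks <- function(avg, window = c(2800, 3800), snr_min = 3,
                       constants = mass_constants()) {
  y <- avg$intensity
  n <- length(y)
  if (n < 3L) return(data.frame(mz = numeric(), neutral_mass = numeric(),
                                height = numeric(), snr = numeric()))
  # robust noise: MAD of points below an initial signal cut
  med <- stats::median(y)
  mad0 <- stats::mad(y, center = med)
  quiet <- y <= med + 5 * max(mad0, .Machine$double.eps)
  baseline <- stats::median(y[quiet])
  noise <- stats::mad(y[quiet], center = baseline)
  if (!is.finite(noise) || noise <= 0) noise <- max(mad0, 1e-12)
  thr <- baseline + snr_min * noise
  is_max <- c(FALSE, y[2:(n - 1L)] > y[1:(n - 2L)] &
                y[2:(n - 1L)] >= y[3:n], FALSE) & y > thr
  apex <- which(is_max)
  if (!length(apex)) return(data.frame(mz = numeric(),
                                       neutral_mass = numeric(),
                                       height = numeric(), snr = numeric()))
  cent <- vapply(apex, function(i) {
    half <- y[i] / 2
    l <- i; while (l > 1L && y[l - 1L] >= half && y[l - 1L] <= y[l]) l <- l - 1L
    r <- i; while (r < n && y[r + 1L] >= half && y[r + 1L] <= y[r]) r <- r + 1L
    idx <- l:r
    sum(avg$mz[idx] * y[idx]) / sum(y[idx])
  }, numeric(1))
  out <- data.frame(mz = cent, neutral_mass = cent - constants$proton,
                    height = y[apex], snr = (y[apex] - baseline) / noise)
  out <- out[out$neutral_mass >= window[1] & out$neutral_mass <= window[2],
             , drop = FALSE]
  out <- out[order(out$mz), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Test whether neutral masses fall in the cyclotide acceptance window
#' @param mass Neutral masses in Da.
#' @param window Lower/upper bounds in Da.
#' @return Logical vector.
#' @export
in_mass_window <- function(mass, window = c(2800, 3800)) {
  mass >= window[1] & mass <= window[2]
}

#' Group picked peaks into isotope envelopes
#'
#' Peaks whose spacing from an envelope's monoisotopic member is within
#' `tol` of `k * spacing` (k <= `max_k`) join that envelope; the lightest
#' member is flagged monoisotopic. Chains whose intensity rises
#' substantially after falling (valley-then-rise, impossible for a single
#' peptide envelope in this mass range) are split at the valley; small
#' rises within `min_rise` of the preceding member are attributed to noise.
#'
#' @param candidates Peak data frame from [pick_peaks()] (sorted by mz).
#' @param spacing Isotopologue spacing in Da.
#' @param tol Matching tolerance in Da.
#' @param max_k Maximum isotopologue index considered.
#' @param min_rise Fractional rise over the preceding member needed to
#'   declare a valley-then-rise split.
#' @param max_jump Upper bound on the member-to-member intensity ratio
#'   while the chain is still rising; peptides below 3.8 kDa have
#'   A+1/A ratios under ~1.9, so a larger jump means the chain is trying
#'   to swallow an unrelated (much taller) peak.
#' @return `candidates` with `envelope` (integer id) and `monoisotopic`
#'   (logical) columns.
#' @export
assign_monoisotopic <- function(candidates, spacing = 1.00335, tol = 0.02,
                                max_k = 12L, min_rise = 0.5,
                                max_jump = 2.5) {
  n <- nrow(candidates)
  env <- integer(n)
  if (n) {
    # open envelopes: parallel vectors of mono m/z, last member height and
    # whether the chain has started falling; interleaved envelopes from
    # nearby peptides are disentangled by attaching each peak to the open
    # envelope with the smallest spacing residual
    e_mono <- numeric(); e_last <- numeric(); e_fall <- logical()
    for (i in seq_len(n)) {
      mz_i <- candidates$mz[i]; h_i <- candidates$height[i]
      best <- 0L; best_res <- Inf
      for (e in seq_along(e_mono)) {
        d <- mz_i - e_mono[e]
        k <- round(d / spacing)
        if (k < 1L || k > max_k) next
        res <- abs(d - k * spacing)
        if (res > tol) next
        if (e_fall[e] && h_i > e_last[e] * (1 + min_rise)) next  # valley-rise
        if (!e_fall[e] && h_i > e_last[e] * max_jump) next  # implausible rise
        if (res < best_res) { best <- e; best_res <- res }
      }
      if (best == 0L) {
        e_mono <- c(e_mono, mz_i); e_last <- c(e_last, h_i)
        e_fall <- c(e_fall, FALSE)
        best <- length(e_mono)
      } else {
        if (h_i < e_last[best]) e_fall[best] <- TRUE
        e_last[best] <- h_i
      }
      env[i] <- best
    }
  }
  candidates$envelope <- env
  candidates$monoisotopic <- !duplicated(env)
  candidates
}

#' Flag envelopes that overlap another envelope
#'
#' An envelope is overlapping when any of its member peaks lies within
#' `radius` Da of a member of a different envelope; both parties are
#' flagged. Only credible envelopes (at least `min_peaks` members)
#' participate in the check: one- or two-peak chains at the noise floor are
#' chance alignments, while a genuine peptide envelope in the cyclotide
#' mass window always shows several members.
#'
#' @param envelopes Data frame from [assign_monoisotopic()].
#' @param radius Overlap radius in Da.
#' @param min_peaks Minimum member count for an envelope to count as a
#'   potential overlapper.
#' @return `envelopes` with a logical `non_overlapping` column.
#' @export
overlap_filter <- function(envelopes, radius = 0.2, min_peaks = 3L) {
  bad_env <- integer()
  n_members <- table(envelopes$envelope)
  credible <- as.integer(names(n_members)[n_members >= min_peaks])
  if (nrow(envelopes) > 1L) {
    for (i in 1:(nrow(envelopes) - 1L)) {
      if (!envelopes$envelope[i] %in% credible) next
      j <- i + 1L
      while (j <= nrow(envelopes) &&
             envelopes$mz[j] - envelopes$mz[i] < radius) {
        if (envelopes$envelope[j] != envelopes$envelope[i] &&
            envelopes$envelope[j] %in% credible) {
          bad_env <- c(bad_env, envelopes$envelope[i], envelopes$envelope[j])
        }
        j <- j + 1L
      }
    }
  }
  envelopes$non_overlapping <- !envelopes$envelope %in% bad_env
  envelopes
}

#' Dilution-linearity filter for one ion
#'
#' Least-squares fit of mean intensity against relative concentration
#' (1 / dilution factor); the ion passes when R^2 >= `r2_min` and the slope
#' is positive. With fewer than `min_points` dilution levels the flag is
#' indeterminate (`NA`) and the ion is excluded downstream.
#'
#' @param intensities Mean intensity per pixel at each dilution level.
#' @param dilution_factors Matching dilution factors (> 0).
#' @param r2_min Minimum R^2.
#' @param min_points Minimum number of dilution levels.
#' @return List `pass` (TRUE/FALSE/NA), `r2`, `slope`, `n`.
#' @export
linearity_filter <- function(intensities, dilution_factors, r2_min = 0.9,
                             min_points = 3L) {
  stopifnot(length(intensities) == length(dilution_factors),
            all(dilution_factors > 0))
  n <- length(intensities)
  if (n < min_points) {
    return(list(pass = NA, r2 = NA_real_, slope = NA_real_, n = n))
  }
  conc <- 1 / dilution_factors
  fit <- stats::lm(intensities ~ conc)
  slope <- unname(stats::coef(fit)[2])
  ss_tot <- sum((intensities - mean(intensities))^2)
  r2 <- if (ss_tot == 0) 0 else 1 - sum(stats::residuals(fit)^2) / ss_tot
  list(pass = is.finite(r2) && r2 >= r2_min && isTRUE(slope > 0),
       r2 = r2, slope = slope, n = n)
}

#' Integrated mean intensity per pixel around a centroid
#'
#' Trapezoidal integral of the average spectrum over `centroid +/- radius`.
#' Because the average spectrum is already the per-pixel mean, this is the
#' spot's mean intensity per pixel for that ion.
#'
#' @param avg An `average_spectrum`.
#' @param centroid Centroid m/z.
#' @param radius Integration half-width in Da.
#' @return Non-negative scalar (0 when the window is empty).
#' @export
integrate_ion <- function(avg, centroid, radius = 0.1) {
  idx <- which(avg$mz >= centroid - radius & avg$mz <= centroid + radius)
  if (length(idx) < 2L) return(0)
  sum(diff(avg$mz[idx]) *
        (avg$intensity[idx][-1] + avg$intensity[idx][-length(idx)]) / 2)
}

#' Build the accepted-ion panel from spot spectra
#'
#' Implements the full acceptance chain on a batch of spots from one
#' species: spot averaging, peak picking on the pooled average, envelope
#' grouping, overlap filtering, dilution-linearity filtering on the spots
#' flagged as the dilution series, and per-spot quantification (integrated
#' mean intensity per pixel at the monoisotopic centroid). Ions absent from
#' a spot quantify as 0, not missing.
#'
#' Spots whose metadata contains `series = "dilution"` (with a
#' `dilution_factor` entry) form the dilution series; all other spots are
#' quantification spots and become panel columns. Multiple species'
#' dilution series may be supplied via `extra_dilution_averages`; an ion
#' passes the linearity criterion when it is linear in at least one series.
#'
#' @param spots List of `spot_dataset` objects, or a list of
#'   pre-computed `average_spectrum` objects with metadata attached as
#'   attribute `metadata` (as produced by the synthetic generator's
#'   streaming mode).
#' @param window,snr_min,r2_min,min_points,overlap_radius,quant_radius
#'   Filter parameters (see the individual filter functions).
#' @param overlap_snr Fixed detection sensitivity for envelope grouping
#'   and the overlap assessment. Interfering ions exist in the average
#'   spectrum regardless of the reporting threshold, so overlap status is
#'   judged on peaks above `min(snr_min, overlap_snr)` while `snr_min`
#'   only selects which monoisotopic ions are reported; this keeps the
#'   accepted set monotone in `snr_min`.
#' @param min_envelope_peaks Minimum member peaks an accepted envelope must
#'   show. Peptides in the 2.8-3.8 kDa window have A+1/A abundance ratios
#'   well above one, so a genuine monoisotopic ion above the noise floor is
#'   always accompanied by its A+1 peak; single-member envelopes are noise.
#' @param grid_step Resampling step for [average_spot()].
#' @param constants [mass_constants()].
#' @return Object of class `peak_panel`: list with `ions` (data frame:
#'   `mz`, `neutral_mass`, `in_window`, `non_overlapping`,
#'   `dilution_linear`, `accepted`, `r2`, `slope`), `intensity` (matrix,
#'   accepted ions x quantification spots) and `metadata` (data frame of
#'   spot metadata, one row per column).
#' @export
build_panel <- function(spots, window = c(2800, 3800), snr_min = 3,
                        r2_min = 0.9, min_points = 3L, overlap_radius = 0.2,
                        quant_radius = 0.1, grid_step = 0.005,
                        overlap_snr = 3, min_envelope_peaks = 2L,
                        constants = mass_constants()) {
  averages <- lapply(spots, function(sp) {
    if (inherits(sp, "average_spectrum")) sp
    else {
      a <- average_spot(sp, grid_step)
      attr(a, "metadata") <- sp$metadata
      attr(a, "spot_id") <- sp$spot_id
      a
    }
  })
  meta <- lapply(averages, function(a) {
    m <- attr(a, "metadata")
    if (is.null(m)) list() else m
  })
  series <- vapply(meta, function(m) {
    if (is.null(m$series)) "quant" else as.character(m$series)
  }, character(1))
  qa <- averages[series != "dilution"]
  da <- averages[series == "dilution"]
  if (!length(qa)) stop("no quantification spots supplied")
  # pooled average over quantification spots for ion discovery; spots
  # whose averages sit on different grids are resampled onto a common one
  pooled <- qa[[1]]
  if (length(qa) > 1L) {
    shared <- all(vapply(qa, function(a) {
      length(a$mz) == length(pooled$mz) && all(a$mz == pooled$mz)
    }, logical(1)))
    if (shared) {
      grid <- pooled$mz
      total <- Reduce(`+`, lapply(qa, `[[`, "intensity"))
    } else {
      lo <- min(vapply(qa, function(a) a$mz[1], numeric(1)))
      hi <- max(vapply(qa, function(a) a$mz[length(a$mz)], numeric(1)))
      grid <- seq(lo, hi, by = grid_step)
      total <- numeric(length(grid))
      for (a in qa) {
        total <- total + stats::approx(a$mz, a$intensity, xout = grid,
                                       yleft = 0, yright = 0)$y
      }
    }
    pooled <- structure(list(mz = grid, intensity = total / length(qa),
                             pixel_count = pooled$pixel_count),
                        class = "average_spectrum")
  }
  # discovery uses an extended window so that out-of-window neighbours
  # still participate in envelope grouping, then flags the window
  cand <- pick_peaks(pooled, window = window + c(-20, 20),
                     snr_min = min(snr_min, overlap_snr),
                     constants = constants)
  cand <- assign_monoisotopic(cand)
  cand <- overlap_filter(cand, radius = overlap_radius)
  env_size <- table(cand$envelope)
  mono <- cand[cand$monoisotopic & cand$snr >= snr_min, , drop = FALSE]
  mono$n_peaks <- as.integer(env_size[as.character(mono$envelope)])
  mono$in_window <- in_mass_window(mono$neutral_mass, window)
  # dilution linearity per ion, pass if linear in >= 1 series
  dil_species <- vapply(da, function(a) {
    m <- attr(a, "metadata")
    if (is.null(m$species)) "one" else as.character(m$species)
  }, character(1))
  lin <- lapply(seq_len(nrow(mono)), function(i) {
    if (!length(da)) return(list(pass = NA, r2 = NA_real_,
                                 slope = NA_real_, n = 0L))
    best <- list(pass = NA, r2 = NA_real_, slope = NA_real_, n = 0L)
    for (spc in unique(dil_species)) {
      sel <- which(dil_species == spc)
      ints <- vapply(da[sel], integrate_ion, numeric(1),
                     centroid = mono$mz[i], radius = quant_radius)
      dfs <- vapply(da[sel], function(a) {
        as.numeric(attr(a, "metadata")$dilution_factor)
      }, numeric(1))
      res <- linearity_filter(ints, dfs, r2_min, min_points)
      if (isTRUE(res$pass)) return(res)
      if (is.na(best$pass) ||
          (!is.na(res$pass) && isTRUE(res$r2 > best$r2))) best <- res
    }
    best
  })
  mono$dilution_linear <- vapply(lin, function(l) {
    if (is.na(l$pass)) NA else l$pass
  }, logical(1))
  mono$r2 <- vapply(lin, `[[`, numeric(1), "r2")
  mono$slope <- vapply(lin, `[[`, numeric(1), "slope")
  mono$accepted <- mono$in_window & mono$non_overlapping &
    mono$n_peaks >= min_envelope_peaks &
    !is.na(mono$dilution_linear) & mono$dilution_linear
  acc <- mono[mono$accepted, , drop = FALSE]
  intens <- matrix(0, nrow = nrow(acc), ncol = length(qa))
  for (j in seq_along(qa)) {
    for (i in seq_len(nrow(acc))) {
      intens[i, j] <- integrate_ion(qa[[j]], acc$mz[i], quant_radius)
    }
  }
  spot_ids <- vapply(seq_along(qa), function(j) {
    sid <- attr(qa[[j]], "spot_id")
    if (is.null(sid)) paste0("spot", j) else as.character(sid)
  }, character(1))
  dimnames(intens) <- list(sprintf("%.4f", acc$neutral_mass), spot_ids)
  meta_df <- data.frame(spot_id = spot_ids, stringsAsFactors = FALSE)
  qm <- meta[series != "dilution"]
  for (field in c("species", "metal", "dose", "time_h", "replicate",
                  "dilution_factor")) {
    vals <- vapply(qm, function(m) {
      if (is.null(m[[field]])) NA_character_ else as.character(m[[field]])
    }, character(1))
    if (!all(is.na(vals))) meta_df[[field]] <- utils::type.convert(
      vals, as.is = TRUE)
  }
  rownames(mono) <- NULL
  structure(list(ions = mono[c("mz", "neutral_mass", "height", "snr",
                               "n_peaks", "in_window", "non_overlapping",
                               "dilution_linear", "accepted", "r2",
                               "slope")],
                 intensity = intens, metadata = meta_df),
            class = "peak_panel")
}

#' @export
print.peak_panel <- function(x, ...) {
  cat(sprintf("<peak_panel> %d candidate ion(s), %d accepted, %d spot(s)\n",
              nrow(x$ions), sum(x$ions$accepted), ncol(x$intensity)))
  invisible(x)
}
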