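# small acquisition window keeps the synthetic spectra light
small_cfg <- function(seed = 1, ...) {
  sim_config(seed = seed, pixels_per_spot = 8L, mz_range = c(2830, 2980),
             grid_step = 0.005, baseline_sd = 0.3, ...)
}
two_ions <- c("GLPVCGETCVGGPCNTPGCSCSRPVCTRN",  # 2842.15
              "GLPVCGETCVGGTCNTPGCSCSWPVCKRN")  # 2903.17

test_that("spot averaging is the arithmetic per-pixel mean", {
  mz <- seq(2900, 2910, by = 0.01)
  i1 <- exp(-(mz - 2905)^2); i2 <- 3 * i1
  spot <- spot_dataset("s", list(list(mz = mz, intensity = i1),
                                 list(mz = mz, intensity = i2)))
  avg <- average_spot(spot)
  expect_equal(avg$intensity, 2 * i1)
  expect_identical(avg$pixel_count, 2L)
  # all pixels identical -> average equals any single pixel
  same <- average_spot(spot_dataset("s", list(list(mz = mz, intensity = i1),
                                              list(mz = mz, intensity = i1))))
  expect_equal(same$intensity, i1)
  # order invariance and brute-force mean on a shared grid
  set.seed(2)
  px <- lapply(1:10, function(i) list(mz = mz, intensity = runif(length(mz))))
  avg1 <- average_spot(spot_dataset("a", px))
  avg2 <- average_spot(spot_dataset("a", rev(px)))
  expect_equal(avg1$intensity, avg2$intensity)
  expect_equal(avg1$intensity,
               Reduce(`+`, lapply(px, `[[`, "intensity")) / 10)
  expect_error(spot_dataset("bad", list()), "length")
})

test_that("averaging two spots pooled equals the pixel-weighted mean", {
  mz <- seq(2900, 2905, by = 0.01)
  set.seed(3)
  px_a <- lapply(1:3, function(i) list(mz = mz, intensity = runif(length(mz))))
  px_b <- lapply(1:5, function(i) list(mz = mz, intensity = runif(length(mz))))
  avg_a <- average_spot(spot_dataset("a", px_a))
  avg_b <- average_spot(spot_dataset("b", px_b))
  pooled <- average_spot(spot_dataset("ab", c(px_a, px_b)))
  expect_equal(pooled$intensity,
               (3 * avg_a$intensity + 5 * avg_b$intensity) / 8)
})

test_that("resampling aligns pixels acquired on different grids", {
  f <- function(x) exp(-((x - 2902)^2) / 0.5)
  px <- list(list(mz = seq(2900, 2904, by = 0.004),
                  intensity = f(seq(2900, 2904, by = 0.004))),
             list(mz = seq(2900.001, 2904, by = 0.005),
                  intensity = f(seq(2900.001, 2904, by = 0.005))))
  avg <- average_spot(spot_dataset("s", px), grid_step = 0.005)
  expect_equal(max(avg$intensity), 1, tolerance = 0.01)
})

test_that("peak picking finds planted peaks and ignores flat spectra", {
  flat <- structure(list(mz = seq(2900, 3000, 0.005),
                         intensity = rep(1, 20001), pixel_count = 1L),
                    class = "average_spectrum")
  expect_identical(nrow(pick_peaks(flat)), 0L)
  # single Gaussian at the varv F [M+H]+ position, SNR ~ 50; a high
  # picking threshold leaves exactly the planted centroid
  mz <- seq(2940, 2980, by = 0.005)
  set.seed(4)
  y <- rnorm(length(mz), 1, 0.02) +
    1 * exp(-((mz - 2958.13)^2) / (2 * 0.011^2))
  avg <- structure(list(mz = mz, intensity = y, pixel_count = 1L),
                   class = "average_spectrum")
  pk <- pick_peaks(avg, window = c(2800, 3800), snr_min = 10)
  expect_identical(nrow(pk), 1L)
  expect_lt(abs(pk$mz - 2958.13), 0.02)
  expect_lt(abs(pk$neutral_mass - 2957.12), 0.03)
})

test_that("the 2.8 kDa bound excludes the truncated reference peptide", {
  # vinc A sits below the window; the full-length homologues pass
  expect_false(in_mass_window(cyc_mass("PVCGETCTLGTCYTAGCSCSWPVCTRN")))
  expect_true(in_mass_window(cyc_mass("GVPICGETCTLGTCYTAGCSCSWPVCTRN")))
  in_win <- in_mass_window(ref_table$calculated_mw)
  expect_identical(ref_table$name[!in_win], "vinc A (incomplete)*")
})

test_that("envelope grouping flags the lightest member and splits on shape", {
  cand <- data.frame(mz = 2900 + c(0, 1.0033, 2.0067, 10, 11.0033),
                     height = c(5, 8, 4, 3, 2))
  cand$neutral_mass <- cand$mz - 1.00728
  g <- assign_monoisotopic(cand)
  expect_identical(g$envelope, c(1L, 1L, 1L, 2L, 2L))
  expect_identical(which(g$monoisotopic), c(1L, 4L))
  # single isolated peak forms its own envelope
  one <- assign_monoisotopic(data.frame(mz = 2900, height = 5,
                                        neutral_mass = 2899))
  expect_true(one$monoisotopic)
  # valley followed by a substantial rise starts a new envelope
  v <- data.frame(mz = 2900 + 1.0033 * (0:4),
                  height = c(5, 8, 2, 6, 9))
  v$neutral_mass <- v$mz - 1.00728
  gv <- assign_monoisotopic(v)
  expect_identical(length(unique(gv$envelope)), 2L)
  expect_identical(which(gv$monoisotopic), c(1L, 4L))
})

test_that("interleaved envelopes from nearby peptides stay separate", {
  a <- 2900 + 1.0033 * (0:4); b <- 2901.1 + 1.0033 * (0:4)
  mzs <- sort(c(a, b))
  h <- numeric(10)
  h[match(a, mzs)] <- c(5, 8, 6, 3, 1)
  h[match(b, mzs)] <- c(4, 7, 5, 2, 1)
  cand <- data.frame(mz = mzs, height = h, neutral_mass = mzs - 1.00728)
  g <- assign_monoisotopic(cand)
  expect_identical(length(unique(g$envelope)), 2L)
  expect_identical(g$mz[g$monoisotopic], c(a[1], b[1]))
})

test_that("overlap flags both parties within the radius", {
  mk <- function(mono, n, hshape) {
    data.frame(mz = mono + 1.0033 * (0:(n - 1)), height = hshape[1:n])
  }
  near <- rbind(cbind(mk(2900, 4, c(5, 8, 6, 3)), envelope = 1L),
                cbind(mk(2900.15, 4, c(4, 7, 5, 2)), envelope = 2L))
  near <- near[order(near$mz), ]
  near$monoisotopic <- !duplicated(near$envelope)
  out <- overlap_filter(near, radius = 0.2)
  expect_true(all(!out$non_overlapping))
  far <- rbind(cbind(mk(2900, 4, c(5, 8, 6, 3)), envelope = 1L),
               cbind(mk(2920, 4, c(4, 7, 5, 2)), envelope = 2L))
  far <- far[order(far$mz), ]
  far$monoisotopic <- !duplicated(far$envelope)
  expect_true(all(overlap_filter(far, radius = 0.2)$non_overlapping))
  # single-peak noise chains do not disqualify a genuine envelope
  noisy <- rbind(cbind(mk(2900, 4, c(5, 8, 6, 3)), envelope = 1L),
                 data.frame(mz = 2900.1, height = 0.2, envelope = 2L))
  noisy <- noisy[order(noisy$mz), ]
  noisy$monoisotopic <- !duplicated(noisy$envelope)
  expect_true(all(overlap_filter(noisy)$non_overlapping[
    noisy$envelope == 1L]))
})

test_that("dilution linearity accepts proportional series only", {
  conc4 <- c(1, 2, 4, 8)
  lin <- linearity_filter(100 / conc4, conc4)
  expect_true(lin$pass)
  expect_equal(lin$r2, 1)
  sat <- linearity_filter(rep(50, 4), conc4)
  expect_false(sat$pass)
  neg <- linearity_filter(c(10, 20, 40, 80), conc4)  # increasing with dilution
  expect_false(neg$pass)
  few <- linearity_filter(c(10, 20), c(1, 2))
  expect_true(is.na(few$pass))
})

test_that("the default linearity threshold passes noisy-but-linear series", {
  # Monte-Carlo calibration: 5% multiplicative noise on a true linear
  # 4-level series passes R^2 >= 0.9 in at least 95% of simulations
  set.seed(6)
  passes <- vapply(1:1000, function(i) {
    y <- (100 / c(1, 2, 4, 8)) * rlnorm(4, 0, 0.05)
    isTRUE(linearity_filter(y, c(1, 2, 4, 8))$pass)
  }, logical(1))
  expect_gte(mean(passes), 0.95)
})

test_that("panel quantities scale with global intensity and stay zero for blanks", {
  cfg <- small_cfg(seed = 9)
  ab <- matrix(c(60, 90, 120, 40, 80, 20, 50, 100), nrow = 2)
  colnames(ab) <- paste0("q", 1:4)
  dil <- outer(c(100, 100), 1 / cfg$dilution_factors)
  colnames(dil) <- paste0("d", seq_along(cfg$dilution_factors))
  dmeta <- lapply(cfg$dilution_factors, function(f) {
    list(series = "dilution", dilution_factor = f)
  })
  spots1 <- c(gen_spots(cfg, two_ions, ab, average_only = TRUE),
              gen_spots(cfg, two_ions, dil, dmeta, average_only = TRUE))
  p1 <- build_panel(spots1)
  # scaling every spectrum by c scales every panel quantity by c
  spots2 <- lapply(spots1, function(a) {
    a$intensity <- 3 * a$intensity
    a
  })
  p2 <- build_panel(spots2)
  expect_identical(dim(p1$intensity), dim(p2$intensity))
  expect_equal(p2$intensity, 3 * p1$intensity, tolerance = 1e-6)
  # blank spot quantifies as zeros, not missing
  blank <- matrix(0, 2, 1, dimnames = list(NULL, "blank"))
  spots3 <- c(gen_spots(sim_config(seed = 9, pixels_per_spot = 8L,
                                   mz_range = c(2830, 2980),
                                   baseline_sd = 0),
                        two_ions, blank, average_only = TRUE),
              spots1)
  p3 <- build_panel(spots3)
  expect_true(all(p3$intensity[, "blank"] == 0))
})

test_that("raising acceptance thresholds never adds panel ions", {
  cfg <- small_cfg(seed = 10)
  ab <- matrix(c(60, 90, 120, 40, 80, 20, 50, 100), nrow = 2)
  colnames(ab) <- paste0("q", 1:4)
  dil <- outer(c(100, 100), 1 / cfg$dilution_factors)
  colnames(dil) <- paste0("d", seq_along(cfg$dilution_factors))
  dmeta <- lapply(cfg$dilution_factors, function(f) {
    list(series = "dilution", dilution_factor = f)
  })
  spots <- c(gen_spots(cfg, two_ions, ab, average_only = TRUE),
             gen_spots(cfg, two_ions, dil, dmeta, average_only = TRUE))
  base_mass <- build_panel(spots)$ions
  base_mass <- base_mass$neutral_mass[base_mass$accepted]
  near_base <- function(panel) {
    m <- panel$ions$neutral_mass[panel$ions$accepted]
    length(m) <= length(base_mass) &&
      all(vapply(m, function(x) any(abs(base_mass - x) < 0.05),
                 logical(1)))
  }
  expect_true(near_base(build_panel(spots, snr_min = 10)))
  expect_true(near_base(build_panel(spots, r2_min = 0.99)))
})

test_that("noiseless spectra recover planted masses within 0.01 Da", {
  cfg <- sim_config(seed = 12, pixels_per_spot = 4L,
                    mz_range = c(2830, 2980), baseline_sd = 0, pixel_cv = 0)
  ab <- matrix(c(100, 80), 2, 1, dimnames = list(NULL, "q1"))
  dil <- outer(c(100, 100), 1 / cfg$dilution_factors)
  colnames(dil) <- paste0("d", seq_along(cfg$dilution_factors))
  dmeta <- lapply(cfg$dilution_factors, function(f) {
    list(series = "dilution", dilution_factor = f)
  })
  spots <- c(gen_spots(cfg, two_ions, ab, average_only = TRUE),
             gen_spots(cfg, two_ions, dil, dmeta, average_only = TRUE))
  p <- build_panel(spots)
  acc <- sort(p$ions$neutral_mass[p$ions$accepted])
  truth <- sort(vapply(two_ions, cyc_mass, numeric(1)))
  expect_identical(length(acc), 2L)
  expect_true(all(abs(acc - truth) < 0.01))
})
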