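design27 <- gen_design(sim_config(seed = 1))

test_that("the treatment design validates its structure", {
  expect_identical(nrow(design27), 27L)  # 1 control + 8 cells, x3 replicates
  expect_identical(sum(design27$metal == "none"), 3L)
  expect_error(treatment_design("s1", "sp", "none", 0, 24, 1), "control")
  expect_error(treatment_design("s1", "sp", "Zn", 500, 72, 1), "dose")
})

test_that("one-way ANOVA and Tukey match a by-hand textbook computation", {
  # balanced k=3, n=3 integer data; F and q computed from first principles
  y <- c(10, 12, 14, 20, 22, 24, 30, 31, 35)
  g <- factor(rep(c("a", "b", "c"), each = 3))
  fit <- aov(y ~ g)
  means <- tapply(y, g, mean)
  grand <- mean(y)
  ss_b <- 3 * sum((means - grand)^2)
  ss_w <- sum((y - means[g])^2)
  f_hand <- (ss_b / 2) / (ss_w / 6)
  expect_equal(unname(summary(fit)[[1]][["F value"]][1]), f_hand)
  tk <- TukeyHSD(fit)$g
  q_hand <- abs(means[["b"]] - means[["a"]]) / sqrt((ss_w / 6) / 3)
  p_hand <- ptukey(q_hand, nmeans = 3, df = 6, lower.tail = FALSE)
  expect_equal(unname(tk["b-a", "p adj"]), p_hand, tolerance = 1e-8)
})

test_that("treatment-vs-control contrasts are extracted with correct signs", {
  set.seed(40)
  y <- rnorm(27, 100, 5)
  names(y) <- design27$spot_id
  up <- design27$metal == "Zn" & design27$dose == 2000 &
    design27$time_h == 72
  y[up] <- y[up] + 300
  res <- anova_tukey(y, design27)
  expect_setequal(res$contrasts$group,
                  c("Zn-200", "Zn-2000", "Pb-200", "Pb-2000"))
  zn2000 <- res$contrasts[res$contrasts$group == "Zn-2000", ]
  expect_gt(zn2000$diff, 250)
  expect_lt(zn2000$p_adj, 0.001)
})

test_that("identical groups yield no calls and degenerate data is flagged", {
  y <- rep(5, 27)
  res <- anova_tukey(y, design27)
  expect_true(res$degenerate)
  expect_false(res$any_significant)
  resb <- rm_anova_tukey(y, design27)
  expect_false(resb$any_significant)
  reg <- regulation_matrix(matrix(5, 2, 27,
                                  dimnames = list(c("i1", "i2"),
                                                  design27$spot_id)),
                           design27)
  expect_true(all(reg$call_A == "none") && all(reg$call_B == "none"))
})

test_that("Tukey-adjusted p-values are never smaller than pairwise t-tests", {
  set.seed(41)
  for (k in 1:20) {
    y <- rnorm(27, 100, 20)
    res <- anova_tukey(y, design27)
    sel <- design27$time_h == 72
    y72 <- y[sel]
    grp <- ifelse(design27$metal[sel] == "none", "control",
                  paste0(design27$metal[sel], "-", design27$dose[sel]))
    fit <- aov(y72 ~ factor(grp))
    mse <- summary(fit)[[1]]["Residuals", "Mean Sq"]
    dfe <- summary(fit)[[1]]["Residuals", "Df"]
    for (i in seq_len(nrow(res$contrasts))) {
      gname <- res$contrasts$group[i]
      d <- mean(y72[grp == gname]) - mean(y72[grp == "control"])
      t_stat <- abs(d) / sqrt(mse * 2 / 3)
      p_t <- 2 * pt(t_stat, dfe, lower.tail = FALSE)
      expect_gte(res$contrasts$p_adj[i] + 1e-12, p_t)
    }
  }
})

test_that("repeated-measures contrasts agree with the emmeans oracle", {
  set.seed(42)
  y <- rnorm(27, 100, 15)
  names(y) <- design27$spot_id
  mine <- rm_anova_tukey(y, design27)
  sel <- design27$metal != "none"
  d <- design27[sel, ]
  d$cell <- factor(paste0(d$metal, "-", d$dose))
  d$time <- factor(d$time_h)
  d$subject <- factor(paste(d$cell, d$replicate))
  d$yv <- y[sel]
  # emmeans re-evaluates the aov call, so the data must be findable from
  # the global environment
  assign(".rm_oracle_data", d, envir = globalenv())
  on.exit(rm(".rm_oracle_data", envir = globalenv()), add = TRUE)
  fit <- eval(bquote(aov(yv ~ cell * time + Error(subject),
                         data = .rm_oracle_data)),
              envir = globalenv())
  prs <- as.data.frame(pairs(emmeans::emmeans(fit, ~ time | cell)))
  # same estimates (sign convention: 72 h - 24 h), same error stratum
  expect_equal(mine$contrasts$diff[match(prs$cell, mine$contrasts$group)],
               -prs$estimate, tolerance = 1e-9)
  q_mine <- abs(mine$contrasts$diff) / sqrt(mine$ms_within / 3)
  expect_equal(sort(q_mine), sort(abs(prs$t.ratio) * sqrt(2)),
               tolerance = 1e-9)
  expect_identical(mine$df_within, unique(prs$df))
})

test_that("the paired design absorbs large between-subject variance", {
  # subject offsets dominate, the time effect is null: the RM branch must
  # stay quiet despite huge between-subject spread
  set.seed(43)
  false_alarms <- 0L
  key <- paste0(design27$metal, design27$dose, design27$replicate)
  for (k in 1:50) {
    offs <- rnorm(length(unique(key)), 0, 200)
    names(offs) <- unique(key)
    y <- 100 + offs[key] + rnorm(27, 0, 5)
    res <- rm_anova_tukey(y, design27)
    if (res$any_significant) false_alarms <- false_alarms + 1L
  }
  expect_lte(false_alarms / 50, 0.12)
})

test_that("identical values per subject at both times yield no time calls", {
  key <- paste0(design27$metal, design27$dose, design27$replicate)
  offs <- seq_along(unique(key)) * 10
  names(offs) <- unique(key)
  y <- offs[key]
  res <- suppressWarnings(rm_anova_tukey(y, design27))
  expect_false(isTRUE(res$any_significant))
  expect_true(all(res$contrasts$diff == 0))
})

test_that("unmatched replicates are dropped with a warning", {
  keep <- !(design27$metal == "Zn" & design27$dose == 200 &
              design27$time_h == 24 & design27$replicate == 1)
  d <- design27[keep, ]
  class(d) <- c("treatment_design", "data.frame")
  set.seed(44)
  y <- rnorm(nrow(d), 100, 10)
  expect_warning(rm_anova_tukey(y, d), "unmatched")
})

test_that("regulation calls are invariant under global rescaling", {
  cfg <- sim_config(seed = 45)
  eff <- data.frame(ion = 1, metal = "Pb", dose = 2000, time_h = 72,
                    lfc = 2)
  sim <- gen_ion_intensities(cfg, design27, 3, eff)
  r1 <- regulation_matrix(sim$intensity, design27)
  r2 <- regulation_matrix(sim$intensity * 1e4, design27)
  expect_identical(r1$call_A, r2$call_A)
  expect_identical(r1$call_B, r2$call_B)
  expect_equal(r1$p_A, r2$p_A, tolerance = 1e-8)
})

test_that("planted effects are called and label permutation destroys them", {
  cfg <- sim_config(seed = 46)
  eff <- data.frame(ion = c(1, 2, 3, 4), metal = "Zn", dose = 2000,
                    time_h = 72, lfc = 2)
  sim <- gen_ion_intensities(cfg, design27, 4, eff)
  reg <- regulation_matrix(sim$intensity, design27)
  zn <- reg[reg$group == "Zn-2000", ]
  expect_identical(zn$call_A, rep("up", 4))
  expect_identical(zn$call_B, rep("up", 4))
  # permuting spot labels breaks the association
  set.seed(47)
  n_sig <- 0L; n_perm <- 30L
  for (k in seq_len(n_perm)) {
    perm <- sim$intensity[, sample(ncol(sim$intensity)), drop = FALSE]
    colnames(perm) <- colnames(sim$intensity)
    regp <- regulation_matrix(perm, design27)
    n_sig <- n_sig + sum(regp$call_A != "none")
  }
  # 4 ions x 4 cells per permutation; expect roughly the family error rate
  expect_lt(n_sig / (n_perm * 16), 0.12)
})

test_that("cross-ion BH adjustment only weakens calls", {
  cfg <- sim_config(seed = 48)
  sim <- gen_ion_intensities(cfg, design27, 20)
  raw <- regulation_matrix(sim$intensity, design27)
  bh <- regulation_matrix(sim$intensity, design27, p_adjust_ions = TRUE)
  expect_true(all(bh$p_A + 1e-12 >= raw$p_A, na.rm = TRUE))
  sig_raw <- raw$call_A != "none"
  sig_bh <- bh$call_A != "none"
  expect_true(all(!sig_bh | sig_raw))
})
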