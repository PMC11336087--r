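#' Treatment-response statistics
#'
#' Two contrast families are computed per ion, mirroring the study design
#' of metal-treated *Viola* cell suspensions:
#'
#' * family A (control vs 72 h): one-way ANOVA across the five 72-h groups
#'   (control, Zn 200, Zn 2000, Pb 200, Pb 2000) followed by Tukey's HSD;
#'   the four treatment-vs-control contrasts are read off.
#' * family B (24 h vs 72 h): repeated-measures ANOVA with biological
#'   replicate as subject (each replicate measured at both times), followed
#'   by Tukey's HSD on the time-within-treatment cell means using the
#'   within-subject error stratum.
#'
#' A regulation call is `up`/`down` only when the Tukey-adjusted p-value is
#' at most `alpha` and the mean difference has the corresponding sign.
#' Analyses are per ion with no cross-ion multiplicity correction by
#' default (Benjamini-Hochberg available via `p_adjust_ions`).
#'
#' @name stats-module
NULL

#' Treatment design constructor / validator
#'
#' @param spot_id,species,metal,dose,time_h,replicate Vectors of equal
#'   length; `metal` in `none/Zn/Pb`, `dose` in 0/200/2000 (uM), `time_h`
#'   in 24/72, `replicate` the biological replicate id. Control rows must
#'   have `metal = "none"`, `dose = 0`, `time_h = 72` (controls are
#'   harvested alongside the 72-h treatments).
#' @return Validated data frame of class `treatment_design`.
#' @export
treatment_design <- function(spot_id, species, metal, dose, time_h,
                             replicate) {
  d <- data.frame(spot_id = as.character(spot_id),
                  species = as.character(species),
                  metal = as.character(metal),
                  dose = as.numeric(dose),
                  time_h = as.numeric(time_h),
                  replicate = as.integer(replicate),
                  stringsAsFactors = FALSE)
  stopifnot(all(d$metal %in% c("none", "Zn", "Pb")),
            all(d$time_h %in% c(24, 72)))
  ctrl <- d$metal == "none"
  if (any(ctrl & (d$dose != 0 | d$time_h != 72))) {
    stop("control rows must have dose 0 and time 72 h")
  }
  if (any(!ctrl & !d$dose %in% c(200, 2000))) {
    stop("treatment doses must be 200 or 2000 uM")
  }
  if (anyDuplicated(d$spot_id)) stop("duplicate spot ids in design")
  class(d) <- c("treatment_design", "data.frame")
  d
}

.group_label <- function(metal, dose) {
  ifelse(metal == "none", "control", paste0(metal, "-", dose))
}

#' One-way ANOVA + Tukey HSD for the control vs 72 h family
#'
#' @param y Numeric response (one ion's per-spot intensities).
#' @param design A [treatment_design()] aligned with `y`.
#' @return List: `p_anova`, `contrasts` (data frame `group`, `diff`
#'   = treated - control, `p_adj`), `degenerate` (TRUE when all groups are
#'   exact ties so no test is possible), `any_significant` over all Tukey
#'   pairs at alpha = 0.05.
#' @export
anova_tukey <- function(y, design) {
  sel <- design$time_h == 72
  y72 <- y[sel]
  grp <- factor(.group_label(design$metal[sel], design$dose[sel]))
  stopifnot(nlevels(grp) >= 2L, all(table(grp) >= 2L))
  if (all(tapply(y72, grp, function(v) max(v) - min(v)) == 0)) {
    lev <- setdiff(levels(grp), "control")
    return(list(p_anova = NA_real_,
                contrasts = data.frame(group = lev,
                                       diff = rep(0, length(lev)),
                                       p_adj = rep(NA_real_, length(lev))),
                degenerate = TRUE, any_significant = FALSE))
  }
  fit <- stats::aov(y72 ~ grp)
  p_anova <- summary(fit)[[1]][["Pr(>F)"]][1]
  tk <- stats::TukeyHSD(fit)$grp
  cn <- rownames(tk)
  vs_control <- grepl("(^control-)|(-control$)", cn)
  sub <- tk[vs_control, , drop = FALSE]
  # orient differences as treated - control
  grp_name <- sub("-?control-?", "", rownames(sub))
  sign_flip <- ifelse(grepl("^control-", rownames(sub)), -1, 1)
  list(p_anova = p_anova,
       contrasts = data.frame(group = grp_name,
                              diff = unname(sub[, "diff"] * sign_flip),
                              p_adj = unname(sub[, "p adj"])),
       degenerate = FALSE,
       any_significant = any(tk[, "p adj"] <= 0.05, na.rm = TRUE))
}

#' Repeated-measures ANOVA + Tukey for the 24 h vs 72 h family
#'
#' Biological replicate is the subject (measured at 24 h and 72 h); the
#' model is `y ~ cell * time + Error(subject)` with `cell = metal:dose`.
#' Tukey's HSD is applied to the time-within-cell contrasts using the
#' within-subject mean square and the studentized range over all
#' cell-by-time means. Replicates lacking one of the two time points are
#' dropped with a warning.
#'
#' @inheritParams anova_tukey
#' @return List: `contrasts` (data frame `group`, `diff` = 72 h - 24 h,
#'   `p_adj`), `ms_within`, `df_within`, `degenerate`, `any_significant`.
#' @export
rm_anova_tukey <- function(y, design) {
  sel <- design$metal != "none"
  d <- design[sel, , drop = FALSE]
  yv <- y[sel]
  d$cell <- .group_label(d$metal, d$dose)
  d$subject <- paste(d$cell, d$replicate, sep = "/")
  # drop subjects without both time points
  tt <- table(d$subject, d$time_h)
  ok_subj <- rownames(tt)[tt[, "24"] == 1L & tt[, "72"] == 1L]
  if (length(ok_subj) < length(unique(d$subject))) {
    warning(sprintf("dropping %d replicate(s) unmatched across times",
                    length(unique(d$subject)) - length(ok_subj)))
  }
  keep <- d$subject %in% ok_subj
  d <- d[keep, , drop = FALSE]; yv <- yv[keep]
  cells <- sort(unique(d$cell))
  empty <- data.frame(group = character(), diff = numeric(),
                      p_adj = numeric())
  if (!length(cells) || !length(yv)) {
    return(list(contrasts = empty, ms_within = NA_real_,
                df_within = NA_real_, degenerate = TRUE,
                any_significant = FALSE))
  }
  cellf <- factor(d$cell); timef <- factor(d$time_h)
  subjf <- factor(d$subject)
  fit <- stats::aov(yv ~ cellf * timef + Error(subjf))
  within <- summary(fit)[["Error: Within"]][[1]]
  ms_within <- within["Residuals", "Mean Sq"]
  df_within <- within["Residuals", "Df"]
  n_per_cell <- min(table(d$cell, d$time_h))
  means <- tapply(yv, list(d$cell, d$time_h), mean)
  n_means <- length(cells) * 2L
  if (!is.finite(ms_within) || ms_within <= 0 || df_within < 1) {
    return(list(contrasts = data.frame(group = cells,
                                       diff = unname(means[cells, "72"] -
                                                       means[cells, "24"]),
                                       p_adj = NA_real_),
                ms_within = ms_within, df_within = df_within,
                degenerate = TRUE, any_significant = FALSE))
  }
  diffs <- means[cells, "72"] - means[cells, "24"]
  se <- sqrt(ms_within / n_per_cell)
  q <- abs(diffs) / se
  p_adj <- stats::ptukey(q, nmeans = n_means, df = df_within,
                         lower.tail = FALSE)
  list(contrasts = data.frame(group = cells, diff = unname(diffs),
                              p_adj = unname(p_adj)),
       ms_within = ms_within, df_within = df_within, degenerate = FALSE,
       any_significant = any(p_adj <= 0.05, na.rm = TRUE))
}

.call_from <- function(diff, p_adj, alpha) {
  ifelse(is.na(p_adj) | p_adj > alpha, "none",
         ifelse(diff > 0, "up", "down"))
}

#' Regulation matrix over all ions and contrasts
#'
#' Runs both contrast families for every panel ion and assembles the
#' machine analogue of an up/down regulation table: one row per ion and
#' treatment cell with `call_A` (control vs 72 h) and `call_B` (24 h vs
#' 72 h).
#'
#' @param panel A `peak_panel` (or a plain intensity matrix, ions x spots).
#' @param design A [treatment_design()] whose `spot_id`s match the panel
#'   columns.
#' @param alpha Significance level for calls.
#' @param transform `"identity"` (raw intensities, the default) or
#'   `"log10"` (applied as `log10(x + 1)`).
#' @param p_adjust_ions Apply Benjamini-Hochberg across ions within each
#'   contrast before calling (off by default).
#' @return Object of class `regulation_table`: data frame `ion`, `group`
#'   (metal-dose cell), `diff_A`, `p_A`, `call_A`, `diff_B`, `p_B`,
#'   `call_B`.
#' @export
regulation_matrix <- function(panel, design, alpha = 0.05,
                              transform = c("identity", "log10"),
                              p_adjust_ions = FALSE) {
  transform <- match.arg(transform)
  intens <- if (inherits(panel, "peak_panel")) panel$intensity else panel
  stopifnot(is.matrix(intens))
  design <- design[match(colnames(intens), design$spot_id), , drop = FALSE]
  if (anyNA(design$spot_id)) stop("panel columns missing from design")
  if (transform == "log10") intens <- log10(intens + 1)
  rows <- list()
  for (i in seq_len(nrow(intens))) {
    ion <- rownames(intens)[i]
    a <- anova_tukey(intens[i, ], design)
    b <- rm_anova_tukey(intens[i, ], design)
    groups <- sort(unique(c(a$contrasts$group, b$contrasts$group)))
    ia <- match(groups, a$contrasts$group)
    ib <- match(groups, b$contrasts$group)
    rows[[i]] <- data.frame(
      ion = ion, group = groups,
      diff_A = a$contrasts$diff[ia], p_A = a$contrasts$p_adj[ia],
      diff_B = b$contrasts$diff[ib], p_B = b$contrasts$p_adj[ib])
  }
  out <- do.call(rbind, rows)
  if (p_adjust_ions) {
    out$p_A <- stats::ave(out$p_A, out$group,
                          FUN = function(p) stats::p.adjust(p, "BH"))
    out$p_B <- stats::ave(out$p_B, out$group,
                          FUN = function(p) stats::p.adjust(p, "BH"))
  }
  out$call_A <- .call_from(out$diff_A, out$p_A, alpha)
  out$call_B <- .call_from(out$diff_B, out$p_B, alpha)
  out <- out[c("ion", "group", "diff_A", "p_A", "call_A",
               "diff_B", "p_B", "call_B")]
  rownames(out) <- NULL
  class(out) <- c("regulation_table", "data.frame")
  out
}

#' Summarise a regulation table as counts per cell
#' @param object A `regulation_table`.
#' @param ... Unused.
#' @return Data frame of up/down/none counts per group and family.
#' @method summary regulation_table
#' @export
summary.regulation_table <- function(object, ...) {
  x <- as.data.frame(object)
  do.call(rbind, lapply(split(x, x$group), function(g) {
    data.frame(group = g$group[1],
               up_A = sum(g$call_A == "up"), down_A = sum(g$call_A == "down"),
               up_B = sum(g$call_B == "up"), down_B = sum(g$call_B == "down"),
               n = nrow(g))
  }))
}
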