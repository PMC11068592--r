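#' Paired and independent t-tests with standardized effect sizes
#'
#' Two-tailed Student t-tests reporting Cohen's dz (paired: mean difference
#' over the SD of differences) or Cohen's d (independent: mean difference
#' over the Bessel-corrected pooled SD). Zero variance makes the statistic
#' undefined and is an explicit error. An optional comparison count `m`
#' attaches a Bonferroni-adjusted p.
#'
#' @param x,y numeric vectors; equal length for the paired test.
#' @param m optional number of comparisons for Bonferroni adjustment.
#' @return An object of class `fpvs_ttest`: `kind`, `t`, `df`, `p`,
#'   `effect` (dz or d), `mean_diff`, `bonferroni_m`, `p_adj`.
#' @export
paired_t <- function(x, y, m = NULL) {
  if (length(x) != length(y)) stop("paired test needs equal lengths")
  if (length(x) < 2) stop("need at least two pairs")
  d <- x - y
  sdd <- stats::sd(d)
  if (sdd == 0) stop("zero variance of differences; t undefined")
  n <- length(d)
  t <- mean(d) / (sdd / sqrt(n))
  .ttest_result("paired", t, n - 1L, mean(d) / sdd, mean(d), m)
}

#' @rdname paired_t
#' @export
independent_t <- function(x, y, m = NULL) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) stop("need at least two observations per group")
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2)
  if (sp2 == 0) stop("zero pooled variance; t undefined")
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  .ttest_result("independent", t, n1 + n2 - 2L,
                (mean(x) - mean(y)) / sqrt(sp2), mean(x) - mean(y), m)
}

.ttest_result <- function(kind, t, df, effect, mean_diff, m) {
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  structure(list(kind = kind, t = t, df = df, p = p, effect = effect,
                 mean_diff = mean_diff,
                 bonferroni_m = m,
                 p_adj = if (is.null(m)) NA_real_ else min(1, m * p)),
            class = "fpvs_ttest")
}

#' @export
print.fpvs_ttest <- function(x, ...) {
  eff <- if (x$kind == "paired") "dz" else "d"
  cat(sprintf("%s t(%d) = %.3f, p = %.4g, %s = %.3f%s\n",
              x$kind, x$df, x$t, x$p, eff, x$effect,
              if (is.na(x$p_adj)) "" else
                sprintf(" (Bonferroni m = %d: p_adj = %.4g)",
                        x$bonferroni_m, x$p_adj)))
  invisible(x)
}

#' Bonferroni adjustment
#'
#' `p_adj = min(1, m * p)` for a fixed comparison count `m`, preserving
#' order.
#'
#' @param p_values numeric vector of raw p-values.
#' @param m comparison count; must be at least `length(p_values)`.
#' @return Adjusted p-values.
#' @export
bonferroni_adjust <- function(p_values, m = length(p_values)) {
  if (m < length(p_values)) stop("`m` must be >= the number of p-values")
  pmin(1, m * p_values)
}

# collapse the two parieto-occipital rows to one value per
# subject x stimulus type x condition
.collapse_laterality <- function(po) {
  agg <- stats::aggregate(
    po$value, by = list(subject = po$subject, group = po$group,
                        stimulus_type = po$stimulus_type,
                        condition = po$condition), FUN = mean)
  names(agg)[names(agg) == "x"] <- "value"
  agg
}

# value vector for one cell, in a fixed subject order
.cell_values <- function(tab, subjects, st, cond) {
  sel <- tab$stimulus_type == st & tab$condition == cond
  v <- tab$value[sel][match(subjects, tab$subject[sel])]
  if (anyNA(v)) stop("incomplete table for ", st, "/", cond)
  v
}

#' Run the full analysis decision tree
#'
#' Executes the study's statistical plan on an ROI summary table: the
#' omnibus mixed ANOVA for the parieto-occipital clusters (Stimulus Type x
#' Condition x Laterality x Group) and for the frontocentral cluster
#' (Stimulus Type x Condition x Group), followed per stimulus type by a
#' Condition x Group ANOVA (parieto-occipital, collapsed over
#' laterality), pairwise condition paired t-tests, and between-group
#' independent t-tests on the three condition difference scores
#' (Self-CloseOther, Self-Stranger, CloseOther-Stranger). Raw and
#' Bonferroni-adjusted p-values are both reported. Greenhouse-Geisser
#' corrected p-values are used for any effect whose Mauchly test is
#' significant.
#'
#' With a single group the group terms are skipped with a notice.
#'
#' @param table an `fpvs_subject_table` (rows for the `left-PO`,
#'   `right-PO` and `frontocentral` ROIs).
#' @param alpha significance level used when flagging effects.
#' @return An object of class `fpvs_contrast_report`: a list with
#'   `po_anova`, `fc_anova`, per-stimulus-type `followups` (each holding
#'   the Condition x Group ANOVA, pairwise t-tests and group difference
#'   tests) and `flags` (named logicals/directions for the headline
#'   effects).
#' @export
run_paper_contrasts <- function(table, alpha = 0.05) {
  tab <- as.data.frame(table)
  stim_types <- sort(unique(tab$stimulus_type))
  groups <- unique(tab$group)
  two_groups <- length(groups) >= 2
  if (!two_groups) message("single-group input: group terms skipped")
  po <- tab[tab$roi %in% c("left-PO", "right-PO"), , drop = FALSE]
  fc <- tab[tab$roi == "frontocentral", , drop = FALSE]
  if (!nrow(po) || !nrow(fc))
    stop("table must contain left-PO, right-PO and frontocentral rows")

  wf_po <- c(if (length(stim_types) > 1) "stimulus_type", "condition",
             "laterality")
  wf_fc <- c(if (length(stim_types) > 1) "stimulus_type", "condition")
  between <- if (two_groups) "group" else NULL
  po_anova <- mixed_anova(po, dv = "value", within = wf_po, between = between)
  fc_anova <- mixed_anova(fc, dv = "value", within = wf_fc, between = between)

  pocl <- .collapse_laterality(po)
  pairs <- list(c("Self", "CloseOther"), c("Self", "Stranger"),
                c("CloseOther", "Stranger"))
  followups <- list()
  for (st in stim_types) {
    sub <- pocl[pocl$stimulus_type == st, , drop = FALSE]
    an <- mixed_anova(sub, dv = "value", within = "condition",
                      between = between)
    subjects <- sort(unique(sub$subject))
    pw <- lapply(pairs, function(pr) {
      tt <- paired_t(.cell_values(sub, subjects, st, pr[1]),
                     .cell_values(sub, subjects, st, pr[2]),
                     m = length(pairs))
      tt$comparison <- paste(pr, collapse = " vs ")
      tt
    })
    gd <- NULL
    if (two_groups) {
      gmap <- unique(sub[c("subject", "group")])
      grp <- gmap$group[match(subjects, gmap$subject)]
      g1 <- groups[1]; g2 <- groups[2]
      gd <- lapply(pairs, function(pr) {
        diff <- .cell_values(sub, subjects, st, pr[1]) -
          .cell_values(sub, subjects, st, pr[2])
        tt <- independent_t(diff[grp == g1], diff[grp == g2],
                            m = length(pairs))
        tt$comparison <- sprintf("(%s - %s): %s vs %s", pr[1], pr[2], g1, g2)
        tt
      })
    }
    followups[[st]] <- list(condition_anova = an, pairwise = pw,
                            group_difference = gd)
  }

  # headline flags
  report_p <- function(an, effect) {
    i <- match(effect, an$effect)
    if (is.na(i)) return(NA_real_)
    if (!is.na(an$sphericity_violated[i]) && an$sphericity_violated[i] &&
        !is.na(an$p_gg[i])) an$p_gg[i] else an$p[i]
  }
  flags <- list()
  if (two_groups) {
    for (st in stim_types) {
      an <- followups[[st]]$condition_anova
      flags[[paste0(tolower(st), "_condition_group_p")]] <-
        report_p(an, "condition:group")
      flags[[paste0(tolower(st), "_condition_group_significant")]] <-
        isTRUE(report_p(an, "condition:group") < alpha)
    }
    # direction: group ordering of the Self - CloseOther difference (Faces)
    if ("Faces" %in% stim_types) {
      sub <- pocl[pocl$stimulus_type == "Faces", , drop = FALSE]
      subjects <- sort(unique(sub$subject))
      gmap <- unique(sub[c("subject", "group")])
      grp <- gmap$group[match(subjects, gmap$subject)]
      dsc <- .cell_values(sub, subjects, "Faces", "Self") -
        .cell_values(sub, subjects, "Faces", "CloseOther")
      means <- tapply(dsc, grp, mean)
      flags$faces_self_minus_close_by_group <- means
    }
  }
  structure(list(po_anova = po_anova, fc_anova = fc_anova,
                 followups = followups, flags = flags,
                 alpha = alpha, groups = groups),
            class = "fpvs_contrast_report")
}

#' @export
print.fpvs_contrast_report <- function(x, ...) {
  cat("==== Parieto-occipital omnibus ANOVA ====\n")
  print(x$po_anova)
  cat("\n==== Frontocentral omnibus ANOVA ====\n")
  print(x$fc_anova)
  for (st in names(x$followups)) {
    cat("\n==== Follow-up:", st, "====\n")
    print(x$followups[[st]]$condition_anova)
    cat("\nPairwise condition tests (paired):\n")
    for (tt in x$followups[[st]]$pairwise) {
      cat("  ", tt$comparison, ": ", sep = ""); print(tt)
    }
    if (!is.null(x$followups[[st]]$group_difference)) {
      cat("Group comparisons of difference scores (independent):\n")
      for (tt in x$followups[[st]]$group_difference) {
        cat("  ", tt$comparison, ": ", sep = ""); print(tt)
      }
    }
  }
  invisible(x)
}
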