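# Orthonormal polynomial-free contrasts for a k-level factor: normalized
# Helmert columns, orthogonal to the unit vector.
.orth_contrasts <- function(k) {
  C <- stats::contr.helmert(k)
  C %*% diag(1 / sqrt(colSums(C^2)), ncol(C))
}

# Kronecker contrast matrix (m x d) for the within-effect given by `in_w`
# (logical over within factors, cell order = expand.grid over levels with
# the FIRST factor varying fastest).
.effect_contrast <- function(levels_list, in_w) {
  mats <- lapply(seq_along(levels_list), function(i) {
    k <- length(levels_list[[i]])
    if (in_w[i]) .orth_contrasts(k) else matrix(1 / sqrt(k), k, 1)
  })
  # expand.grid varies the first factor fastest; kronecker's rightmost
  # factor varies fastest, so reverse
  out <- mats[[length(mats)]]
  if (length(mats) > 1)
    for (i in rev(seq_len(length(mats) - 1))) out <- out %x% mats[[i]]
  out
}

# Reshape a long table into subjects x within-cells, checking completeness.
# Returns list(Y, group, levels_list, cell_grid).
.table_to_matrix <- function(table, dv, within, between, subject) {
  x <- as.data.frame(table)
  miss <- setdiff(c(dv, within, subject, between), names(x))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  levels_list <- lapply(within, function(w) sort(unique(as.character(x[[w]]))))
  names(levels_list) <- within
  grid <- expand.grid(levels_list, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  subj <- sort(unique(as.character(x[[subject]])))
  m <- nrow(grid)
  key_x <- do.call(paste, c(lapply(within, function(w) as.character(x[[w]])),
                            sep = "\r"))
  key_g <- do.call(paste, c(lapply(within, function(w) grid[[w]]), sep = "\r"))
  Y <- matrix(NA_real_, length(subj), m,
              dimnames = list(subj, NULL))
  r <- match(as.character(x[[subject]]), subj)
  cc <- match(key_x, key_g)
  if (anyNA(cc)) stop("rows with unmatched within-factor levels")
  if (anyDuplicated(cbind(r, cc))) {
    i <- which(duplicated(cbind(r, cc)))[1]
    stop("duplicate cell for subject ", subj[r[i]], " (",
         gsub("\r", "/", key_x[i]), ")")
  }
  Y[cbind(r, cc)] <- x[[dv]]
  if (anyNA(Y)) {
    bad <- which(is.na(Y), arr.ind = TRUE)[1, ]
    stop("design not complete: subject ", subj[bad[1]], " lacks cell ",
         gsub("\r", "/", key_g[bad[2]]))
  }
  group <- NULL
  if (!is.null(between)) {
    gmap <- unique(x[c(subject, between)])
    if (anyDuplicated(gmap[[subject]]))
      stop("a subject appears in more than one group")
    group <- factor(gmap[[between]][match(subj, gmap[[subject]])])
  }
  list(Y = Y, group = group, levels_list = levels_list, grid = grid)
}

# pooled within-group covariance of contrast scores U (n x d)
.pooled_cov <- function(U, group) {
  if (is.null(group)) group <- factor(rep(1, nrow(U)))
  g <- nlevels(group)
  S <- matrix(0, ncol(U), ncol(U))
  for (lv in levels(group)) {
    Ug <- U[group == lv, , drop = FALSE]
    Ugc <- sweep(Ug, 2, colMeans(Ug))
    S <- S + crossprod(Ugc)
  }
  S / (nrow(U) - g)
}

.gg_from_cov <- function(S) {
  d <- ncol(S)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  (sum(ev))^2 / (d * sum(ev^2))
}

#' Mixed-design repeated-measures ANOVA
#'
#' Univariate decomposition for a balanced design with any number of
#' crossed within-subject factors and at most one between-subjects factor:
#' the between-subject variation is split into the group effect and
#' subject-within-group error; every within effect and its group
#' interaction are tested against the matching effect-by-subject error
#' stratum. Partial eta squared is reported per effect, and for within
#' effects with more than one numerator df the Greenhouse-Geisser epsilon,
#' Mauchly's test and the epsilon-corrected p-value are computed from the
#' pooled covariance of the effect's orthonormal contrast scores.
#' Following common reporting practice, the corrected p is flagged as the
#' one to report (`sphericity_violated`) when Mauchly's p < .05.
#'
#' The sums of squares follow the sequential convention of `aov` (within
#' effects computed about the all-subjects mean), which coincides with the
#' Type III decomposition whenever group sizes are equal; the design must
#' be complete (every subject measured in every within cell).
#'
#' @param table long-format data (e.g. an `fpvs_subject_table`).
#' @param dv name of the response column (microvolts in this package).
#' @param within character vector of within-subject factor columns.
#' @param between name of the between-subjects factor column, or `NULL`
#'   for a fully within design.
#' @param subject name of the subject identifier column.
#' @return An object of class `fpvs_anova`: a data frame with one row per
#'   effect (`effect`, `ss`, `df`, `ss_error`, `df_error`, `F`, `p`,
#'   `pes`, `epsilon_gg`, `p_gg`, `mauchly_w`, `mauchly_p`,
#'   `sphericity_violated`), plus attributes `ss_total` and `n_subjects`.
#' @examples
#' tab <- expand.grid(subject = paste0("s", 1:8),
#'                    condition = c("a", "b", "c"))
#' tab$group <- rep(c("g1", "g2"), each = 4)[match(tab$subject,
#'                                                 paste0("s", 1:8))]
#' tab$value <- stats::rnorm(nrow(tab))
#' mixed_anova(tab, dv = "value", within = "condition", between = "group")
#' @export
mixed_anova <- function(table, dv = "value", within, between = "group",
                        subject = "subject") {
  dat <- .table_to_matrix(table, dv, within, between, subject)
  Y <- dat$Y
  group <- dat$group
  N <- nrow(Y); m <- ncol(Y)
  if (!is.null(group) && nlevels(group) < 2) {
    group <- NULL
    message("only one group present; between-subject terms skipped")
  }
  g <- if (is.null(group)) 1L else nlevels(group)
  if (N < g + 1) stop("need at least two subjects per group")
  grand <- mean(Y)

  rows <- list()
  add_row <- function(effect, ss, df, ss_err, df_err, eps = NA, wst = NA,
                      wp = NA) {
    F <- (ss / df) / (ss_err / df_err)
    p <- stats::pf(F, df, df_err, lower.tail = FALSE)
    p_gg <- if (!is.na(eps) && df > 1)
      stats::pf(F, eps * df, eps * df_err, lower.tail = FALSE) else NA_real_
    rows[[length(rows) + 1L]] <<- data.frame(
      effect = effect, ss = ss, df = df, ss_error = ss_err,
      df_error = df_err, F = F, p = p, pes = ss / (ss + ss_err),
      epsilon_gg = if (df > 1) eps else NA_real_, p_gg = p_gg,
      mauchly_w = wst, mauchly_p = wp,
      sphericity_violated = if (!is.na(wp)) wp < 0.05 else NA)
  }

  # between-subject stratum
  subj_means <- rowMeans(Y)
  if (!is.null(group)) {
    gm <- tapply(subj_means, group, mean)
    ng <- tabulate(group)
    ss_g <- m * sum(ng * (gm - grand)^2)
    ss_s <- m * sum((subj_means - gm[as.integer(group)])^2)
    add_row(between, ss_g, g - 1L, ss_s, N - g)
  } else {
    ss_s <- m * sum((subj_means - grand)^2)
  }

  # within strata: every nonempty subset of the within factors
  p_fac <- length(within)
  for (mask in seq_len(2^p_fac - 1L)) {
    in_w <- as.logical(bitwAnd(mask, 2^(seq_len(p_fac) - 1L)))
    C <- .effect_contrast(dat$levels_list, in_w)
    d <- ncol(C)
    U <- Y %*% C
    ubar <- colMeans(U)
    ss_w <- N * sum(ubar^2)
    if (!is.null(group)) {
      ss_cells <- 0
      for (lv in levels(group)) {
        Ug <- U[group == lv, , drop = FALSE]
        ss_cells <- ss_cells + nrow(Ug) * sum(colMeans(Ug)^2)
      }
      ss_wg <- ss_cells - ss_w
      ss_err <- sum(U^2) - ss_cells
    } else {
      ss_wg <- NA
      ss_err <- sum(U^2) - ss_w
    }
    df_err <- d * (N - g)
    eps <- NA_real_; wst <- NA_real_; wp <- NA_real_
    if (d > 1) {
      S <- .pooled_cov(U, group)
      eps <- max(.gg_from_cov(S), 1 / d)
      msph <- .mauchly_from_cov(S, N - g)
      wst <- msph$W; wp <- msph$p
    }
    nm <- paste(within[in_w], collapse = ":")
    add_row(nm, ss_w, d, ss_err, df_err, eps, wst, wp = wp)
    if (!is.null(group))
      add_row(paste(nm, between, sep = ":"), ss_wg, d * (g - 1L), ss_err,
              df_err, eps, wst, wp = wp)
  }

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "ss_total") <- sum((Y - grand)^2)
  attr(out, "n_subjects") <- N
  class(out) <- c("fpvs_anova", "data.frame")
  out
}

#' @export
print.fpvs_anova <- function(x, digits = 4, ...) {
  cat("Mixed-design repeated-measures ANOVA (", attr(x, "n_subjects"),
      " subjects)\n\n", sep = "")
  fmt <- as.data.frame(x)
  fmt$ss <- signif(fmt$ss, digits); fmt$ss_error <- signif(fmt$ss_error, digits)
  fmt$F <- round(fmt$F, 2)
  fmt$p <- signif(fmt$p, 3); fmt$pes <- round(fmt$pes, 2)
  fmt$epsilon_gg <- round(fmt$epsilon_gg, 3)
  fmt$p_gg <- signif(fmt$p_gg, 3)
  fmt$mauchly_w <- round(fmt$mauchly_w, 3)
  fmt$mauchly_p <- signif(fmt$mauchly_p, 3)
  fmt$sphericity_violated <- NULL
  print(fmt, row.names = FALSE)
  viol <- x$effect[!is.na(x$sphericity_violated) & x$sphericity_violated]
  if (length(viol))
    cat("\nSphericity violated (Mauchly p < .05); report p_gg for:",
        paste(unique(viol), collapse = ", "), "\n")
  invisible(x)
}

# Mauchly's test from a pooled contrast covariance with n' error df
.mauchly_from_cov <- function(S, n_err) {
  d <- ncol(S)
  if (d < 2) return(list(W = NA_real_, chi_sq = NA_real_, df = NA_real_,
                         p = NA_real_))
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0))
    return(list(W = 0, chi_sq = Inf, df = d * (d + 1) / 2 - 1, p = 0))
  W <- prod(ev) / (mean(ev))^d
  rho <- 1 - (2 * d^2 + d + 2) / (6 * d * n_err)
  chi <- -n_err * rho * log(W)
  df <- d * (d + 1) / 2 - 1
  list(W = W, chi_sq = chi, df = df,
       p = stats::pchisq(chi, df, lower.tail = FALSE))
}

# contrast scores of one within factor, other within factors averaged out
.factor_scores <- function(table, factor, dv, between, subject) {
  x <- as.data.frame(table)
  for (col in c(factor, subject)) x[[col]] <- as.character(x[[col]])
  lev <- sort(unique(x[[factor]]))
  k <- length(lev)
  if (k < 3) stop("factor `", factor, "` has ", k,
                  " levels; sphericity holds trivially for k < 3")
  agg <- stats::aggregate(x[[dv]],
                          by = list(subject = x[[subject]],
                                    level = x[[factor]]), FUN = mean)
  subj <- sort(unique(agg$subject))
  Y <- matrix(NA_real_, length(subj), k, dimnames = list(subj, lev))
  Y[cbind(match(agg$subject, subj), match(agg$level, lev))] <- agg$x
  if (anyNA(Y)) stop("design not complete for factor ", factor)
  group <- NULL
  if (!is.null(between) && between %in% names(x)) {
    gmap <- unique(x[c(subject, between)])
    group <- factor(gmap[[between]][match(subj, gmap[[subject]])])
    if (nlevels(group) < 2) group <- NULL
  }
  U <- Y %*% .orth_contrasts(k)
  list(U = U, group = group, k = k)
}

#' Mauchly's test of sphericity
#'
#' Tests whether the covariance of a within-subject factor's orthonormal
#' contrast scores is spherical, using the chi-square approximation with
#' `k(k-1)/2 - 1` degrees of freedom (covariance pooled across groups when
#' a between factor is present; other within factors are averaged out).
#'
#' @param table long-format data.
#' @param factor within-subject factor column (needs at least 3 levels).
#' @param dv,between,subject column names as in [mixed_anova()]; use
#'   `between = NULL` for a single-group design.
#' @return A list of class `fpvs_sphericity`: `W`, `chi_sq`, `df`, `p`.
#' @export
mauchly <- function(table, factor, dv = "value", between = "group",
                    subject = "subject") {
  fs <- .factor_scores(table, factor, dv, between, subject)
  n_err <- nrow(fs$U) - if (is.null(fs$group)) 1L else nlevels(fs$group)
  out <- .mauchly_from_cov(.pooled_cov(fs$U, fs$group), n_err)
  class(out) <- "fpvs_sphericity"
  out
}

#' @export
print.fpvs_sphericity <- function(x, ...) {
  cat(sprintf("Mauchly's test: W = %.4f, chi-square(%d) = %.3f, p = %.4g\n",
              x$W, x$df, x$chi_sq, x$p))
  invisible(x)
}

#' Greenhouse-Geisser epsilon
#'
#' Box's epsilon estimate from the pooled covariance of a within factor's
#' orthonormal contrast scores; multiplying both ANOVA degrees of freedom
#' by it corrects for sphericity violations. Bounded in
#' `[1/(k-1), 1]`.
#'
#' @inheritParams mauchly
#' @return The epsilon estimate (scalar).
#' @export
gg_epsilon <- function(table, factor, dv = "value", between = "group",
                       subject = "subject") {
  fs <- .factor_scores(table, factor, dv, between, subject)
  max(.gg_from_cov(.pooled_cov(fs$U, fs$group)), 1 / (fs$k - 1))
}
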