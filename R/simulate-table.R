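#' Simulate an ROI summary table directly
#'
#' Draws subject-level ROI summary values straight from the amplitude
#' design, bypassing EEG synthesis: each value is the design's ground-truth
#' summed oddball amplitude for the cell's region class, plus a per-subject
#' additive offset (shared across all of that subject's cells) and
#' independent cell-level Gaussian noise. This is the generator used for
#' large Monte-Carlo calibrations (type-I rate, power), where synthesising
#' thousands of full multichannel recordings would add nothing but runtime:
#' the EEG-level and table-level routes are tied together by the
#' end-to-end recovery tests.
#'
#' The default residual SD (0.45 microvolts) reflects the subject-level
#' variability implied by published FPVS cluster means and standard errors
#' at comparable sample sizes.
#'
#' @param n_per_group named integer vector of subjects per group.
#' @param effect_design amplitude design, see [default_effect_design()].
#' @param stimulus_types,conditions design levels.
#' @param sd_subject SD of the shared per-subject offset (microvolts).
#' @param sd_resid SD of the independent cell noise (microvolts).
#' @param null if `TRUE`, every group uses the first group's design rows
#'   (no group effect; for type-I calibration).
#' @param seed integer seed.
#' @return An `fpvs_subject_table` with rows for the `left-PO`, `right-PO`
#'   and `frontocentral` ROIs.
#' @export
simulate_subject_table <- function(n_per_group = c(NT = 24, autism = 20),
                                   effect_design = default_effect_design(),
                                   stimulus_types = c("Faces", "Names"),
                                   conditions = c("Self", "CloseOther",
                                                  "Stranger"),
                                   sd_subject = 0.3, sd_resid = 0.45,
                                   null = FALSE, seed = 1L) {
  groups <- names(n_per_group)
  subj <- data.frame(
    subject = unlist(lapply(groups, function(g)
      sprintf("%s%02d", g, seq_len(n_per_group[[g]])))),
    group = rep(groups, times = n_per_group))
  rois <- data.frame(roi = c("left-PO", "right-PO", "frontocentral"),
                     laterality = c("left", "right", "n/a"),
                     region_class = c("parieto-occipital",
                                      "parieto-occipital", "frontocentral"),
                     stringsAsFactors = FALSE)
  tab <- expand.grid(roi_i = seq_len(nrow(rois)), condition = conditions,
                     stimulus_type = stimulus_types,
                     subj_i = seq_len(nrow(subj)),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tab$subject <- subj$subject[tab$subj_i]
  tab$group <- subj$group[tab$subj_i]
  tab$roi <- rois$roi[tab$roi_i]
  tab$laterality <- rois$laterality[tab$roi_i]
  rc <- rois$region_class[tab$roi_i]
  dg <- if (null) rep(groups[1], nrow(tab)) else tab$group
  key <- function(g, st, cond, r) paste(g, st, cond, r, sep = "\r")
  amp_map <- stats::setNames(effect_design$amp,
                             key(effect_design$group,
                                 effect_design$stimulus_type,
                                 effect_design$condition,
                                 effect_design$region_class))
  mu <- amp_map[key(dg, tab$stimulus_type, tab$condition, rc)]
  if (anyNA(mu)) stop("effect design does not cover all requested cells")
  with_seed(seed, {
    offset <- stats::rnorm(nrow(subj), 0, sd_subject)[tab$subj_i]
    tab$value <- pmax(0, mu + offset) + stats::rnorm(nrow(tab), 0, sd_resid)
  })
  tab <- tab[c("subject", "group", "stimulus_type", "condition", "roi",
               "laterality", "value")]
  rownames(tab) <- NULL
  class(tab) <- c("fpvs_subject_table", "data.frame")
  tab
}
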