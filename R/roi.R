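#' Collapsed-localizer electrode selection
#'
#' Automated stand-in for choosing analysis electrodes by visual
#' inspection: channel responses are grand-averaged across subjects,
#' conditions and stimulus types (so the choice cannot bias condition
#' contrasts), and within each predeclared scalp region the `k` electrodes
#' with the largest grand-average summed baseline-subtracted amplitude are
#' selected. Ties are broken alphabetically by label.
#'
#' @param channel_responses data frame with at least `channel` and
#'   `summed_bs` columns, one row per subject x condition x stimulus type
#'   x channel (extra columns ignored).
#' @param montage an [make_montage()] supplying the region map.
#' @param k electrodes per region.
#' @return A list of three `fpvs_roi` objects (left-PO, right-PO,
#'   frontocentral), like [fixed_rois()].
#' @export
collapsed_localizer <- function(channel_responses, montage = make_montage(),
                                k = 4) {
  if (!all(c("channel", "summed_bs") %in% names(channel_responses)))
    stop("`channel_responses` needs `channel` and `summed_bs` columns")
  ga <- tapply(channel_responses$summed_bs, channel_responses$channel, mean)
  out <- list()
  for (roi_name in names(.roi_region)) {
    members <- names(montage$region)[montage$region == .roi_region[roi_name]]
    members <- intersect(members, names(ga))
    if (length(members) < k)
      stop("region ", .roi_region[roi_name], " has ", length(members),
           " measured electrodes, fewer than k = ", k)
    ord <- members[order(-ga[members], members)]
    out[[roi_name]] <- structure(
      list(name = roi_name, electrodes = ord[seq_len(k)],
           laterality = switch(roi_name, `left-PO` = "left",
                               `right-PO` = "right", "n/a")),
      class = "fpvs_roi")
  }
  out
}

#' Reduce channel responses to ROI summaries
#'
#' Averages each subject's summed baseline-subtracted amplitude over the
#' electrodes of every region of interest, producing the long-format table
#' the group statistics consume. The input must be complete: a missing
#' subject x condition x stimulus type x electrode cell is an error naming
#' the gap.
#'
#' @param channel_responses data frame with columns `subject`, `group`,
#'   `stimulus_type`, `condition`, `channel`, `summed_bs`.
#' @param rois list of `fpvs_roi`, e.g. [fixed_rois()] or
#'   [collapsed_localizer()].
#' @return An object of class `fpvs_subject_table` (a data frame): one row
#'   per subject x stimulus type x condition x roi with columns `subject`,
#'   `group`, `stimulus_type`, `condition`, `roi`, `laterality`, `value`
#'   (microvolts).
#' @export
summarize_rois <- function(channel_responses, rois = fixed_rois()) {
  need <- c("subject", "group", "stimulus_type", "condition", "channel",
            "summed_bs")
  miss <- setdiff(need, names(channel_responses))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  x <- channel_responses
  cells <- unique(x[c("subject", "group", "stimulus_type", "condition")])
  out <- vector("list", 0)
  for (r in rois) {
    for (i in seq_len(nrow(cells))) {
      sel <- x$subject == cells$subject[i] &
        x$stimulus_type == cells$stimulus_type[i] &
        x$condition == cells$condition[i] & x$channel %in% r$electrodes
      got <- x$channel[sel]
      gap <- setdiff(r$electrodes, got)
      if (length(gap))
        stop("missing response for subject ", cells$subject[i], ", ",
             cells$stimulus_type[i], "/", cells$condition[i],
             ", electrode(s) ", paste(gap, collapse = ", "))
      out[[length(out) + 1L]] <- data.frame(
        subject = cells$subject[i], group = cells$group[i],
        stimulus_type = cells$stimulus_type[i],
        condition = cells$condition[i], roi = r$name,
        laterality = r$laterality,
        value = mean(x$summed_bs[sel]))
    }
  }
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  class(tab) <- c("fpvs_subject_table", "data.frame")
  tab
}

#' @export
print.fpvs_subject_table <- function(x, ...) {
  cat(sprintf("<fpvs_subject_table> %d rows: %d subject(s) x %s x %s x %s\n",
              nrow(x), length(unique(x$subject)),
              paste(unique(x$stimulus_type), collapse = "/"),
              paste(unique(x$condition), collapse = "/"),
              paste(unique(x$roi), collapse = "/")))
  NextMethod()
}
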