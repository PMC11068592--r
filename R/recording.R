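#' Continuous multichannel EEG recording
#'
#' Light container for a continuous recording: a channels x samples matrix
#' in microvolts, channel labels, sampling rate, event markers and the
#' current reference state.
#'
#' @param data numeric matrix, channels x samples, microvolts.
#' @param labels character vector of unique channel names, one per row.
#' @param fs sampling rate in Hz.
#' @param events data frame with columns `sample` (1-based sample index)
#'   and `code` (integer stimulus code); may have zero rows.
#' @param reference `"as-recorded"` or `"average"`.
#' @return An object of class `fpvs_recording`.
#' @export
new_recording <- function(data, labels, fs,
                          events = data.frame(sample = integer(),
                                              code = integer()),
                          reference = "as-recorded") {
  data <- as.matrix(data)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a positive scalar (Hz)")
  if (nrow(data) != length(labels))
    stop("`data` must have one row per label")
  if (anyDuplicated(labels)) stop("channel labels must be unique")
  reference <- match.arg(reference, c("as-recorded", "average"))
  events <- as.data.frame(events)
  if (nrow(events)) {
    if (!all(c("sample", "code") %in% names(events)))
      stop("`events` needs columns `sample` and `code`")
    if (any(events$sample < 1L | events$sample > ncol(data)))
      stop("event sample indices out of range")
  }
  structure(list(labels = as.character(labels), fs = fs, data = data,
                 events = events, reference = reference),
            class = "fpvs_recording")
}

#' @export
print.fpvs_recording <- function(x, ...) {
  cat(sprintf("<fpvs_recording> %d ch x %d samples @ %g Hz (%.1f s), %s reference, %d event(s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs,
              x$reference, nrow(x$events)))
  invisible(x)
}

#' One condition's epoch
#'
#' A segment of a recording tied to a single condition and stimulus type.
#' Before cropping `n_cycles` is `NA`; [crop_to_integer_cycles()] trims the
#' epoch to an integer number of oddball cycles and records the count.
#'
#' @param data,labels,fs,reference as in [new_recording()].
#' @param condition `"Self"`, `"CloseOther"` or `"Stranger"`.
#' @param stimulus_type `"Faces"` or `"Names"`.
#' @param n_cycles integer count of oddball cycles contained, or `NA`.
#' @return An object of class `fpvs_epoch`.
#' @export
new_epoch <- function(data, labels, fs, condition, stimulus_type,
                      reference = "as-recorded", n_cycles = NA_integer_) {
  condition <- match.arg(condition, c("Self", "CloseOther", "Stranger"))
  stimulus_type <- match.arg(stimulus_type, c("Faces", "Names"))
  rec <- new_recording(data, labels, fs, reference = reference)
  structure(list(labels = rec$labels, fs = fs, data = rec$data,
                 condition = condition, stimulus_type = stimulus_type,
                 reference = reference, n_cycles = n_cycles),
            class = c("fpvs_epoch", "fpvs_recording"))
}

#' @export
print.fpvs_epoch <- function(x, ...) {
  cat(sprintf("<fpvs_epoch> %s/%s: %d ch x %d samples @ %g Hz (%.2f s)%s\n",
              x$stimulus_type, x$condition, nrow(x$data), ncol(x$data), x$fs,
              ncol(x$data) / x$fs,
              if (is.na(x$n_cycles)) "" else
                sprintf(", %d oddball cycles", x$n_cycles)))
  invisible(x)
}

# condition/stimulus-type <-> BrainVision stimulus code table.
# Faces: S1..S3, Names: S11..S13, in condition order Self/CloseOther/Stranger.
.conditions <- c("Self", "CloseOther", "Stranger")
.stim_types <- c("Faces", "Names")

#' Stimulus marker code table
#'
#' Maps a condition and stimulus type to the integer stimulus code written
#' in BrainVision markers (`Stimulus,S<code>`), and back. Faces use codes
#' 1-3 and Names 11-13, in the order Self, CloseOther, Stranger.
#'
#' @param condition,stimulus_type design labels.
#' @return `event_code()` an integer code; `decode_event()` a list with
#'   `condition` and `stimulus_type` (or `NULL` for unknown codes).
#' @examples
#' event_code("Stranger", "Names")   # 13
#' decode_event(2)
#' @export
event_code <- function(condition, stimulus_type) {
  ci <- match(condition, .conditions)
  si <- match(stimulus_type, .stim_types)
  if (is.na(ci) || is.na(si)) stop("unknown condition or stimulus type")
  (si - 1L) * 10L + ci
}

#' @rdname event_code
#' @param code integer stimulus code.
#' @export
decode_event <- function(code) {
  si <- code %/% 10L + 1L
  ci <- code %% 10L
  if (si < 1L || si > 2L || ci < 1L || ci > 3L) return(NULL)
  list(condition = .conditions[ci], stimulus_type = .stim_types[si])
}
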