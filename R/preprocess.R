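#' Re-reference to the common average
#'
#' Subtracts the instantaneous mean across channels from every sample, the
#' standard average-reference transform. Applying it twice is a no-op; a
#' warning is issued if the recording is already average-referenced.
#'
#' @param recording an `fpvs_recording` (or `fpvs_epoch`).
#' @return The re-referenced recording with `reference = "average"`.
#' @export
rereference_average <- function(recording) {
  if (identical(recording$reference, "average")) {
    warning("recording is already average-referenced; returning unchanged")
    return(recording)
  }
  recording$data <- sweep(recording$data, 2, colMeans(recording$data))
  recording$reference <- "average"
  recording
}

#' Interpolate bad channels
#'
#' Replaces each listed channel by the inverse-distance-weighted mean of
#' its `k` nearest good neighbours on the unit sphere (chord distance on
#' the montage positions). Following common practice at most two channels
#' per recording are expected; more are interpolated with a warning.
#'
#' @param recording an `fpvs_recording`.
#' @param bad_labels channels to replace (may be empty).
#' @param montage an [make_montage()] object supplying positions.
#' @param k number of good neighbours to average.
#' @return The recording with bad channels replaced.
#' @export
interpolate_bad_channels <- function(recording, bad_labels,
                                     montage = make_montage(), k = 4) {
  if (!length(bad_labels)) return(recording)
  miss <- setdiff(bad_labels, recording$labels)
  if (length(miss)) stop("unknown label(s): ", paste(miss, collapse = ", "))
  good <- setdiff(recording$labels, bad_labels)
  if (!length(good)) stop("all channels marked bad")
  if (length(bad_labels) > 2L)
    warning("interpolating more than two channels (", length(bad_labels), ")")
  pos <- montage$positions
  for (b in bad_labels) {
    d <- sqrt(colSums((t(pos[good, , drop = FALSE]) - pos[b, ])^2))
    nb <- good[order(d)][seq_len(min(k, length(good)))]
    w <- 1 / pmax(d[match(nb, good)], 1e-9)
    w <- w / sum(w)
    recording$data[match(b, recording$labels), ] <-
      as.vector(w %*% recording$data[match(nb, recording$labels), ,
                                     drop = FALSE])
  }
  recording
}

#' Zero-phase band-pass filter
#'
#' Band-passes every channel with 4th-order Butterworth high-pass and
#' low-pass sections applied forward and backward (`filtfilt`), giving zero
#' phase distortion so spectral peak positions are untouched. The cascade
#' realisation is used because a direct transfer-function band-pass with a
#' 0.1 Hz edge at a 500 Hz rate is numerically fragile.
#'
#' @param recording an `fpvs_recording` or `fpvs_epoch`.
#' @param lo,hi band edges in Hz; `0 < lo < hi < fs/2`.
#' @param order filter order of each section.
#' @return The filtered recording.
#' @export
bandpass <- function(recording, lo = 0.1, hi = 70, order = 4) {
  fs <- recording$fs
  if (!(lo > 0 && lo < hi)) stop("need 0 < lo < hi")
  if (hi >= fs / 2) stop("`hi` must be below the Nyquist frequency ", fs / 2)
  hp <- signal::butter(order, lo / (fs / 2), type = "high")
  lp <- signal::butter(order, hi / (fs / 2), type = "low")
  for (i in seq_len(nrow(recording$data))) {
    x <- signal::filtfilt(hp, recording$data[i, ])
    recording$data[i, ] <- signal::filtfilt(lp, x)
  }
  recording
}

#' Cut one condition's epoch from a recording
#'
#' Extracts the segment starting at the stimulus marker matching the given
#' condition and stimulus type.
#'
#' @param recording an `fpvs_recording` with events.
#' @param condition,stimulus_type design cell to extract.
#' @param duration epoch length in seconds.
#' @return An `fpvs_epoch` of `round(duration * fs)` samples starting at
#'   the event sample.
#' @export
segment <- function(recording, condition, stimulus_type, duration = 84) {
  code <- event_code(condition, stimulus_type)
  ev <- recording$events[recording$events$code == code, , drop = FALSE]
  if (!nrow(ev)) stop("no event for ", condition, "/", stimulus_type,
                      " (code ", code, ")")
  start <- ev$sample[1]
  n <- round(duration * recording$fs)
  if (start + n - 1L > ncol(recording$data))
    stop("epoch exceeds recording: needs ", n, " samples from sample ",
         start, " but only ", ncol(recording$data) - start + 1L, " remain")
  new_epoch(recording$data[, start:(start + n - 1L), drop = FALSE],
            recording$labels, recording$fs, condition, stimulus_type,
            reference = recording$reference)
}

#' Crop an epoch to an integer number of oddball cycles
#'
#' Trims the epoch (anchored at its start) to
#' `floor(n_cycles / f_odd * fs)` samples so that the oddball frequency and
#' its harmonics fall on (very nearly) exact FFT bins, making rectangular
#' (window-free) spectra appropriate.
#'
#' @param epoch an `fpvs_epoch`.
#' @param f_odd oddball frequency, Hz.
#' @param n_cycles number of oddball cycles to keep.
#' @return The cropped epoch with `n_cycles` recorded.
#' @export
crop_to_integer_cycles <- function(epoch, f_odd = 5.77 / 5, n_cycles = 96) {
  n <- floor(n_cycles / f_odd * epoch$fs)
  if (n > ncol(epoch$data))
    stop("epoch too short: ", ncol(epoch$data), " samples < ", n)
  epoch$data <- epoch$data[, seq_len(n), drop = FALSE]
  epoch$n_cycles <- as.integer(n_cycles)
  epoch
}
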