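#' Single-sided amplitude spectrum
#'
#' FFT of every channel with amplitudes normalized by N/2, so a cosine of
#' peak amplitude A at an exact bin frequency yields a bin value of A
#' microvolts. No taper is applied: after integer-cycle cropping the
#' stimulation frequencies are (essentially) bin-centred and the
#' rectangular window is exact. Note the DC bin, normalized by the same
#' N/2, reads twice the mean.
#'
#' @param epoch an `fpvs_epoch` (any `fpvs_recording` works).
#' @return An object of class `fpvs_spectrum`: list with `freqs` (Hz, from
#'   0 in steps of `1/duration`), `amps` (channels x bins, microvolts,
#'   non-negative), `delta_f`, `labels`, and the epoch's `condition` /
#'   `stimulus_type` when present.
#' @export
amplitude_spectrum <- function(epoch) {
  n <- ncol(epoch$data)
  if (is.null(n) || n == 0) stop("empty epoch")
  nb <- floor(n / 2) + 1L
  amps <- t(apply(epoch$data, 1, function(x) abs(stats::fft(x))[seq_len(nb)])) /
    (n / 2)
  if (nrow(epoch$data) == 1L) amps <- matrix(amps, nrow = 1L)
  structure(list(freqs = (seq_len(nb) - 1) * epoch$fs / n,
                 amps = amps, delta_f = epoch$fs / n,
                 labels = epoch$labels,
                 condition = epoch$condition,
                 stimulus_type = epoch$stimulus_type),
            class = "fpvs_spectrum")
}

#' @export
print.fpvs_spectrum <- function(x, ...) {
  cat(sprintf("<fpvs_spectrum> %d ch x %d bins, delta_f = %.6g Hz (0-%.4g Hz)\n",
              nrow(x$amps), length(x$freqs), x$delta_f, max(x$freqs)))
  invisible(x)
}

#' Oddball harmonic frequencies
#'
#' Multiples of the oddball frequency up to `max_multiple`, excluding every
#' multiple that coincides with a harmonic of the base frequency (for a
#' 5:1 design these are the 5th, 10th, ... multiples), since those bins
#' reflect the base response.
#'
#' @param f_odd oddball frequency, Hz.
#' @param max_multiple highest multiple considered.
#' @param f_base base frequency, Hz; must be `5 * f_odd`.
#' @return Numeric vector of target frequencies in Hz.
#' @examples
#' harmonic_frequencies()  # 1.154, 2.308, ..., 9.232 Hz without 5.77
#' @export
harmonic_frequencies <- function(f_odd = 5.77 / 5, max_multiple = 8,
                                 f_base = 5.77) {
  if (abs(f_base - 5 * f_odd) > 1e-9) stop("`f_base` must equal 5 * `f_odd`")
  if (max_multiple < 1) stop("`max_multiple` must be at least 1")
  .oddball_multiples(max_multiple) * f_odd
}

#' Noise window definition
#'
#' The neighbouring-bin window used for baseline subtraction and z-scores:
#' `n_side` bins on each side of the bin of interest, of which the
#' `n_exclude` immediately adjacent bins are excluded (to avoid signal
#' spread), leaving `2 * (n_side - n_exclude)` noise bins. The defaults
#' (10 and 1) reproduce the +/-0.12 Hz window with 18 noise bins at the
#' 0.012 Hz resolution of an 83.2 s epoch.
#'
#' @param n_side half-window width in bins.
#' @param n_exclude adjacent bins excluded per side.
#' @return A list of class `fpvs_noise_window`.
#' @export
noise_window <- function(n_side = 10, n_exclude = 1) {
  if (!(n_side > n_exclude && n_exclude >= 0))
    stop("need n_side > n_exclude >= 0")
  structure(list(n_side = as.integer(n_side),
                 n_exclude = as.integer(n_exclude)),
            class = "fpvs_noise_window")
}

# offsets of the noise bins relative to the bin of interest, shrunk
# symmetrically (with a warning) near the spectrum edge
.noise_offsets <- function(bin, nbins, window) {
  side <- (window$n_exclude + 1L):window$n_side
  max_off <- max(side)
  room <- min(bin - 1L, nbins - bin)
  if (room < max_off) {
    if (room <= window$n_exclude)
      stop("no noise bins available at bin ", bin)
    warning("noise window shrunk to +/-", room, " bins at spectrum edge")
    side <- (window$n_exclude + 1L):room
  }
  c(-side, side)
}

.noise_amps <- function(spectrum, channel, bin, window) {
  i <- if (is.character(channel)) match(channel, spectrum$labels) else channel
  if (is.na(i) || i < 1 || i > nrow(spectrum$amps))
    stop("unknown channel: ", channel)
  off <- .noise_offsets(bin, length(spectrum$freqs), window)
  list(target = spectrum$amps[i, bin], noise = spectrum$amps[i, bin + off])
}

#' Baseline-subtracted amplitude at a bin
#'
#' Amplitude at the bin of interest minus the mean amplitude of the
#' surrounding noise bins (see [noise_window()]). The result may be
#' negative; no clipping is applied. Because the window is symmetric, any
#' constant offset or linear trend across it cancels exactly.
#'
#' @param spectrum an `fpvs_spectrum`.
#' @param channel channel label or row index.
#' @param bin 1-based bin index.
#' @param window an [noise_window()].
#' @return Baseline-subtracted amplitude in microvolts.
#' @export
baseline_subtracted_amplitude <- function(spectrum, channel, bin,
                                          window = noise_window()) {
  a <- .noise_amps(spectrum, channel, bin, window)
  a$target - mean(a$noise)
}

#' Z-score of a bin against its noise window
#'
#' `(amplitude - noise mean) / noise SD` over the same noise bins as
#' [baseline_subtracted_amplitude()], with the sample (n-1) SD. When the
#' noise SD is zero the convention is `Inf` for a positive numerator,
#' `-Inf` for a negative one and `0` when the bin equals the noise mean.
#'
#' @inheritParams baseline_subtracted_amplitude
#' @return The z-score.
#' @export
zscore_amplitude <- function(spectrum, channel, bin,
                             window = noise_window()) {
  a <- .noise_amps(spectrum, channel, bin, window)
  num <- a$target - mean(a$noise)
  s <- stats::sd(a$noise)
  if (s == 0) {
    if (num > 0) return(Inf)
    if (num < 0) return(-Inf)
    return(0)
  }
  num / s
}

#' Nearest frequency bin
#'
#' Index of the spectrum bin closest to a target frequency, with exact
#' midpoint ties broken towards the lower bin.
#'
#' @param spectrum an `fpvs_spectrum`.
#' @param target frequency in Hz, within the spectrum's range.
#' @return 1-based bin index.
#' @export
nearest_bin <- function(spectrum, target) {
  if (target < 0 || target > max(spectrum$freqs))
    stop("target frequency ", target, " Hz outside the spectrum")
  as.integer(ceiling(target / spectrum$delta_f - 0.5)) + 1L
}

#' Select significant oddball harmonics
#'
#' Decides how many oddball harmonics to quantify, from the z-scores of a
#' grand-average spectrum (mean amplitude over channels, subjects and
#' conditions): the maximal consecutive run of oddball multiples, starting
#' at the fundamental, whose z exceeds `z_threshold`. Multiples coinciding
#' with base-frequency harmonics are skipped without breaking the run, and
#' the fundamental is always retained.
#'
#' @param grand_avg_spectrum an `fpvs_spectrum` with a single (averaged)
#'   channel row, or several rows which are averaged here.
#' @param f_odd,f_base stimulation frequencies, Hz.
#' @param z_threshold significance threshold (2.32 corresponds to p < .01
#'   one-sided under a standard-normal reference).
#' @param window an [noise_window()].
#' @param max_multiple highest multiple examined.
#' @return Numeric vector of retained target frequencies in Hz.
#' @export
select_harmonics <- function(grand_avg_spectrum, f_odd = 5.77 / 5,
                             f_base = 5.77, z_threshold = 2.32,
                             window = noise_window(), max_multiple = 16) {
  sp <- grand_avg_spectrum
  if (nrow(sp$amps) > 1L) {
    sp$amps <- matrix(colMeans(sp$amps), nrow = 1L)
    sp$labels <- "grand-average"
  }
  kept <- numeric(0)
  for (k in seq_len(max_multiple)) {
    f <- k * f_odd
    if (f > max(sp$freqs) - window$n_side * sp$delta_f) break
    if (.is_base_multiple(k)) next
    z <- zscore_amplitude(sp, 1L, nearest_bin(sp, f), window)
    if (k == 1L) { kept <- f; if (z <= z_threshold) break else next }
    if (z > z_threshold) kept <- c(kept, f) else break
  }
  kept
}

.is_base_multiple <- function(k) k %% 5L == 0L

#' Oddball response of one channel
#'
#' Baseline-subtracted amplitudes at the oddball target frequencies
#' (nearest bins) and their sum — the dependent measure of the analysis —
#' together with the per-frequency z-scores.
#'
#' @param spectrum an `fpvs_spectrum`.
#' @param channel channel label or index.
#' @param target_freqs target frequencies in Hz, typically from
#'   [harmonic_frequencies()] restricted by [select_harmonics()].
#' @param window an [noise_window()].
#' @return An object of class `fpvs_oddball_response`: list with `channel`,
#'   `target_freqs`, `per_freq_bs`, `summed_bs` and `z_per_freq`.
#' @export
oddball_response <- function(spectrum, channel, target_freqs,
                             window = noise_window()) {
  bins <- vapply(target_freqs, nearest_bin, integer(1), spectrum = spectrum)
  bs <- vapply(bins, function(b)
    baseline_subtracted_amplitude(spectrum, channel, b, window), numeric(1))
  z <- vapply(bins, function(b)
    zscore_amplitude(spectrum, channel, b, window), numeric(1))
  structure(list(channel = channel, target_freqs = target_freqs,
                 per_freq_bs = bs, summed_bs = sum(bs), z_per_freq = z),
            class = "fpvs_oddball_response")
}

#' @export
print.fpvs_oddball_response <- function(x, ...) {
  cat(sprintf("<fpvs_oddball_response> channel %s: summed bs = %.4g uV over %d target(s)\n",
              as.character(x$channel), x$summed_bs, length(x$target_freqs)))
  invisible(x)
}

#' Base-rate response of one channel
#'
#' Same quantification as [oddball_response()] but at the base stimulation
#' frequency and its harmonics (up to `max_freq`); indexes general visual
#' entrainment. Base targets never overlap the oddball targets, which
#' exclude base multiples by construction.
#'
#' @param spectrum an `fpvs_spectrum`.
#' @param channel channel label or index.
#' @param f_base base frequency, Hz.
#' @param window an [noise_window()].
#' @param max_freq highest harmonic frequency considered, Hz.
#' @return An `fpvs_oddball_response` whose targets are base multiples.
#' @export
base_response <- function(spectrum, channel, f_base = 5.77,
                          window = noise_window(), max_freq = 70) {
  targets <- f_base * seq_len(floor(max_freq / f_base))
  targets <- targets[targets <= max(spectrum$freqs) -
                       window$n_side * spectrum$delta_f]
  oddball_response(spectrum, channel, targets, window)
}
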