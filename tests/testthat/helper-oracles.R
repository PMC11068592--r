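# Shared oracles and small builders used across the test files.

# Direct DFT single-sided amplitude oracle (O(n^2), for small toys only).
dft_amplitude_oracle <- function(x, fs) {
  n <- length(x)
  nb <- floor(n / 2) + 1L
  k <- seq_len(nb) - 1L
  t <- seq_len(n) - 1L
  amps <- vapply(k, function(kk)
    Mod(sum(x * exp(-2i * pi * kk * t / n))), numeric(1)) / (n / 2)
  list(freqs = k * fs / n, amps = amps)
}

# The 14-channel subset (both parieto-occipital clusters, the full
# frontocentral cluster, and Fp1/Fp2 for the ICA step) used for fast
# EEG-level tests.
test_channels <- function() {
  c("Fp1", "Fp2", "Fz", "FC1", "FC2", "Cz", "P7", "PO7", "O1", "TP9",
    "P8", "PO8", "O2", "TP10")
}

# A pure-signal config: no noise, no line interference, no blinks.
# Named arguments in ... override the clean defaults.
clean_config <- function(...) {
  args <- list(noise_scale = 0, line_amp = 0, blink_rate = 0,
               channels = test_channels())
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

# Collapse a long table over within factors not in `keep` (mean per cell).
collapse_within <- function(tab, keep) {
  by <- c(list(subject = tab$subject, group = tab$group),
          stats::setNames(lapply(keep, function(k) tab[[k]]), keep))
  agg <- stats::aggregate(tab$value, by = by, FUN = mean)
  names(agg)[names(agg) == "x"] <- "value"
  agg
}

# Build an fpvs_spectrum by hand from an amplitude matrix.
manual_spectrum <- function(amps, delta_f, labels = NULL) {
  amps <- rbind(amps)
  dimnames(amps) <- NULL
  if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(amps)))
  structure(list(freqs = (seq_len(ncol(amps)) - 1) * delta_f,
                 amps = amps, delta_f = delta_f, labels = labels,
                 condition = NULL, stimulus_type = NULL),
            class = "fpvs_spectrum")
}

# Build an epoch holding exact-bin cosines: amplitude amp[i] at freq[i] Hz.
# Duration floor(96 / 1.154 * fs) samples unless n given.
cosine_epoch <- function(freqs, amps, fs = 500,
                         n = floor(96 / 1.154 * fs),
                         labels = "PO8", condition = "Self",
                         stimulus_type = "Faces") {
  t <- (seq_len(n) - 1) / fs
  x <- rep(0, n)
  for (i in seq_along(freqs)) x <- x + amps[i] * cos(2 * pi * freqs[i] * t)
  new_epoch(matrix(x, 1, n), labels, fs, condition, stimulus_type)
}

# Orthonormal Helmert contrast matrix, rebuilt independently of the package
# internals, for the ANOVA/sphericity formula oracles.
helmert_orth <- function(k) {
  C <- stats::contr.helmert(k)
  C %*% diag(1 / sqrt(colSums(C^2)), ncol(C))
}

# Long-format random mixed-design table: 2-level stimulus_type x 3-level
# condition within, 2 groups between.
random_mixed_table <- function(n1 = 6, n2 = 5, seed = 42) {
  set.seed(seed)
  subj <- c(sprintf("a%02d", seq_len(n1)), sprintf("b%02d", seq_len(n2)))
  grp <- rep(c("g1", "g2"), c(n1, n2))
  tab <- expand.grid(subject = subj, stimulus_type = c("Faces", "Names"),
                     condition = c("Self", "CloseOther", "Stranger"),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tab$group <- grp[match(tab$subject, subj)]
  tab$value <- rnorm(nrow(tab))
  tab
}
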