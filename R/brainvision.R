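#' Read a BrainVision recording
#'
#' Parses a BrainVision `.vhdr` header together with its companion binary
#' `.eeg` data file and `.vmrk` marker file. Multiplexed `IEEE_FLOAT_32`
#' and `INT_16` (with per-channel resolution) binary formats are supported;
#' amplitudes are returned in microvolts (channel units of uV/µV, mV and V
#' are converted).
#'
#' @param header_path path to the `.vhdr` file.
#' @return An `fpvs_recording`; `Stimulus` markers become events with their
#'   `S<code>` description parsed into integer codes.
#' @seealso [write_brainvision()]
#' @export
read_brainvision <- function(header_path) {
  if (!file.exists(header_path)) stop("missing header file: ", header_path)
  hdr <- .parse_bv_ini(readLines(header_path, warn = FALSE))
  ci <- hdr[["Common Infos"]]
  if (is.null(ci)) stop("not a BrainVision header: no [Common Infos]")
  dir <- dirname(header_path)
  data_path <- file.path(dir, ci[["DataFile"]])
  marker_path <- if (!is.null(ci[["MarkerFile"]]))
    file.path(dir, ci[["MarkerFile"]]) else NULL
  if (!file.exists(data_path)) stop("missing data file: ", data_path)
  if (!identical(toupper(ci[["DataFormat"]]), "BINARY"))
    stop("unsupported DataFormat: ", ci[["DataFormat"]])
  orient <- ci[["DataOrientation"]]
  if (!is.null(orient) && toupper(orient) != "MULTIPLEXED")
    stop("unsupported DataOrientation: ", orient)
  nch <- as.integer(ci[["NumberOfChannels"]])
  fs <- 1e6 / as.numeric(ci[["SamplingInterval"]])

  chan <- hdr[["Channel Infos"]]
  if (is.null(chan) || length(chan) != nch)
    stop("header channel table does not match NumberOfChannels")
  parts <- lapply(chan[order(as.integer(sub("^Ch", "", names(chan))))],
                  function(x) strsplit(x, ",", fixed = TRUE)[[1]])
  labels <- vapply(parts, `[`, character(1), 1)
  resolution <- vapply(parts, function(p) {
    r <- if (length(p) >= 3) p[3] else ""
    if (is.na(r) || r == "") 1 else as.numeric(r)
  }, numeric(1))
  unit_scale <- vapply(parts, function(p) {
    u <- if (length(p) >= 4) p[4] else "µV"
    switch(u, "µV" = 1, "uV" = 1, "mV" = 1e3, "V" = 1e6,
           stop("unit not convertible to microvolts: ", u))
  }, numeric(1))

  fmt <- toupper(hdr[["Binary Infos"]][["BinaryFormat"]])
  sz <- file.info(data_path)$size
  con <- file(data_path, "rb")
  on.exit(close(con))
  if (identical(fmt, "IEEE_FLOAT_32")) {
    raw_vals <- readBin(con, "numeric", n = sz / 4, size = 4,
                        endian = "little")
  } else if (identical(fmt, "INT_16")) {
    raw_vals <- readBin(con, "integer", n = sz / 2, size = 2, signed = TRUE,
                        endian = "little")
  } else stop("unsupported BinaryFormat: ", fmt)
  nsamp <- length(raw_vals) %/% nch
  data <- matrix(raw_vals[seq_len(nch * nsamp)], nrow = nch)
  data <- data * resolution * unit_scale

  events <- data.frame(sample = integer(), code = integer())
  if (!is.null(marker_path) && file.exists(marker_path)) {
    mk <- .parse_bv_ini(readLines(marker_path, warn = FALSE))[["Marker Infos"]]
    if (!is.null(mk)) {
      rows <- lapply(mk, function(x) strsplit(x, ",", fixed = TRUE)[[1]])
      stim <- Filter(function(p) identical(p[1], "Stimulus"), rows)
      if (length(stim)) {
        events <- data.frame(
          sample = vapply(stim, function(p) as.integer(p[3]), integer(1)),
          code = vapply(stim, function(p)
            as.integer(sub("^S\\s*", "", p[2])), integer(1)))
        events <- events[order(events$sample), , drop = FALSE]
        rownames(events) <- NULL
      }
    }
  }
  new_recording(data, labels, fs, events = events)
}

#' Write a BrainVision recording
#'
#' Writes an `fpvs_recording` as a BrainVision triplet: `.vhdr` header,
#' little-endian multiplexed `IEEE_FLOAT_32` `.eeg` data (microvolts) and
#' `.vmrk` markers (a `New Segment` marker plus one `Stimulus,S<code>`
#' marker per event).
#'
#' @param recording an `fpvs_recording`.
#' @param path output path; the `.vhdr`/`.vmrk`/`.eeg` extensions are
#'   derived from it.
#' @return Invisibly, the header path.
#' @export
write_brainvision <- function(recording, path) {
  if (!inherits(recording, "fpvs_recording")) stop("not an fpvs_recording")
  if (length(recording$data) == 0) stop("recording has no samples")
  base <- sub("\\.vhdr$", "", path)
  stem <- basename(base)
  hdr_path <- paste0(base, ".vhdr")
  eeg_path <- paste0(base, ".eeg")
  vmrk_path <- paste0(base, ".vmrk")

  con <- file(eeg_path, "wb")
  writeBin(as.vector(recording$data), con, size = 4, endian = "little")
  close(con)

  hdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "; Written by the fpvs package",
    "",
    "[Common Infos]",
    "Codepage=UTF-8",
    paste0("DataFile=", stem, ".eeg"),
    paste0("MarkerFile=", stem, ".vmrk"),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", nrow(recording$data)),
    sprintf("SamplingInterval=%.10g", 1e6 / recording$fs),
    "",
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,,µV", seq_along(recording$labels),
            recording$labels))
  writeLines(hdr, hdr_path, useBytes = FALSE)

  mk <- c(
    "Brain Vision Data Exchange Marker File, Version 1.0",
    "",
    "[Common Infos]",
    "Codepage=UTF-8",
    paste0("DataFile=", stem, ".eeg"),
    "",
    "[Marker Infos]",
    "Mk1=New Segment,,1,1,0,00000000000000000000")
  if (nrow(recording$events)) {
    ev <- recording$events[order(recording$events$sample), , drop = FALSE]
    mk <- c(mk, sprintf("Mk%d=Stimulus,S%3d,%d,1,0",
                        seq_len(nrow(ev)) + 1L, ev$code, ev$sample))
  }
  writeLines(mk, vmrk_path)
  invisible(hdr_path)
}

# minimal INI parser for BrainVision header/marker files: returns a list of
# sections, each a named list of key=value strings (comments dropped)
.parse_bv_ini <- function(lines) {
  out <- list()
  section <- NULL
  for (ln in lines) {
    ln <- sub("﻿", "", ln)
    if (grepl("^\\s*(;|$)", ln)) next
    m <- regmatches(ln, regexec("^\\[(.+)\\]\\s*$", ln))[[1]]
    if (length(m)) { section <- m[2]; out[[section]] <- list(); next }
    if (is.null(section)) next
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq > 0)
      out[[section]][[substr(ln, 1, eq - 1)]] <-
        sub("\\s+$", "", substr(ln, eq + 1, nchar(ln)))
  }
  out
}
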