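#' Pipeline configuration
#'
#' Bundles every stage's parameters into one object: the simulation config,
#' preprocessing band edges and ICA threshold, the noise window, harmonic
#' search depth and z threshold, and the ROI mode. A single seed governs
#' all randomness.
#'
#' @param sim an [sim_config()]; its seed is overridden by `seed`.
#' @param band_lo,band_hi band-pass edges, Hz.
#' @param ica_threshold absolute EOG correlation above which an independent
#'   component is removed.
#' @param window an [noise_window()].
#' @param max_harmonic highest oddball multiple considered.
#' @param z_threshold harmonic retention threshold (z > 2.32 is p < .01).
#' @param roi_mode `"fixed"` (predeclared clusters, the default used for
#'   statistics) or `"localizer"` (data-driven top-4 per region).
#' @param interpolate named list mapping subject ids to channels to
#'   interpolate (normally empty; used to exercise bad-channel handling).
#' @param write_raw also write each simulated recording as a BrainVision
#'   triplet.
#' @param seed master seed.
#' @return A list of class `fpvs_pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), band_lo = 0.1,
                            band_hi = 70, ica_threshold = 0.8,
                            window = noise_window(), max_harmonic = 8,
                            z_threshold = 2.32,
                            roi_mode = c("fixed", "localizer"),
                            interpolate = list(), write_raw = FALSE,
                            seed = 1L) {
  roi_mode <- match.arg(roi_mode)
  sim$seed <- as.integer(seed)
  structure(list(sim = sim, band_lo = band_lo, band_hi = band_hi,
                 ica_threshold = ica_threshold, window = window,
                 max_harmonic = max_harmonic, z_threshold = z_threshold,
                 roi_mode = roi_mode, interpolate = interpolate,
                 write_raw = write_raw, seed = as.integer(seed)),
            class = "fpvs_pipeline_config")
}

#' Preprocess one recording into a cropped epoch
#'
#' The standard chain: average re-reference, optional bad-channel
#' interpolation, zero-phase band-pass, segmentation at the condition's
#' train-onset marker, ICA ocular correction, and integer-cycle cropping.
#'
#' @param recording an `fpvs_recording` with a marker for the requested
#'   cell.
#' @param condition,stimulus_type design cell to extract.
#' @param config an [pipeline_config()].
#' @param bad_labels channels to interpolate before filtering.
#' @return A list with `epoch` (cropped, corrected `fpvs_epoch`) and `log`
#'   (one-row data frame: channels interpolated, ICA components removed).
#' @export
preprocess_recording <- function(recording, condition, stimulus_type,
                                 config = pipeline_config(),
                                 bad_labels = character()) {
  rec <- rereference_average(recording)
  if (length(bad_labels))
    rec <- interpolate_bad_channels(rec, bad_labels)
  rec <- bandpass(rec, config$band_lo, config$band_hi)
  ep <- segment(rec, condition, stimulus_type, duration = config$sim$epoch_s)
  oc <- ocular_correct(ep, threshold = config$ica_threshold,
                       seed = config$seed)
  ep <- crop_to_integer_cycles(oc$epoch, f_odd = config$sim$f_odd,
                               n_cycles = config$sim$n_cycles)
  list(epoch = ep,
       log = data.frame(condition = condition,
                        stimulus_type = stimulus_type,
                        n_interpolated = length(bad_labels),
                        n_components_removed = oc$n_removed))
}

# per-channel response table for one spectrum at the candidate oddball
# multiples: raw amplitude, noise mean, baseline-subtracted amplitude, z
.channel_response_table <- function(spectrum, f_odd, max_harmonic, window) {
  mult <- .oddball_multiples(max_harmonic)
  freqs <- mult * f_odd
  bins <- vapply(freqs, nearest_bin, integer(1), spectrum = spectrum)
  out <- vector("list", length(spectrum$labels))
  for (i in seq_along(spectrum$labels)) {
    raw <- spectrum$amps[i, bins]
    nm <- vapply(bins, function(b) {
      a <- .noise_amps(spectrum, i, b, window)
      mean(a$noise)
    }, numeric(1))
    z <- vapply(bins, function(b)
      zscore_amplitude(spectrum, i, b, window), numeric(1))
    out[[i]] <- data.frame(channel = spectrum$labels[i], multiple = mult,
                           frequency = freqs, raw_amp = raw,
                           noise_mean = nm, bs_amp = raw - nm, z = z)
  }
  do.call(rbind, out)
}

#' Run the whole pipeline
#'
#' Simulate -> preprocess -> spectra -> harmonic selection -> ROI summary
#' -> group statistics, writing every product into `out_dir`: the
#' ground-truth amplitude table, a preprocessing log, the grand-average
#' spectrum, per-cell channel responses, the topography export, the ROI
#' summary table, the ANOVA/t-test report (CSV and text) and a manifest
#' (config hash, seed, package/R versions). Re-running with the same
#' config reproduces all numeric outputs exactly.
#'
#' @param config an [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with the in-memory products: `grand_avg`
#'   spectrum, `responses` (channel-level table), `retained_freqs`,
#'   `rois`, `table` (ROI summary) and `report` (contrast report).
#' @export
run_all <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("[stage: ", name, "] ", conditionMessage(e), call. = FALSE))
  }
  cfg <- config$sim
  acc <- new.env()
  acc$sum_amps <- NULL
  acc$n_spec <- 0L
  acc$resp <- list()
  acc$log <- list()

  study <- stage("simulate+preprocess+spectrum", simulate_study(
    cfg, callback = function(sim, subject, group) {
      rec <- sim$recording
      cond <- sim$ground_truth$condition[1]
      st <- sim$ground_truth$stimulus_type[1]
      if (config$write_raw)
        write_brainvision(rec, file.path(out_dir, sprintf(
          "%s_%s_%s", subject, st, cond)))
      bad <- config$interpolate[[subject]]
      if (is.null(bad)) bad <- character()
      pp <- preprocess_recording(rec, cond, st, config, bad_labels = bad)
      sp <- amplitude_spectrum(pp$epoch)
      if (is.null(acc$sum_amps)) acc$sum_amps <- sp$amps * 0
      acc$sum_amps <- acc$sum_amps + sp$amps
      acc$n_spec <- acc$n_spec + 1L
      acc$last_spec <- sp
      rt <- .channel_response_table(sp, cfg$f_odd, config$max_harmonic,
                                    config$window)
      rt <- cbind(data.frame(subject = subject, group = group,
                             stimulus_type = st, condition = cond), rt)
      acc$resp[[length(acc$resp) + 1L]] <- rt
      acc$log[[length(acc$log) + 1L]] <-
        cbind(data.frame(subject = subject), pp$log)
    }))

  responses <- do.call(rbind, acc$resp)
  prep_log <- do.call(rbind, acc$log)
  grand_avg <- acc$last_spec
  grand_avg$amps <- acc$sum_amps / acc$n_spec
  grand_avg$condition <- NULL
  grand_avg$stimulus_type <- NULL

  retained <- stage("harmonic selection", select_harmonics(
    grand_avg, f_odd = cfg$f_odd, f_base = cfg$f_base,
    z_threshold = config$z_threshold, window = config$window,
    max_multiple = config$max_harmonic))

  resp_kept <- responses[responses$frequency %in% retained, , drop = FALSE]
  chan_sum <- stage("summed responses", {
    agg <- stats::aggregate(
      resp_kept$bs_amp,
      by = list(subject = resp_kept$subject, group = resp_kept$group,
                stimulus_type = resp_kept$stimulus_type,
                condition = resp_kept$condition,
                channel = resp_kept$channel), FUN = sum)
    names(agg)[names(agg) == "x"] <- "summed_bs"
    agg
  })

  montage <- make_montage()
  rois <- stage("roi selection", if (config$roi_mode == "localizer")
    collapsed_localizer(chan_sum, montage) else fixed_rois())
  table <- stage("roi summary", summarize_rois(chan_sum, rois))
  report <- stage("statistics", run_paper_contrasts(table))

  stage("outputs", {
    utils::write.csv(study$ground_truth,
                     file.path(out_dir, "ground_truth.csv"),
                     row.names = FALSE)
    utils::write.csv(prep_log, file.path(out_dir, "preprocessing_log.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(frequency = grand_avg$freqs,
                                amplitude = colMeans(grand_avg$amps)),
                     file.path(out_dir, "grand_average_spectrum.csv"),
                     row.names = FALSE)
    utils::write.csv(responses, file.path(out_dir, "channel_responses.csv"),
                     row.names = FALSE)
    ga_by_chan <- tapply(chan_sum$summed_bs, chan_sum$channel, mean)
    topo <- data.frame(electrode = names(ga_by_chan),
                       montage$positions[names(ga_by_chan), , drop = FALSE],
                       grand_avg_bs = as.vector(ga_by_chan))
    names(topo)[2:4] <- c("x", "y", "z")
    utils::write.csv(topo, file.path(out_dir, "topography.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(table),
                     file.path(out_dir, "roi_table.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(report$po_anova),
                     file.path(out_dir, "anova_parieto_occipital.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(report$fc_anova),
                     file.path(out_dir, "anova_frontocentral.csv"),
                     row.names = FALSE)
    writeLines(utils::capture.output(print(report)),
               file.path(out_dir, "stats_report.txt"))
    cfg_file <- file.path(out_dir, "config.yaml")
    yaml::write_yaml(.config_to_list(config), cfg_file)
    manifest <- list(
      seed = config$seed,
      config_md5 = unname(tools::md5sum(cfg_file)),
      retained_frequencies = retained,
      n_recordings = acc$n_spec,
      r_version = R.version.string,
      package_version = as.character(utils::packageVersion("fpvs")))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })

  invisible(list(grand_avg = grand_avg, responses = responses,
                 retained_freqs = retained, rois = rois, table = table,
                 report = report))
}

# plain-list view of a pipeline config for YAML round-tripping
.config_to_list <- function(config) {
  sim <- unclass(config$sim)
  sim$effect_design <- as.list(as.data.frame(sim$effect_design))
  sim$base_amp <- as.list(sim$base_amp)
  sim$n_per_group <- as.list(sim$n_per_group)
  list(sim = sim,
       band_lo = config$band_lo, band_hi = config$band_hi,
       ica_threshold = config$ica_threshold,
       window = unclass(config$window),
       max_harmonic = config$max_harmonic,
       z_threshold = config$z_threshold,
       roi_mode = config$roi_mode,
       write_raw = config$write_raw,
       seed = config$seed)
}

#' Read a pipeline configuration from YAML
#'
#' Rebuilds a [pipeline_config()] from a YAML file written by the pipeline
#' (or authored by hand); missing fields take the package defaults.
#'
#' @param path YAML file path.
#' @return An `fpvs_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$sim
  if (!is.null(sim_args$effect_design))
    sim_args$effect_design <- as.data.frame(sim_args$effect_design)
  if (!is.null(sim_args$base_amp))
    sim_args$base_amp <- unlist(sim_args$base_amp)
  if (!is.null(sim_args$n_per_group))
    sim_args$n_per_group <- unlist(sim_args$n_per_group)
  sim_args$channels <- unlist(sim_args$channels)
  sim <- do.call(sim_config, sim_args[!vapply(sim_args, is.null,
                                              logical(1))])
  args <- y[setdiff(names(y), c("sim", "window"))]
  args$sim <- sim
  if (!is.null(y$window)) args$window <- do.call(noise_window, y$window)
  do.call(pipeline_config, args)
}

#' Write tiny BrainVision test fixtures
#'
#' Creates two small (8-channel, 10 s, 500 Hz) BrainVision recordings for
#' I/O and unit testing: `tone` carries a pure 2 microvolt cosine at
#' 1.154 Hz on PO8 only (single Self/Faces marker at sample 1), and
#' `markers` carries low-amplitude noise with the three Faces condition
#' markers at 1 s, 3 s and 5 s.
#'
#' @param out_dir directory for the fixture files (created if needed).
#' @return Invisibly, a list describing the fixtures (paths and declared
#'   ground truth).
#' @export
make_fixtures <- function(out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  labels <- c("Fp1", "Fp2", "Fz", "Cz", "PO7", "PO8", "O1", "O2")
  fs <- 500; n <- 10 * fs
  t <- (seq_len(n) - 1) / fs

  tone <- matrix(0, length(labels), n)
  tone[labels == "PO8", ] <- 2 * cos(2 * pi * 1.154 * t)
  rec1 <- new_recording(tone, labels, fs,
                        events = data.frame(sample = 1L,
                                            code = event_code("Self",
                                                              "Faces")))
  p1 <- write_brainvision(rec1, file.path(out_dir, "tone"))

  noise <- with_seed(99L, matrix(stats::rnorm(length(labels) * n, 0, 0.5),
                                 length(labels), n))
  ev <- data.frame(sample = c(1L, 3L, 5L) * fs + 1L,
                   code = vapply(c("Self", "CloseOther", "Stranger"),
                                 event_code, integer(1),
                                 stimulus_type = "Faces"))
  rec2 <- new_recording(noise, labels, fs, events = ev)
  p2 <- write_brainvision(rec2, file.path(out_dir, "markers"))

  invisible(list(
    tone = list(path = p1, channel = "PO8", freq = 1.154, amplitude = 2),
    markers = list(path = p2, events = ev)))
}
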