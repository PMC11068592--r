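# Run code with a private, seeded RNG stream; the caller's RNG is untouched.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  code
}

# deterministic per-recording seed derived from the config seed
.derive_seed <- function(seed, ...) {
  parts <- unlist(lapply(list(...), function(x)
    if (is.character(x)) sum(utf8ToInt(x)) else as.integer(x)))
  s <- as.double(seed %% 2147483647)
  for (p in parts) s <- (s * 131 + as.double(p) + 7) %% 2147483629
  as.integer(s)
}

#' Default condition-by-group amplitude design
#'
#' The ground-truth summed oddball amplitudes (microvolts, totalled over the
#' retained target harmonics) injected by the simulator, per group,
#' stimulus type, condition and scalp region class. The neurotypical (NT)
#' face design is graded (Self > CloseOther > Stranger) while the autism
#' face design carries an equal Self and CloseOther response
#' (Self = CloseOther > Stranger); name amplitudes are identical across
#' groups. Values approximate the microvolt scale of published FPVS oddball
#' responses and are sized for statistical power at realistic sample sizes.
#'
#' @return data frame with columns `group`, `stimulus_type`, `condition`,
#'   `region_class` (`"parieto-occipital"`, `"frontocentral"`, `"other"`)
#'   and `amp` (microvolts).
#' @export
default_effect_design <- function() {
  g <- function(group, stim, amps_po, amps_fc, amps_other)
    data.frame(group = group, stimulus_type = stim,
               condition = rep(c("Self", "CloseOther", "Stranger"), 3),
               region_class = rep(c("parieto-occipital", "frontocentral",
                                    "other"), each = 3),
               amp = c(amps_po, amps_fc, amps_other))
  rbind(
    g("NT",     "Faces", c(1.50, 0.90, 0.35), c(0.70, 0.53, 0.20), rep(0.10, 3)),
    g("autism", "Faces", c(0.90, 0.90, 0.35), c(0.70, 0.53, 0.20), rep(0.10, 3)),
    g("NT",     "Names", c(0.46, 0.38, 0.22), c(0.21, 0.20, 0.07), rep(0.05, 3)),
    g("autism", "Names", c(0.46, 0.38, 0.22), c(0.21, 0.20, 0.07), rep(0.05, 3)))
}

#' Simulation configuration
#'
#' Assembles the full parameter set of the synthetic EEG generator. The
#' defaults encode the stimulation protocol (5.77 Hz base rate, oddball
#' every fifth stimulus at 1.154 Hz, 96 oddball cycles, 500 Hz sampling)
#' and an effect structure in which the neurotypical group shows a graded
#' Self > CloseOther > Stranger face response while the autism group's
#' Self and CloseOther face responses coincide.
#'
#' @param f_base base stimulation frequency, Hz.
#' @param f_odd oddball frequency, Hz; must satisfy `f_base = 5 * f_odd`.
#' @param fs sampling rate, Hz.
#' @param n_cycles number of oddball cycles per train.
#' @param epoch_s epoch length cut around each train onset, seconds.
#' @param pre_s,post_s padding simulated before the train onset marker and
#'   after the epoch, seconds.
#' @param n_per_group named integer vector, subjects per group.
#' @param conditions,stimulus_types design levels to simulate.
#' @param effect_design amplitude design, see [default_effect_design()].
#' @param base_amp named vector of summed steady-state base-rate amplitudes
#'   (microvolts) per region class.
#' @param harmonic_rolloff multiplicative amplitude decay per harmonic
#'   order, in (0, 1].
#' @param max_harmonic highest oddball multiple injected (multiples of 5,
#'   i.e. base-rate bins, carry only base amplitude).
#' @param n_base_harmonics number of base-rate harmonics injected.
#' @param noise_scale RMS of the 1/f background noise per channel,
#'   microvolts. The default is deliberately low so that ground-truth
#'   recovery, not SNR realism, is the generator's contract.
#' @param noise_exponent spectral exponent alpha of the 1/f^alpha noise
#'   power spectrum (amplitude falls as f^(-alpha/2)).
#' @param line_freq,line_amp mains interference frequency (Hz) and
#'   amplitude (microvolts); 50 Hz sits inside the analysis band on
#'   purpose.
#' @param blink_rate,blink_amp,blink_width_s ocular artifacts: Poisson
#'   blink rate (events/minute), peak amplitude at the frontopolar sites
#'   (microvolts) and raised-cosine blink duration (seconds).
#' @param between_subject_sd SD of the additive per-subject amplitude
#'   perturbation (microvolts), truncated so amplitudes stay non-negative.
#' @param zero_common_mode if `TRUE` (default), signal phases are drawn
#'   independently per channel and the spatial mean of each harmonic's
#'   complex amplitude is subtracted, making the injected topography
#'   exactly orthogonal to the common mode: average re-referencing then
#'   leaves the signal untouched. The ground-truth table records the
#'   realized (post-nulling) per-channel amplitudes. Set `FALSE` to inject
#'   the design amplitudes exactly (e.g. a tone on a single channel).
#' @param channels optional subset of montage labels to simulate (defaults
#'   to the full 64-channel montage).
#' @param seed integer master seed; every recording's randomness is derived
#'   from it deterministically.
#' @return A list of class `fpvs_sim_config`.
#' @export
sim_config <- function(f_base = 5.77, f_odd = f_base / 5, fs = 500,
                       n_cycles = 96, epoch_s = 84, pre_s = 1, post_s = 1,
                       n_per_group = c(NT = 24, autism = 20),
                       conditions = c("Self", "CloseOther", "Stranger"),
                       stimulus_types = c("Faces", "Names"),
                       effect_design = default_effect_design(),
                       base_amp = c(`parieto-occipital` = 2.0,
                                    frontocentral = 1.0, other = 0.5),
                       harmonic_rolloff = 0.7, max_harmonic = 8,
                       n_base_harmonics = 4,
                       noise_scale = 0.25, noise_exponent = 1.0,
                       line_freq = 50, line_amp = 1.0,
                       blink_rate = 15, blink_amp = 100,
                       blink_width_s = 0.3,
                       between_subject_sd = 0.3,
                       zero_common_mode = TRUE,
                       channels = NULL, seed = 1L) {
  if (abs(f_base - 5 * f_odd) > 1e-9)
    stop("`f_base` must equal 5 * `f_odd`")
  if (fs <= 0) stop("`fs` must be positive")
  if (harmonic_rolloff <= 0 || harmonic_rolloff > 1)
    stop("`harmonic_rolloff` must be in (0, 1]")
  if (any(effect_design$amp < 0) || any(base_amp < 0) || noise_scale < 0 ||
      line_amp < 0 || blink_amp < 0)
    stop("amplitudes must be non-negative")
  if (epoch_s < n_cycles / f_odd)
    stop("`epoch_s` shorter than `n_cycles` oddball cycles")
  cfg <- list(f_base = f_base, f_odd = f_odd, fs = fs, n_cycles = n_cycles,
              epoch_s = epoch_s, pre_s = pre_s, post_s = post_s,
              n_per_group = n_per_group, conditions = conditions,
              stimulus_types = stimulus_types,
              effect_design = effect_design, base_amp = base_amp,
              harmonic_rolloff = harmonic_rolloff,
              max_harmonic = max_harmonic,
              n_base_harmonics = n_base_harmonics,
              noise_scale = noise_scale, noise_exponent = noise_exponent,
              line_freq = line_freq, line_amp = line_amp,
              blink_rate = blink_rate, blink_amp = blink_amp,
              blink_width_s = blink_width_s,
              between_subject_sd = between_subject_sd,
              zero_common_mode = zero_common_mode,
              channels = channels, seed = as.integer(seed))
  class(cfg) <- "fpvs_sim_config"
  cfg
}

#' @export
print.fpvs_sim_config <- function(x, ...) {
  cat(sprintf("<fpvs_sim_config> base %g Hz / oddball %g Hz, fs %g Hz, %d cycles\n",
              x$f_base, x$f_odd, x$fs, x$n_cycles))
  cat(sprintf("  groups: %s; noise %g uV RMS (1/f^%g); seed %d\n",
              paste(sprintf("%s=%d", names(x$n_per_group), x$n_per_group),
                    collapse = ", "),
              x$noise_scale, x$noise_exponent, x$seed))
  invisible(x)
}

# oddball multiples injected (base-rate bins excluded) and their
# rolloff weights, normalised so the weights sum to 1
.oddball_multiples <- function(max_harmonic) {
  k <- seq_len(max_harmonic)
  k[k %% 5L != 0L]
}
.rolloff_weights <- function(orders, rolloff) {
  w <- rolloff^(orders - 1)
  w / sum(w)
}

# frontal blink topography: Gaussian falloff in great-circle distance
# from the midpoint of Fp1/Fp2
.blink_weights <- function(montage, labels) {
  mid <- colMeans(montage$positions[c("Fp1", "Fp2"), , drop = FALSE])
  mid <- mid / sqrt(sum(mid^2))
  ang <- acos(pmin(1, pmax(-1, montage$positions[labels, , drop = FALSE] %*% mid)))
  w <- exp(-(ang^2) / (2 * 0.6^2))
  as.vector(w)
}

# within-region electrode gain: the four predeclared cluster electrodes get
# the region's full gain, other in-region electrodes a reduced one
.electrode_gain <- function(montage, labels) {
  cluster <- unlist(lapply(fixed_rois(), `[[`, "electrodes"))
  gain <- ifelse(labels %in% cluster, 1.0,
                 ifelse(montage$region[labels] == "other", 1.0, 0.6))
  names(gain) <- labels
  gain
}

.region_class <- function(montage, labels) {
  r <- montage$region[labels]
  out <- ifelse(r %in% c("left-parieto-occipital", "right-parieto-occipital"),
                "parieto-occipital",
                ifelse(r == "frontocentral", "frontocentral", "other"))
  names(out) <- labels
  out
}

# 1/f^alpha Gaussian noise, length n, rescaled to the requested RMS;
# spectrum flattened below f0 to keep the DC end finite
.pink_noise <- function(n, fs, rms, alpha, f0 = 0.1) {
  if (rms == 0) return(numeric(n))
  nf <- floor(n / 2)
  f <- (1:nf) * fs / n
  shape <- pmax(f, f0)^(-alpha / 2)
  re <- stats::rnorm(nf); im <- stats::rnorm(nf)
  spec <- complex(real = re, imaginary = im) * shape
  full <- complex(length.out = n)
  full[2:(nf + 1)] <- spec
  if (n %% 2 == 0) {
    full[nf + 1] <- complex(real = re[nf] * shape[nf])
    full[(nf + 2):n] <- Conj(full[nf:2])
  } else {
    full[(nf + 2):n] <- Conj(full[(nf + 1):2])
  }
  x <- Re(stats::fft(full, inverse = TRUE)) / n
  x <- x - mean(x)
  s <- stats::sd(x)
  if (s == 0) numeric(n) else x * (rms / s)
}

#' Simulate one FPVS-EEG recording
#'
#' Generates a continuous recording for one subject, condition and stimulus
#' type: steady-state cosines at the base frequency and its harmonics plus
#' oddball-frequency harmonics (base-rate multiples carry base amplitude
#' only), 1/f background noise, mains interference and frontally weighted
#' blink artifacts. A train-onset stimulus marker is written at the end of
#' the pre-padding. The per-channel, per-harmonic amplitudes actually
#' injected (after common-mode nulling, see [sim_config()]) are returned as
#' a ground-truth table so downstream recovery can be checked exactly.
#'
#' All randomness (phases, noise, blinks) is derived deterministically from
#' `config$seed` and the identifying arguments, so the same call is
#' bit-reproducible.
#'
#' @param config an [sim_config()] object.
#' @param subject_id subject identifier string.
#' @param group group label present in `names(config$n_per_group)`.
#' @param condition,stimulus_type design cell to simulate.
#' @param subject_offset additive amplitude perturbation (microvolts)
#'   applied to this subject's design amplitudes before truncation at zero;
#'   [simulate_study()] draws it with SD `between_subject_sd`.
#' @return A list with elements `recording` (an `fpvs_recording`),
#'   `ground_truth` (data frame: subject, group, condition, stimulus_type,
#'   channel, component, frequency, amplitude_uV) and `blink_course`
#'   (the unit blink regressor, for artifact-removal validation).
#' @export
simulate_recording <- function(config, subject_id, group, condition,
                               stimulus_type, subject_offset = 0) {
  if (!group %in% names(config$n_per_group)) stop("unknown group: ", group)
  if (!condition %in% config$conditions) stop("unknown condition: ", condition)
  if (!stimulus_type %in% config$stimulus_types)
    stop("unknown stimulus type: ", stimulus_type)
  montage <- make_montage()
  labels <- if (is.null(config$channels)) montage$labels else {
    miss <- setdiff(config$channels, montage$labels)
    if (length(miss)) stop("unknown channels: ", paste(miss, collapse = ", "))
    config$channels
  }
  fs <- config$fs
  n <- round((config$pre_s + config$epoch_s + config$post_s) * fs)
  t <- (seq_len(n) - 1) / fs
  nch <- length(labels)

  rclass <- .region_class(montage, labels)
  gain <- .electrode_gain(montage, labels)
  des <- config$effect_design
  row_amp <- function(rc) {
    i <- which(des$group == group & des$stimulus_type == stimulus_type &
                 des$condition == condition & des$region_class == rc)
    if (!length(i)) stop("effect design has no cell for ", group, "/",
                         stimulus_type, "/", condition, "/", rc)
    des$amp[i[1]]
  }
  cell_amp <- vapply(rclass, row_amp, numeric(1))
  odd_total <- pmax(0, cell_amp + subject_offset) * gain
  base_total <- pmax(0, config$base_amp[rclass] + subject_offset) * gain

  odd_mult <- .oddball_multiples(config$max_harmonic)
  odd_w <- .rolloff_weights(odd_mult, config$harmonic_rolloff)
  base_mult <- seq_len(config$n_base_harmonics)
  base_w <- .rolloff_weights(base_mult, config$harmonic_rolloff)

  seed <- .derive_seed(config$seed, subject_id, group, condition,
                       stimulus_type)
  out <- with_seed(seed, {
    # per-channel, per-harmonic phases: incoherent across the scalp. With
    # `zero_common_mode` the spatial mean of each harmonic's complex
    # amplitude is subtracted, so average re-referencing leaves the signal
    # untouched; the realized (post-nulling) moduli become the ground truth.
    make_tones <- function(totals, weights) {
      camp <- vapply(weights, function(wk) {
        phi <- stats::runif(nch, 0, 2 * pi)
        totals * wk * exp(1i * phi)
      }, complex(nch))
      camp <- matrix(camp, nrow = nch)
      if (isTRUE(config$zero_common_mode) && nch > 1)
        camp <- sweep(camp, 2, colMeans(camp))
      camp
    }
    synth <- function(data, camp, mults, f0) {
      for (i in seq_along(mults)) {
        w <- 2 * pi * mults[i] * f0 * t
        data <- data + outer(Re(camp[, i]), cos(w)) -
          outer(Im(camp[, i]), sin(w))
      }
      data
    }
    odd_camp <- make_tones(odd_total, odd_w)
    base_camp <- make_tones(base_total, base_w)
    data <- matrix(0, nch, n)
    data <- synth(data, odd_camp, odd_mult, config$f_odd)
    data <- synth(data, base_camp, base_mult, config$f_base)
    if (config$noise_scale > 0)
      for (i in seq_len(nch))
        data[i, ] <- data[i, ] + .pink_noise(n, fs, config$noise_scale,
                                             config$noise_exponent)
    if (config$line_amp > 0)
      data <- data + matrix(config$line_amp *
                              sin(2 * pi * config$line_freq * t),
                            nch, n, byrow = TRUE)
    blink_course <- numeric(n)
    if (config$blink_rate > 0 && config$blink_amp > 0) {
      n_blinks <- stats::rpois(1, config$blink_rate * n / fs / 60)
      if (n_blinks > 0) {
        onsets <- sort(stats::runif(n_blinks, 0, n / fs - config$blink_width_s))
        wlen <- round(config$blink_width_s * fs)
        shape <- 0.5 * (1 - cos(2 * pi * seq(0, 1, length.out = wlen)))
        for (on in onsets) {
          i0 <- round(on * fs) + 1L
          idx <- i0:(i0 + wlen - 1L)
          idx <- idx[idx <= n]
          blink_course[idx] <- blink_course[idx] + shape[seq_along(idx)]
        }
        data <- data + outer(config$blink_amp * .blink_weights(montage, labels),
                             blink_course)
      }
    }
    list(data = data, blink_course = blink_course,
         odd_amp = Mod(odd_camp), base_amp = Mod(base_camp))
  })

  events <- data.frame(sample = round(config$pre_s * fs) + 1L,
                       code = event_code(condition, stimulus_type))
  rec <- new_recording(out$data, labels, fs, events = events)

  gt <- rbind(
    data.frame(channel = rep(labels, each = length(odd_mult)),
               component = "oddball",
               frequency = rep(odd_mult * config$f_odd, times = nch),
               amplitude_uV = as.vector(t(out$odd_amp))),
    data.frame(channel = rep(labels, each = length(base_mult)),
               component = "base",
               frequency = rep(base_mult * config$f_base, times = nch),
               amplitude_uV = as.vector(t(out$base_amp))))
  gt <- cbind(data.frame(subject = subject_id, group = group,
                         condition = condition,
                         stimulus_type = stimulus_type), gt)
  rownames(gt) <- NULL
  list(recording = rec, ground_truth = gt, blink_course = out$blink_course)
}

#' Simulate a full study
#'
#' Generates recordings for every subject x condition x stimulus type cell
#' of the design. Each subject receives one additive amplitude perturbation
#' (SD `between_subject_sd`, shared across all their cells, truncated so
#' amplitudes stay non-negative).
#'
#' For large designs the recordings can be consumed one at a time via
#' `callback` instead of being accumulated in memory.
#'
#' @param config an [sim_config()] object.
#' @param callback optional `function(sim, subject, group)` invoked per
#'   recording; when supplied, recordings are not retained.
#' @return An object of class `fpvs_study`: list with `subjects` (data
#'   frame subject/group/offset), `ground_truth` (combined table) and
#'   `recordings` (named list of [simulate_recording()] results, empty if
#'   `callback` was used).
#' @export
simulate_study <- function(config, callback = NULL) {
  if (any(config$n_per_group < 1)) stop("need at least one subject per group")
  groups <- names(config$n_per_group)
  subjects <- data.frame(
    subject = unlist(lapply(groups, function(g)
      sprintf("%s%02d", g, seq_len(config$n_per_group[[g]])))),
    group = rep(groups, times = config$n_per_group))
  subjects$offset <- with_seed(.derive_seed(config$seed, "offsets"),
                               stats::rnorm(nrow(subjects), 0,
                                            config$between_subject_sd))
  recordings <- list()
  gt <- vector("list", 0)
  for (i in seq_len(nrow(subjects))) {
    for (st in config$stimulus_types) {
      for (cond in config$conditions) {
        sim <- simulate_recording(config, subjects$subject[i],
                                  subjects$group[i], cond, st,
                                  subject_offset = subjects$offset[i])
        gt[[length(gt) + 1L]] <- sim$ground_truth
        if (is.null(callback)) {
          recordings[[paste(subjects$subject[i], st, cond, sep = "_")]] <- sim
        } else {
          callback(sim, subjects$subject[i], subjects$group[i])
        }
      }
    }
  }
  structure(list(subjects = subjects,
                 ground_truth = do.call(rbind, gt),
                 recordings = recordings),
            class = "fpvs_study")
}

#' @export
print.fpvs_study <- function(x, ...) {
  cat(sprintf("<fpvs_study> %d subjects (%s), %d recording cell(s)\n",
              nrow(x$subjects),
              paste(sprintf("%s=%d", names(table(x$subjects$group)),
                            table(x$subjects$group)), collapse = ", "),
              max(length(x$recordings),
                  nrow(unique(x$ground_truth[c("subject", "condition",
                                               "stimulus_type")])))))
  invisible(x)
}

#' Replace channels with high-variance noise
#'
#' Corrupts the listed channels of a recording with white noise whose SD is
#' several times the recording's median channel SD, emulating broken or
#' bridged electrodes so that bad-channel handling can be exercised. More
#' than two bad channels is allowed but warned about, mirroring the usual
#' per-participant limit.
#'
#' @param recording an `fpvs_recording`.
#' @param labels channels to corrupt (may be empty).
#' @param seed integer seed for the injected noise.
#' @return The corrupted recording.
#' @export
inject_bad_channels <- function(recording, labels, seed = 1L) {
  if (!length(labels)) return(recording)
  miss <- setdiff(labels, recording$labels)
  if (length(miss)) stop("unknown label(s): ", paste(miss, collapse = ", "))
  if (length(labels) > 2L)
    warning("more than two bad channels injected (", length(labels), ")")
  med_sd <- stats::median(apply(recording$data, 1, stats::sd))
  if (med_sd == 0) med_sd <- 1
  recording$data[match(labels, recording$labels), ] <-
    with_seed(seed, matrix(stats::rnorm(length(labels) * ncol(recording$data),
                                        0, 8 * med_sd),
                           nrow = length(labels)))
  recording
}
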