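test_that("amplitude normalization returns a cosine's peak amplitude", {
  fs <- 500
  n <- floor(96 / 1.154 * fs)
  f_exact <- 96 * fs / n  # exactly on the frequency grid
  ep <- cosine_epoch(f_exact, 2, fs = fs, n = n)
  sp <- amplitude_spectrum(ep)
  expect_equal(sp$delta_f, fs / n)
  expect_equal(length(sp$freqs), floor(n / 2) + 1)
  expect_equal(sp$amps[1, nearest_bin(sp, f_exact)], 2, tolerance = 1e-9)
  # at the protocol's 1.154 Hz the crop is commensurate only to ~1e-3 cycles
  ep2 <- cosine_epoch(1.154, 2, fs = fs, n = n)
  sp2 <- amplitude_spectrum(ep2)
  expect_equal(sp2$amps[1, nearest_bin(sp2, 1.154)], 2, tolerance = 1e-5)
})

test_that("zero signal gives a zero spectrum and empty input errors", {
  ep <- new_epoch(matrix(0, 2, 1000), c("A", "B"), 500, "Self", "Faces")
  expect_true(all(amplitude_spectrum(ep)$amps == 0))
  empty <- structure(list(data = matrix(numeric(0), 1, 0), labels = "A",
                          fs = 500), class = c("fpvs_epoch",
                                               "fpvs_recording"))
  expect_error(amplitude_spectrum(empty), "empty")
})

test_that("two exact-bin cosines are recovered independently", {
  fs <- 100; n <- 1000
  f1 <- 5 * fs / n; f2 <- 20 * fs / n
  t <- (seq_len(n) - 1) / fs
  x <- 1.5 * cos(2 * pi * f1 * t) + 0.5 * cos(2 * pi * f2 * t + 1)
  ep <- new_epoch(matrix(x, 1, n), "Cz", fs, "Self", "Faces")
  sp <- amplitude_spectrum(ep)
  expect_equal(sp$amps[1, 6], 1.5, tolerance = 1e-9)
  expect_equal(sp$amps[1, 21], 0.5, tolerance = 1e-9)
})

test_that("amplitude_spectrum matches a direct DFT oracle", {
  set.seed(71)
  fs <- 250
  for (n in c(256, 1000)) {
    x <- rnorm(n)
    ep <- new_epoch(matrix(x, 1, n), "Cz", fs, "Self", "Faces")
    sp <- amplitude_spectrum(ep)
    oracle <- dft_amplitude_oracle(x, fs)
    expect_lt(max(abs(sp$amps[1, ] - oracle$amps)), 1e-9)
    expect_equal(sp$freqs, oracle$freqs)
  }
})

test_that("harmonic_frequencies skips multiples of the base rate", {
  expect_equal(round(harmonic_frequencies(), 2),
               c(1.15, 2.31, 3.46, 4.62, 6.92, 8.08, 9.23))
  expect_length(harmonic_frequencies(), 7)
  expect_equal(harmonic_frequencies(max_multiple = 1), 1.154)
  f10 <- harmonic_frequencies(max_multiple = 10)
  expect_false(any(abs(f10 - 5.77) < 1e-9))
  expect_false(any(abs(f10 - 11.54) < 1e-9))
  # the 10th multiple (11.54 Hz) is the base's 2nd harmonic, so the
  # highest retained multiple is the 9th
  expect_equal(max(f10), 9 * 1.154)
  expect_length(f10, 8)
  expect_error(harmonic_frequencies(f_odd = 1, f_base = 6), "5 \\* `f_odd`")
  expect_error(harmonic_frequencies(max_multiple = 0), "at least 1")
})

test_that("noise_window validates its shape", {
  w <- noise_window()
  expect_equal(w$n_side, 10L)
  expect_equal(w$n_exclude, 1L)
  expect_error(noise_window(1, 1), "n_side > n_exclude")
  expect_error(noise_window(5, -1), "n_side > n_exclude")
})

test_that("nearest_bin rounds correctly and breaks ties downward", {
  sp <- manual_spectrum(rep(1, 101), delta_f = 0.5)
  expect_equal(nearest_bin(sp, 10), 21L)          # exact hit
  expect_equal(nearest_bin(sp, 10 + 0.4 * 0.5), 21L)  # within half a bin
  expect_equal(nearest_bin(sp, 10.25), 21L)       # midpoint -> lower bin
  expect_equal(nearest_bin(sp, 10.26), 22L)
  expect_equal(nearest_bin(sp, 0), 1L)
  expect_error(nearest_bin(sp, 51), "outside")
  expect_error(nearest_bin(sp, -1), "outside")
})

test_that("baseline subtraction cancels flat and linear backgrounds", {
  w <- noise_window()
  flat <- manual_spectrum(rep(3, 201), 0.01)
  expect_equal(baseline_subtracted_amplitude(flat, 1, 100, w), 0)
  peak <- manual_spectrum(c(rep(0, 99), 2.5, rep(0, 101)), 0.01)
  expect_equal(baseline_subtracted_amplitude(peak, 1, 100, w), 2.5)
  ramp <- manual_spectrum(seq(0, 2, length.out = 201), 0.01)
  expect_lt(abs(baseline_subtracted_amplitude(ramp, 1, 100, w)), 1e-9)
  # adding a constant to the whole spectrum changes nothing
  shifted <- ramp
  shifted$amps <- shifted$amps + 7
  expect_equal(baseline_subtracted_amplitude(shifted, 1, 100, w),
               baseline_subtracted_amplitude(ramp, 1, 100, w),
               tolerance = 1e-12)
  # negative results are not clipped
  dip <- manual_spectrum(c(rep(1, 99), 0.2, rep(1, 101)), 0.01)
  expect_lt(baseline_subtracted_amplitude(dip, 1, 100, w), 0)
})

test_that("the noise window shrinks at the spectrum edge with a warning", {
  sp <- manual_spectrum(rep(1, 50), 0.01)
  expect_warning(v <- baseline_subtracted_amplitude(sp, 1, 6, noise_window()),
                 "shrunk")
  expect_equal(v, 0)
  expect_error(suppressWarnings(
    baseline_subtracted_amplitude(sp, 1, 2, noise_window())),
    "no noise bins")
  expect_error(baseline_subtracted_amplitude(sp, "nope", 20, noise_window()),
               "unknown channel")
})

test_that("z-scores use the noise bins' sample statistics", {
  w <- noise_window()
  amps <- rep(c(0.9, 1.1), 101)[1:201]
  bin <- 100L
  noise_vals <- amps[bin + c(-(2:10), 2:10)]
  m <- mean(noise_vals); s <- sd(noise_vals)
  amps[bin] <- m + 1.7 * s
  sp <- manual_spectrum(amps, 0.01)
  expect_equal(zscore_amplitude(sp, 1, bin, w), 1.7, tolerance = 1e-12)
  # bs amplitude and z share the same noise bins
  expect_equal(baseline_subtracted_amplitude(sp, 1, bin, w), 1.7 * s,
               tolerance = 1e-12)
  # conventions at zero noise SD
  flat <- manual_spectrum(rep(2, 201), 0.01)
  expect_equal(zscore_amplitude(flat, 1, 100, w), 0)
  up <- flat; up$amps[1, 100] <- 3
  expect_identical(zscore_amplitude(up, 1, 100, w), Inf)
  dn <- flat; dn$amps[1, 100] <- 1
  expect_identical(zscore_amplitude(dn, 1, 100, w), -Inf)
})

# build a spectrum whose z-scores at the oddball multiples of 1 Hz equal a
# requested pattern (delta_f 0.01 -> harmonics sit 100 bins apart)
spectrum_with_z <- function(z_by_multiple, delta_f = 0.01, fmax = 10.5) {
  nb <- round(fmax / delta_f) + 1L
  amps <- rep(c(0.9, 1.1), length.out = nb)
  for (k in as.integer(names(z_by_multiple))) {
    bin <- round(k * 1 / delta_f) + 1L
    noise_vals <- amps[bin + c(-(2:10), 2:10)]
    amps[bin] <- mean(noise_vals) + z_by_multiple[[as.character(k)]] *
      sd(noise_vals)
  }
  manual_spectrum(amps, delta_f)
}

test_that("select_harmonics keeps the maximal consecutive significant run", {
  w <- noise_window()
  sp <- spectrum_with_z(list(`1` = 5, `2` = 4, `3` = 3, `4` = 2.5,
                             `6` = 3, `7` = 2.4, `8` = 2.35, `9` = 1.0))
  got <- select_harmonics(sp, f_odd = 1, f_base = 5, window = w,
                          max_multiple = 9)
  expect_equal(got, c(1, 2, 3, 4, 6, 7, 8))  # base multiple 5 skipped
  # nothing significant: the fundamental is still retained
  none <- spectrum_with_z(list(`1` = 1))
  expect_equal(select_harmonics(none, f_odd = 1, f_base = 5, window = w,
                                max_multiple = 9), 1)
  # a broken run stops at the break even if later multiples pass
  broken <- spectrum_with_z(list(`1` = 5, `2` = 1, `3` = 5))
  expect_equal(select_harmonics(broken, f_odd = 1, f_base = 5, window = w,
                                max_multiple = 9), 1)
})

test_that("select_harmonics averages multi-channel grand averages", {
  w <- noise_window()
  sp1 <- spectrum_with_z(list(`1` = 6, `2` = 6))
  two <- sp1
  two$amps <- rbind(sp1$amps[1, ], sp1$amps[1, ])
  two$labels <- c("A", "B")
  expect_equal(select_harmonics(two, f_odd = 1, f_base = 5, window = w,
                                max_multiple = 3),
               select_harmonics(sp1, f_odd = 1, f_base = 5, window = w,
                                max_multiple = 3))
})

test_that("oddball_response sums per-frequency baseline-subtracted bins", {
  w <- noise_window()
  peak <- manual_spectrum(c(rep(0, 99), 2.5, rep(0, 101)), 0.01,
                          labels = "PO8")
  r1 <- oddball_response(peak, "PO8", 0.99, w)
  expect_equal(r1$summed_bs,
               baseline_subtracted_amplitude(peak, "PO8", 100, w))
  expect_length(r1$per_freq_bs, 1)
  # injected 1 / 0.5 / 0.25 uV at oddball multiples 1-3, noise-free epoch
  f <- 1.154 * (1:3)
  ep <- cosine_epoch(f, c(1, 0.5, 0.25))
  sp <- amplitude_spectrum(ep)
  r <- oddball_response(sp, "PO8", f, w)
  expect_equal(r$per_freq_bs, c(1, 0.5, 0.25), tolerance = 1e-3)
  expect_equal(r$summed_bs, 1.75, tolerance = 1e-3)
  expect_equal(r$summed_bs, sum(r$per_freq_bs))
  expect_length(r$z_per_freq, 3)
})

test_that("summed response is unbiased on signal-free epochs", {
  des <- default_effect_design()
  des$amp <- 0
  cfg <- sim_config(effect_design = des,
                    base_amp = c(`parieto-occipital` = 0,
                                 frontocentral = 0, other = 0),
                    noise_scale = 0.25, line_amp = 0, blink_rate = 0,
                    channels = "PO8", seed = 37L)
  targets <- harmonic_frequencies()
  vals <- vapply(seq_len(200), function(r) {
    c2 <- cfg; c2$seed <- 50000L + r
    sim <- simulate_recording(c2, sprintf("s%03d", r), "NT", "Self", "Faces")
    ep <- crop_to_integer_cycles(segment(sim$recording, "Self", "Faces", 84))
    oddball_response(amplitude_spectrum(ep), "PO8", targets)$summed_bs
  }, numeric(1))
  sem <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals)), 2 * sem)
})

test_that("base_response quantifies base-rate entrainment separately", {
  des <- default_effect_design()
  des$amp <- 0
  cfg <- sim_config(effect_design = des,
                    base_amp = c(`parieto-occipital` = 2,
                                 frontocentral = 2, other = 2),
                    n_base_harmonics = 1, noise_scale = 0, line_amp = 0,
                    blink_rate = 0, channels = "PO8",
                    zero_common_mode = FALSE)
  sim <- simulate_recording(cfg, "NT01", "NT", "Self", "Faces")
  ep <- crop_to_integer_cycles(segment(sim$recording, "Self", "Faces", 84))
  sp <- amplitude_spectrum(ep)
  br <- base_response(sp, "PO8")
  expect_equal(br$per_freq_bs[1], 2, tolerance = 0.01)
  expect_lt(max(abs(br$per_freq_bs[-1])), 0.01)
  # base targets never intersect oddball targets
  expect_length(intersect(round(br$target_freqs, 6),
                          round(harmonic_frequencies(max_multiple = 16), 6)),
                0)
  # zero base amplitude gives ~0
  zr <- base_response(amplitude_spectrum(
    cosine_epoch(1.154, 1)), "PO8")
  expect_lt(max(abs(zr$per_freq_bs)), 1e-3)
})
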