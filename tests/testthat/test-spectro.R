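# spectro_segment: resampling, spectrograms, segmentation, the
# connected-component noise filter, and image export.

test_that("resampling preserves rate-44100 input and output length", {
  x <- sin(2 * pi * 440 * seq(0, 1, length.out = 44100))
  expect_identical(resample_to_44100(x, 44100), x)
  y <- resample_to_44100(rnorm(48000), 48000)
  expect_lte(abs(length(y) - 44100), 1)
  expect_error(resample_to_44100(numeric(0), 48000), "empty")
})

test_that("downsampling is alias-free (spectral check)", {
  t48 <- seq_len(48000) / 48000
  y <- resample_to_44100(sin(2 * pi * 15000 * t48), 48000)
  spec <- compute_spectrogram(y)
  pw <- rowMeans(10^(spec$power / 10))
  main <- max(pw[spec$freq_axis > 14000 & spec$freq_axis < 16000])
  alias <- max(pw[spec$freq_axis > 100 & spec$freq_axis < 10000])
  expect_lt(10 * log10(alias / main), -60)
  # tone frequency is preserved
  expect_lt(abs(spec$freq_axis[which.max(pw)] - 15000), 44100 / 1024)
})

test_that("spectrogram frequency tracking: tone constant, chirp monotone", {
  tone <- synthesize_song(tone_song_spec(1, 400, 50, f_low = 5000), -70)
  spec <- compute_spectrogram(tone$waveform)
  frames <- spec$time_axis > 200 & spec$time_axis < 450
  peaks <- apply(spec$power[, frames], 2, which.max)
  expect_equal(length(unique(peaks)), 1)

  chirp <- synthesize_song(
    song_spec("A", -80, 40, 1,
              data.frame(type_id = 0L, onset_ms = 150, duration_ms = 500,
                         f_low_hz = 3000, f_high_hz = 8000,
                         shape = "chirp")), -70)
  spec2 <- compute_spectrogram(chirp$waveform)
  frames2 <- which(spec2$time_axis > 220 & spec2$time_axis < 580)
  peaks2 <- apply(spec2$power[, frames2], 2, which.max)
  expect_true(all(diff(peaks2) >= 0))

  expect_error(compute_spectrogram(rnorm(100)), "longer than")
})

test_that("segmentation recovers tone intervals and honors min_silence", {
  rec <- synthesize_song(tone_song_spec(3, 100, 50), -50)
  spec <- compute_spectrogram(rec$waveform)
  p20 <- segmentation_params(min_silence_ms = 20)
  iv <- segment_syllables(spec, p20)
  expect_equal(nrow(iv), 3)
  truth <- data.frame(onset_ms = c(150, 300, 450),
                      offset_ms = c(250, 400, 550))
  # within +- 2 time bins of truth
  expect_true(all(abs(iv$onset_ms - truth$onset_ms) <= 2 * spec$hop_ms))
  expect_true(all(abs(iv$offset_ms - truth$offset_ms) <= 2 * spec$hop_ms))

  # raising min_silence above the gap merges everything
  iv80 <- segment_syllables(spec, segmentation_params(min_silence_ms = 80))
  expect_equal(nrow(iv80), 1)

  # monotonicity: more min_silence never yields more intervals
  counts <- vapply(c(5, 15, 30, 60, 120), function(ms)
    nrow(segment_syllables(spec, segmentation_params(min_silence_ms =
                                                       ms))),
    numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("pure noise yields zero intervals at the default quantile", {
  set.seed(42)
  iv <- segment_syllables(compute_spectrogram(rnorm(44100, 0, 0.05)))
  expect_equal(nrow(iv), 0)
})

test_that("half-open interval arithmetic reconstructs the frame grid", {
  rec <- synthesize_song(tone_song_spec(4, 90, 60), -50)
  spec <- compute_spectrogram(rec$waveform)
  iv <- segment_syllables(spec)
  # every boundary sits on the (window-centered) hop grid, so sound +
  # silence tiles the spectrogram span exactly
  g <- (iv$onset_ms - spec$t0_ms) / spec$hop_ms
  expect_true(all(abs(g - round(g)) < 1e-9))
  expect_true(all(iv$offset_ms > iv$onset_ms))
  expect_true(all(iv$onset_ms[-1] >= iv$offset_ms[-nrow(iv)]))
})

test_that("noise-component filter drops speckle and keeps real syllables", {
  rec <- synthesize_song(tone_song_spec(2, 100, 60), -50)
  spec <- compute_spectrogram(rec$waveform)
  iv <- segment_syllables(spec)
  # absurdly high threshold discards every interval
  p_hi <- segmentation_params(noise_element_threshold = 10^6)
  expect_equal(nrow(filter_noise_components(spec, iv, p_hi)$intervals), 0)
  # default thresholds keep both
  fl <- filter_noise_components(spec, iv, segmentation_params())
  expect_equal(nrow(fl$intervals), 2)
  # monotonicity: higher threshold never retains more components
  thr <- c(10, 100, 500, 2000)
  ncomp <- vapply(thr, function(k) {
    f <- filter_noise_components(spec, iv,
                                 segmentation_params(
                                   noise_element_threshold = k))
    sum(f$intervals$n_components)
  }, numeric(1))
  expect_true(all(diff(ncomp) <= 0))
})

test_that("component labeling matches a hand-counted constructed mask", {
  m <- matrix(FALSE, 8, 10)
  m[2:4, 2:4] <- TRUE          # 9-element block
  m[7, 7] <- TRUE              # singleton
  m[1, 9] <- TRUE; m[2, 10] <- TRUE  # diagonal pair (8-connected)
  lab <- songcline:::cpp_label_components(m)
  sizes <- sort(tabulate(lab[lab > 0]))
  expect_equal(sizes, c(1, 2, 9))
  expect_equal(max(lab), 3)
})

test_that("spectrogram image export meets the 224x224x3 contract", {
  rec <- synthesize_song(tone_song_spec(2, 120, 80), -45)
  f1 <- withr::local_tempfile(fileext = ".png")
  f2 <- withr::local_tempfile(fileext = ".png")
  export_spectrogram_image(rec$waveform, f1)
  arr <- read_spectrogram_image(f1)
  expect_equal(dim(arr), c(224L, 224L, 3L))
  expect_true(all(arr >= 0 & arr <= 1))
  # determinism: identical pixel arrays
  export_spectrogram_image(rec$waveform, f2)
  expect_identical(arr, read_spectrogram_image(f2))
  # near-silence input -> (numerically) uniform background
  set.seed(1)
  f3 <- withr::local_tempfile(fileext = ".png")
  export_spectrogram_image(rnorm(44100, 0, 1e-4), f3)
  arr3 <- read_spectrogram_image(f3)
  expect_lt(sd(arr3), 0.25)
})
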