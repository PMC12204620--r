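# synth_song: generator invariants, seeded determinism, geographic
# sampling, alignments.

test_that("synthesize_song renders planned syllables as supra-noise runs", {
  spec <- tone_song_spec(3, 100, 50)
  rec <- synthesize_song(spec, -50)
  expect_s3_class(rec, "synthetic_recording")
  expect_equal(rec$sample_rate, 44100)
  expect_lte(max(abs(rec$waveform)), 0.9 + 1e-12)

  # energy-vs-time profile has exactly 3 supra-noise runs
  env <- abs(rec$waveform)
  win <- 441  # 10 ms
  smooth <- stats::filter(env, rep(1 / win, win), sides = 2)
  smooth[is.na(smooth)] <- 0
  runs <- rle(as.numeric(smooth > max(smooth) / 10))
  expect_equal(sum(runs$values == 1), 3)
})

test_that("same spec and seed give bit-identical waveforms", {
  spec <- tone_song_spec(2, 80, 60, seed = 99)
  expect_identical(synthesize_song(spec, -45)$waveform,
                   synthesize_song(spec, -45)$waveform)
})

test_that("chirp energy is confined to its frequency band (STFT check)", {
  spec <- song_spec("A", -80, 40, 3,
                    data.frame(type_id = 0L, onset_ms = 150,
                               duration_ms = 300, f_low_hz = 3000,
                               f_high_hz = 8000, shape = "chirp"))
  rec <- synthesize_song(spec, -60)
  # independent short-time Fourier analysis (own fft, not the package's
  # spectrogram path)
  fs <- 44100; win <- 1024
  starts <- seq(round(0.18 * fs), round(0.40 * fs), by = 512)
  freqs <- (seq_len(win / 2) - 1) * fs / win
  bin_hz <- fs / win
  for (s in starts) {
    seg <- rec$waveform[s:(s + win - 1)] *
      0.5 * (1 - cos(2 * pi * seq(0, 1, length.out = win)))
    mag <- Mod(fft(seg))[seq_len(win / 2)]
    strong <- freqs[mag > max(mag) / 10]
    expect_gte(min(strong), 3000 - 2 * bin_hz)
    expect_lte(max(strong), 8000 + 2 * bin_hz)
  }
})

test_that("song_spec rejects invalid plans", {
  syl <- data.frame(type_id = 0L, onset_ms = 150, duration_ms = 100,
                    f_low_hz = 3000, f_high_hz = 3200, shape = "tone")
  expect_error(song_spec("A", -80, 40, 1, syl, duration_ms = 200),
               "extend")
  bad <- rbind(syl, within(syl, onset_ms <- 200))  # overlapping
  expect_error(song_spec("A", -80, 40, 1, bad), "overlap")
  gap <- within(syl, type_id <- 2L)                # ids not dense
  expect_error(song_spec("A", -80, 40, 1, gap), "dense")
})

test_that("sample_population assigns species deterministically by region", {
  model <- population_model(n_recordings = 400)
  pop <- sample_population(model, seed = 3, plan_songs = FALSE)
  m <- pop$metadata
  expect_true(all(m$species[m$longitude < -102] == "B"))
  expect_true(all(m$species[m$longitude >= -91] == "A"))
  # determinism and metadata-only equivalence
  pop2 <- sample_population(model, seed = 3)
  expect_identical(m, pop2$metadata)
  # ground-truth intervals: sorted, disjoint, inside the bout
  for (sp in pop2$specs[1:25]) {
    offs <- sp$syllables$onset_ms + sp$syllables$duration_ms
    expect_true(all(diff(sp$syllables$onset_ms) > 0))
    expect_true(all(sp$syllables$onset_ms[-1] >=
                      offs[-length(offs)] - 1e-9))
    expect_lte(max(offs), sp$duration_ms)
  }
})

test_that("in-zone hybrid share matches hybrid_fraction within binomial error", {
  pop <- sample_population(population_model(n_recordings = 10000),
                           seed = 9, plan_songs = FALSE)
  m <- pop$metadata
  inz <- m$longitude >= -102 & m$longitude < -91
  share <- mean(m$species[inz] == "hybrid_unsure")
  se <- sqrt(0.025 * 0.975 / sum(inz))
  expect_lt(abs(share - 0.025), 3 * se)
})

test_that("a zero cline leaves species parameter means flat in longitude", {
  prof <- default_profile_b()
  prof$cline_slope[] <- 0
  model <- population_model(profile_b = prof, n_recordings = 300)
  pop <- sample_population(model, seed = 5)
  bb <- which(pop$metadata$species == "B")
  f_hi <- vapply(pop$specs[bb], function(s) max(s$syllables$f_high_hz),
                 numeric(1))
  fit <- lm(f_hi ~ pop$metadata$longitude[bb])
  expect_gt(summary(fit)$coefficients[2, 4], 0.01)  # slope not significant
})

test_that("generate_dataset writes one WAV + truth + metadata row each", {
  dir <- withr::local_tempdir()
  meta <- generate_dataset(population_model(), n = 5, seed = 2,
                           out_dir = dir)
  expect_equal(nrow(meta), 5)
  expect_true(all(file.exists(meta$wav_path)))
  expect_true(all(file.exists(meta$truth_path)))
  expect_true(file.exists(file.path(dir, "metadata.csv")))
  # dates honor the default all-breeding-season window
  months <- as.integer(format(as.Date(meta$date), "%m"))
  expect_true(all(months >= 4 & months <= 8))
  # same seed -> identical metadata
  dir2 <- withr::local_tempdir()
  meta2 <- generate_dataset(population_model(), n = 5, seed = 2,
                            out_dir = dir2)
  expect_identical(meta$species, meta2$species)
  expect_identical(meta$longitude, meta2$longitude)
  # truth round-trips and matches the WAV on disk
  tr <- jsonlite::read_json(meta$truth_path[1], simplifyVector = TRUE)
  w <- read_wav(meta$wav_path[1])
  expect_equal(w$sample_rate, 44100)
  expect_lte(max(tr$syllables$offset_ms), tr$duration_ms)
})

test_that("generate_alignment produces the configured differentiation", {
  # fixed differences only: zero within, positive between
  aln <- generate_alignment(genetic_model(c(4, 4), 100, 10, 0, seed = 1))
  d <- seq_distance_matrix(aln, mode = "p_distance")
  expect_equal(max(d[1:4, 1:4]), 0)
  expect_equal(max(d[5:8, 5:8]), 0)
  expect_true(all(d[1:4, 5:8] > 0))
  expect_equal(unique(as.vector(d[1:4, 5:8])), 0.1)

  expect_error(genetic_model(c(2, 2), 5, 10, 0), "exceeds")

  # FASTA + sidecar round trip
  fa <- withr::local_tempfile(fileext = ".fasta")
  meta <- withr::local_tempfile(fileext = ".csv")
  generate_alignment(genetic_model(c(3, 3), 60, 4, 0.01, seed = 2),
                     fasta_path = fa, meta_path = meta)
  back <- read_alignment(fa, meta)
  expect_equal(nrow(back$sequences), 6)
  expect_equal(back$labels, rep(c("pop1", "pop2"), each = 3))
})

test_that("two_class_gaussians hits its analytic Bayes accuracy", {
  g <- two_class_gaussians(20000, 0.85, d = 8, seed = 4)
  # Bayes rule is known in closed form: midpoint hyperplane
  w <- rep(g$delta / sqrt(8), 8)
  s <- as.vector(g$x %*% w)
  thr <- sum(w * w / 2)
  bayes_pred <- ifelse(s > thr, "B", "A")
  expect_lt(abs(mean(bayes_pred == g$y) - 0.85), 0.01)
})
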