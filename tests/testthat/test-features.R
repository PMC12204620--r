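# song_features: syllable measurement, percent-overlap similarity,
# greedy typing, the 16-feature vector and its algebraic identities.

make_measure <- function(mask, row_offset = 1L) {
  attr(mask, "row_offset") <- row_offset
  structure(list(duration_ms = 10 * ncol(mask), f_upper_hz = 0,
                 f_lower_hz = 0, mask = mask),
            class = "syllable_measure")
}

test_that("syllable measurement recovers generator frequency bands", {
  spec_def <- tone_song_spec(2, 120, 60, f_low = c(4000, 6000), bw = 150)
  ch <- segment_chain(synthesize_song(spec_def, -55)$waveform)
  meas <- measure_syllables(ch$spec, ch$intervals, ch$masks)
  bin <- ch$spec$freq_axis[2] - ch$spec$freq_axis[1]
  # tone mainlobe spreads about +-2 bins around the band
  expect_lt(abs(meas[[1]]$f_lower_hz - 4000), 3 * bin)
  expect_lt(abs(meas[[1]]$f_upper_hz - 4150), 3 * bin)
  expect_lt(abs(meas[[2]]$f_lower_hz - 6000), 3 * bin)
  # identical masks give identical measures
  expect_equal(meas[[1]]$duration_ms,
               ch$intervals$offset_ms[1] - ch$intervals$onset_ms[1])
})

test_that("chirp band endpoints are recovered", {
  spec <- song_spec("A", -80, 40, 3,
                    data.frame(type_id = 0L, onset_ms = 150,
                               duration_ms = 250, f_low_hz = 3000,
                               f_high_hz = 8000, shape = "chirp"))
  ch <- segment_chain(synthesize_song(spec, -55)$waveform)
  m <- measure_syllables(ch$spec, ch$intervals, ch$masks)[[1]]
  expect_lt(abs(m$f_lower_hz - 3000), 300)
  expect_lt(abs(m$f_upper_hz - 8000), 300)
})

test_that("similarity follows the shared/mean-count formula", {
  base <- matrix(FALSE, 6, 8)
  base[2:4, 2:7] <- TRUE                       # 18 elements
  a <- make_measure(base)
  expect_equal(syllable_similarity(a, a), 100)

  # copy with half the elements deleted: 100 * (n/2) / (3n/4) = 66.67
  half <- base
  on <- which(half)
  half[on[seq(1, length(on), by = 2)]] <- FALSE
  b <- make_measure(half)
  expect_equal(syllable_similarity(a, b), 100 * 9 / 13.5, tolerance = 1e-9)
  # symmetric; min-normalizer config switch
  expect_equal(syllable_similarity(a, b), syllable_similarity(b, a))
  expect_equal(syllable_similarity(a, b, normalizer = "min"), 100)

  # disjoint frequency bands: zero overlap at every lag
  hi <- matrix(FALSE, 6, 8); hi[2:4, 2:7] <- TRUE
  c_m <- make_measure(hi, row_offset = 50L)
  expect_equal(syllable_similarity(a, c_m), 0)

  # time-shift invariance: the lag search recovers full overlap
  shifted <- cbind(matrix(FALSE, 6, 3), base)[, 1:8]
  expect_gt(syllable_similarity(a, make_measure(shifted)), 70)
})

test_that("greedy founder typing is deterministic with inclusive ties", {
  m1 <- matrix(FALSE, 10, 6); m1[2:4, 2:5] <- TRUE
  m2 <- matrix(FALSE, 10, 6); m2[7:9, 2:5] <- TRUE
  trill <- replicate(4, make_measure(m1), simplify = FALSE)
  # trill of identical syllables: one type
  expect_equal(assign_syllable_types(trill), rep(0L, 4))
  # distinct-band intro + identical trill: two types
  meas <- c(list(make_measure(m2)), trill)
  expect_equal(assign_syllable_types(meas), c(0L, rep(1L, 4)))
  # borderline exactly at threshold joins (>= is inclusive)
  half <- m1; on <- which(half)
  half[on[seq(1, length(on), 2)]] <- FALSE
  sim <- syllable_similarity(make_measure(m1), make_measure(half))
  p_exact <- typing_params(sim)
  expect_equal(assign_syllable_types(list(make_measure(m1),
                                          make_measure(half)), p_exact),
               c(0L, 0L))
  p_above <- typing_params(sim + 1e-6)
  expect_equal(assign_syllable_types(list(make_measure(m1),
                                          make_measure(half)), p_above),
               c(0L, 1L))
})

test_that("feature vector arithmetic matches its definitions", {
  iv <- data.frame(onset_ms = seq(0, 1800, by = 200),
                   offset_ms = seq(0, 1800, by = 200) + 100)
  m1 <- matrix(FALSE, 10, 4); m1[3:5, 2:3] <- TRUE
  m2 <- matrix(FALSE, 10, 4); m2[6:8, 2:3] <- TRUE
  meas <- lapply(rep(c(1, 2), 5), function(k) {
    m <- make_measure(if (k == 1) m1 else m2)
    m$f_lower_hz <- if (k == 1) 3000 else 5000
    m$f_upper_hz <- if (k == 1) 4000 else 6500
    m$duration_ms <- 100
    m
  })
  v <- compute_feature_vector(meas, types = rep(c(0L, 1L), 5), iv)
  expect_equal(unname(v["bout_duration_ms"]), 1900)
  expect_equal(unname(v["n_syllables"]), 10)
  expect_equal(unname(v["syllable_rate_per_ms"]), 10 / 1900)
  expect_equal(unname(v["syllable_repetition"]), 5)
  expect_equal(unname(v["overall_freq_range_hz"]), 6500 - 3000)
  expect_equal(unname(v["largest_syll_freq_range_hz"]), 1500)
  expect_equal(unname(v["smallest_syll_freq_range_hz"]), 1000)
  expect_equal(unname(v["avg_syll_freq_range_hz"]), 1250)
})

test_that("feature identities hold on pipeline-computed songs", {
  feats <- small_population_features(n = 25, seed = 31)
  expect_gt(nrow(feats), 20)
  expect_equal(feats$syllable_repetition * feats$n_unique_syllables,
               feats$n_syllables, tolerance = 1e-9)
  expect_equal(feats$overall_freq_range_hz,
               feats$max_freq_hz - feats$min_freq_hz, tolerance = 1e-9)
  expect_true(all(feats$smallest_syll_freq_range_hz <=
                    feats$avg_syll_freq_range_hz + 1e-9))
  expect_true(all(feats$avg_syll_freq_range_hz <=
                    feats$largest_syll_freq_range_hz + 1e-9))
  expect_true(all(feats$n_unique_syllables <= feats$n_syllables))
})

test_that("log transform validates positivity and inverts cleanly", {
  x <- matrix(c(1, exp(1), 2, 4), 2, 2,
              dimnames = list(NULL, c("a", "b")))
  lx <- log_transform_features(x)
  expect_equal(unname(lx[1, "a"]), 0)
  expect_equal(unname(lx[2, "a"]), 1)
  expect_equal(exp(lx), x)
  x[1, 2] <- -5
  expect_error(log_transform_features(x), "b")
})
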