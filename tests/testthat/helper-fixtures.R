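# Fixture builders shared across the suite.  Everything is generated in
# code; no binary fixtures are stored.

# A simple bout of constant tones: n syllables of `dur_ms` separated by
# `gap_ms`, in distinct frequency bands.
tone_song_spec <- function(n = 3, dur_ms = 100, gap_ms = 50,
                           f_low = seq(3000, by = 1000, length.out = n),
                           bw = 200, seed = 7, species = "A") {
  onsets <- 150 + (seq_len(n) - 1) * (dur_ms + gap_ms)
  song_spec(species, -80, 40, seed,
            data.frame(type_id = seq_len(n) - 1L, onset_ms = onsets,
                       duration_ms = dur_ms, f_low_hz = f_low,
                       f_high_hz = f_low + bw, shape = "tone"))
}

# Segment + noise-filter one waveform with given params.
segment_chain <- function(waveform, seg = segmentation_params(),
                          sp = spectrogram_params()) {
  spec <- compute_spectrogram(waveform, sp)
  iv <- segment_syllables(spec, seg)
  fl <- filter_noise_components(spec, iv, seg)
  list(spec = spec, intervals = fl$intervals, masks = fl$masks)
}

# One-to-one interval matching at >= 50% overlap; returns matched count
# and spurious count.
match_intervals <- function(truth, found) {
  used <- rep(FALSE, nrow(found))
  matched <- 0L
  for (k in seq_len(nrow(truth))) {
    best <- 0; bi <- 0L
    for (j in seq_len(nrow(found))) {
      if (used[j]) next
      ov <- min(truth$offset_ms[k], found$offset_ms[j]) -
        max(truth$onset_ms[k], found$onset_ms[j])
      len <- max(truth$offset_ms[k] - truth$onset_ms[k],
                 found$offset_ms[j] - found$onset_ms[j])
      if (ov / len > best) { best <- ov / len; bi <- j }
    }
    if (best >= 0.5) { used[bi] <- TRUE; matched <- matched + 1L }
  }
  list(matched = matched, spurious = sum(!used))
}

# Small synthetic feature table with geography for split/stat tests.
toy_feature_table <- function(n = 60, seed = 1) {
  set.seed(seed)
  lon <- runif(n, -120, -70)
  species <- ifelse(lon < -96.5, "B", "A")
  x <- matrix(rexp(n * 16, rate = 0.01) + 1, n, 16)
  colnames(x) <- song_feature_names()
  cbind(data.frame(id = sprintf("s%03d", 1:n)), as.data.frame(x),
        data.frame(species = species, longitude = lon,
                   latitude = runif(n, 30, 48),
                   conversion_status = sample(c("converted",
                                                "unconverted"), n, TRUE)))
}

# Run the full pipeline from waveforms to a feature table for a small
# default population; memoised per test file via options.
small_population_features <- function(n = 40, seed = 11) {
  pop <- sample_population(population_model(n_recordings = n), seed)
  waves <- lapply(pop$specs,
                  function(s) synthesize_song(s, -50)$waveform)
  song_feature_table(waves, pop$metadata)
}

# Naive AMOVA oracle: explicit loops over the definitional sums of
# squares, independent of the package's vectorized path.
amova_oracle <- function(d, labels) {
  labels <- as.character(labels)
  n <- length(labels)
  pops <- unique(labels)
  k <- length(pops)
  ss_total <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) ss_total <- ss_total +
      d[i, j]^2
  ss_total <- ss_total / n
  ss_within <- 0
  for (p in pops) {
    rows <- which(labels == p)
    if (length(rows) < 2) next
    s <- 0
    for (i in rows) for (j in rows) if (j > i) s <- s + d[i, j]^2
    ss_within <- ss_within + s / length(rows)
  }
  ss_among <- ss_total - ss_within
  sizes <- table(labels)
  n0 <- (n - sum(sizes^2) / n) / (k - 1)
  ms_within <- ss_within / (n - k)
  sigma_a <- (ss_among / (k - 1) - ms_within) / n0
  list(ss_among = ss_among, ss_within = ss_within,
       sigma_among = sigma_a, sigma_within = ms_within,
       phi = sigma_a / (sigma_a + ms_within))
}

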