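# Syllable measurements, syllable typing by percent time-frequency overlap,
# and the sixteen per-bout song features that every downstream statistical
# and machine-learning stage consumes.

#' Names of the sixteen song features, in canonical order
#' @export
song_feature_names <- function() {
  c("bout_duration_ms", "n_syllables", "syllable_rate_per_ms",
    "smallest_syllable_ms", "largest_syllable_ms", "mean_syllable_ms",
    "n_unique_syllables", "syllable_repetition",
    "avg_upper_freq_hz", "avg_lower_freq_hz", "max_freq_hz", "min_freq_hz",
    "overall_freq_range_hz", "largest_syll_freq_range_hz",
    "smallest_syll_freq_range_hz", "avg_syll_freq_range_hz")
}

#' Measure duration and frequency bounds of segmented syllables
#'
#' Duration is `offset - onset`; the frequency bounds are the highest and
#' lowest frequency-bin centers containing retained mask elements within
#' the interval.  For the bounds (only), mask elements more than `rel_db`
#' below the syllable's own power maximum are ignored: a noise-referenced
#' global threshold would otherwise report the spectral-leakage skirt of
#' narrowband syllables rather than their band edges.
#'
#' @param spec a [compute_spectrogram()] result (supplies the frequency
#'   axis and per-element power).
#' @param intervals data frame from [filter_noise_components()].
#' @param masks retained-element masks from [filter_noise_components()].
#' @param rel_db per-syllable dynamic range (dB) for the frequency bounds.
#' @return list of `syllable_measure` objects: `duration_ms`,
#'   `f_upper_hz`, `f_lower_hz`, `mask`.
#' @export
measure_syllables <- function(spec, intervals, masks, rel_db = 35) {
  stopifnot(nrow(intervals) == length(masks))
  lapply(seq_len(nrow(intervals)), function(i) {
    m <- masks[[i]]
    if (sum(m) == 0) stop_fmt("measure_syllables: empty mask at syllable %d",
                              i)
    freq <- attr(m, "freq_axis") %||% spec$freq_axis
    strong <- m & spec$power >= max(spec$power[m]) - rel_db
    rows_on <- which(rowSums(strong) > 0)
    structure(list(duration_ms = intervals$offset_ms[i] -
                     intervals$onset_ms[i],
                   f_upper_hz = freq[max(rows_on)],
                   f_lower_hz = freq[min(rows_on)],
                   mask = trim_mask(m)),
              class = "syllable_measure")
  })
}

# drop empty rows/columns so similarity lags are over the occupied extent
trim_mask <- function(m) {
  rows <- which(rowSums(m) > 0)
  cols <- which(colSums(m) > 0)
  out <- m[min(rows):max(rows), min(cols):max(cols), drop = FALSE]
  attr(out, "row_offset") <- min(rows)
  out
}

#' Percent time-frequency overlap between two syllables
#'
#' The two binary masks are aligned at every integer time lag with the
#' frequency rows fixed in absolute position; the similarity is 100 times
#' the maximum over lags of the shared on-element count divided by the mean
#' of the two element counts.  Symmetric; identical masks score 100.
#'
#' @param a,b `syllable_measure` objects (or bare logical matrices with a
#'   `row_offset` attribute).
#' @param normalizer denominator for the shared count: `"mean"` (default)
#'   or `"min"` of the two element counts.
#' @return similarity percent in \[0, 100\].
#' @export
syllable_similarity <- function(a, b, normalizer = c("mean", "min")) {
  normalizer <- match.arg(normalizer)
  ma <- if (inherits(a, "syllable_measure")) a$mask else a
  mb <- if (inherits(b, "syllable_measure")) b$mask else b
  na <- sum(ma); nb <- sum(mb)
  if (na == 0 || nb == 0) stop_fmt("syllable_similarity: empty mask")
  # place both masks on a common frequency grid
  ra <- attr(ma, "row_offset") %||% 1L
  rb <- attr(mb, "row_offset") %||% 1L
  r0 <- min(ra, rb)
  nr <- max(ra + nrow(ma), rb + nrow(mb)) - r0
  pa <- matrix(FALSE, nr, ncol(ma))
  pa[(ra - r0 + 1):(ra - r0 + nrow(ma)), ] <- ma
  pb <- matrix(FALSE, nr, ncol(mb))
  pb[(rb - r0 + 1):(rb - r0 + nrow(mb)), ] <- mb

  best <- 0
  for (lag in seq(-(ncol(pb) - 1L), ncol(pa) - 1L)) {
    ca <- max(1L, 1L + lag):min(ncol(pa), ncol(pb) + lag)
    cb <- ca - lag
    shared <- sum(pa[, ca, drop = FALSE] & pb[, cb, drop = FALSE])
    if (shared > best) best <- shared
  }
  100 * best / if (normalizer == "mean") mean(c(na, nb)) else min(na, nb)
}

#' Syllable-typing parameters
#'
#' @param similarity_threshold_percent minimum percent overlap for two
#'   syllables to be the same type.  Corpus-calibrated species defaults:
#'   26.6 (western, B), 25.5 (eastern, A), 25.0 (hybrid/unsure and
#'   fallback); see [similarity_threshold_for_species()].
#' @return list of class `typing_params`.
#' @export
typing_params <- function(similarity_threshold_percent = 25.0) {
  if (similarity_threshold_percent <= 0 ||
      similarity_threshold_percent >= 100)
    stop_fmt("typing_params: threshold must be in (0, 100)")
  structure(list(similarity_threshold_percent =
                   similarity_threshold_percent),
            class = "typing_params")
}

#' @rdname typing_params
#' @param species species label (`"A"`, `"B"`, or other).
#' @export
similarity_threshold_for_species <- function(species) {
  switch(as.character(species), B = 26.6, A = 25.5, 25.0)
}

#' Assign syllable types by greedy founder matching
#'
#' The first syllable founds type 0; each subsequent syllable joins the
#' earliest-founded type whose founder it overlaps at or above the
#' threshold (inclusive), otherwise it founds a new type.  Deterministic
#' and stable under the bout's natural syllable order.
#'
#' @param measures list from [measure_syllables()].
#' @param p a [typing_params()].
#' @return integer vector of dense type labels starting at 0.
#' @export
assign_syllable_types <- function(measures, p = typing_params()) {
  n <- length(measures)
  if (n == 0) stop_fmt("assign_syllable_types: no syllables")
  types <- integer(n)
  founders <- 1L                     # indices of type founders, in order
  for (i in seq_len(n)[-1]) {
    assigned <- FALSE
    for (t in seq_along(founders)) {
      if (syllable_similarity(measures[[founders[t]]], measures[[i]]) >=
          p$similarity_threshold_percent) {
        types[i] <- t - 1L
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      founders <- c(founders, i)
      types[i] <- length(founders) - 1L
    }
  }
  types
}

#' Compute the sixteen-feature song vector
#'
#' Bout duration is last offset minus first onset; the rate of syllable
#' production is syllables per ms of bout; the degree of syllable
#' repetition is syllables per unique syllable; overall frequency range is
#' the overall maximum syllable frequency minus the overall minimum; the
#' per-syllable ranges feed the largest/smallest/average range features.
#'
#' @param measures list from [measure_syllables()].
#' @param types integer labels from [assign_syllable_types()].
#' @param intervals the intervals the measures were taken from (for onsets).
#' @return named numeric vector over [song_feature_names()].
#' @export
compute_feature_vector <- function(measures, types, intervals) {
  n <- length(measures)
  if (n == 0) stop_fmt("compute_feature_vector: no syllables")
  stopifnot(length(types) == n, nrow(intervals) == n)
  dur <- vapply(measures, `[[`, numeric(1), "duration_ms")
  fup <- vapply(measures, `[[`, numeric(1), "f_upper_hz")
  flo <- vapply(measures, `[[`, numeric(1), "f_lower_hz")
  rng <- fup - flo
  bout <- max(intervals$offset_ms) - min(intervals$onset_ms)
  n_unique <- length(unique(types))
  c(bout_duration_ms = bout,
    n_syllables = n,
    syllable_rate_per_ms = n / bout,
    smallest_syllable_ms = min(dur),
    largest_syllable_ms = max(dur),
    mean_syllable_ms = mean(dur),
    n_unique_syllables = n_unique,
    syllable_repetition = n / n_unique,
    avg_upper_freq_hz = mean(fup),
    avg_lower_freq_hz = mean(flo),
    max_freq_hz = max(fup),
    min_freq_hz = min(flo),
    overall_freq_range_hz = max(fup) - min(flo),
    largest_syll_freq_range_hz = max(rng),
    smallest_syll_freq_range_hz = min(rng),
    avg_syll_freq_range_hz = mean(rng))
}

#' Natural-log transform a feature table
#'
#' @param vectors matrix or data frame of positive feature values.
#' @return object of the same shape, element-wise `log`.
#' @export
log_transform_features <- function(vectors) {
  num <- as.matrix(vectors)
  bad <- which(colSums(num <= 0 | !is.finite(num)) > 0)
  if (length(bad))
    stop_fmt("log_transform_features: non-positive values in feature(s): %s",
             paste(colnames(num)[bad], collapse = ", "))
  out <- log(num)
  if (is.data.frame(vectors)) out <- as.data.frame(out)
  out
}

#' Run the full segmentation-to-features chain over recordings
#'
#' Segments each waveform, filters noise components with the per-species
#' element threshold, types syllables with the per-species similarity
#' threshold, and assembles one feature row per song.  Songs whose every
#' syllable is discarded by the noise filter are excluded and reported in
#' the `excluded` attribute.
#'
#' @param waveforms list of numeric waveforms at 44,100 Hz.
#' @param metadata data frame with columns `id`, `species`, `latitude`,
#'   `longitude`, `conversion_status` (one row per waveform).
#' @param sp spectrogram parameters.
#' @param seg segmentation parameters; the per-species
#'   `noise_element_threshold` is substituted unless `per_species = FALSE`.
#' @param per_species use species-specific noise/similarity thresholds.
#' @return data frame: `id`, the 16 features, `species`, `longitude`,
#'   `latitude`, `conversion_status`; excluded ids in `attr(, "excluded")`.
#' @export
song_feature_table <- function(waveforms, metadata,
                               sp = spectrogram_params(),
                               seg = segmentation_params(),
                               per_species = TRUE) {
  stopifnot(length(waveforms) == nrow(metadata))
  rows <- vector("list", length(waveforms))
  excluded <- character(0)
  for (i in seq_along(waveforms)) {
    species <- metadata$species[i]
    p <- seg
    thr <- typing_params()
    if (per_species) {
      p$noise_element_threshold <- noise_threshold_for_species(species)
      thr <- typing_params(similarity_threshold_for_species(species))
    }
    spec <- compute_spectrogram(waveforms[[i]], sp)
    iv <- segment_syllables(spec, p)
    if (nrow(iv) == 0) { excluded <- c(excluded, metadata$id[i]); next }
    fl <- filter_noise_components(spec, iv, p)
    if (nrow(fl$intervals) == 0) {
      excluded <- c(excluded, metadata$id[i]); next
    }
    meas <- measure_syllables(spec, fl$intervals, fl$masks)
    types <- assign_syllable_types(meas, thr)
    feats <- compute_feature_vector(meas, types, fl$intervals)
    rows[[i]] <- cbind(data.frame(id = metadata$id[i]),
                       as.data.frame(t(feats)),
                       data.frame(species = species,
                                  longitude = metadata$longitude[i],
                                  latitude = metadata$latitude[i],
                                  conversion_status =
                                    metadata$conversion_status[i]))
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) out <- data.frame()
  attr(out, "excluded") <- excluded
  out
}
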