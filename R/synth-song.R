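# Synthetic towhee-like song generator.  Every downstream stage (segmentation,
# feature measurement, geography, classification) is tested against recordings
# produced here, where the syllable intervals, frequency bands and species
# parameters are known exactly.

#' Species song-parameter profile
#'
#' Describes the distribution of song parameters for one species: how many
#' short introductory notes precede the trill, how fast the trill is, the
#' frequency band, and how those means drift with longitude (the cline).
#'
#' @param label species id, e.g. `"A"` (eastern) or `"B"` (western).
#' @param intro_count_range integer range (min, max) of introductory notes.
#' @param trill_count_range integer range of trill repetitions.
#' @param trill_syllable_ms,trill_gap_ms `c(mean, sd)` in milliseconds.
#' @param f_low_hz,f_high_hz `c(mean, sd)` of the trill band edges in Hz.
#' @param n_types mean number of distinct syllable types per song (intro
#'   notes are each their own type; the trill adds one more).
#' @param cline_slope named numeric vector: per-degree-longitude shift applied
#'   to the means of `trill_syllable_ms`, `trill_gap_ms`, `f_low_hz`,
#'   `f_high_hz` relative to `ref_lon`.
#' @param ref_lon reference longitude at which the profile means apply.
#' @param single_syllable_trill_prob probability that the trill fuses into a
#'   single unbroken syllable (observed in fast western trills).
#' @return an object of class `species_profile`.
#' @export
species_profile <- function(label,
                            intro_count_range,
                            trill_count_range,
                            trill_syllable_ms,
                            trill_gap_ms,
                            f_low_hz,
                            f_high_hz,
                            n_types = mean(intro_count_range) + 1,
                            cline_slope = c(trill_syllable_ms = 0,
                                            trill_gap_ms = 0,
                                            f_low_hz = 0, f_high_hz = 0),
                            ref_lon = -96.5,
                            single_syllable_trill_prob = 0) {
  p <- list(label = label,
            intro_count_range = as.integer(intro_count_range),
            trill_count_range = as.integer(trill_count_range),
            trill_syllable_ms = trill_syllable_ms,
            trill_gap_ms = trill_gap_ms,
            f_low_hz = f_low_hz, f_high_hz = f_high_hz,
            n_types = n_types,
            cline_slope = cline_slope, ref_lon = ref_lon,
            single_syllable_trill_prob = single_syllable_trill_prob)
  stopifnot(p$f_low_hz[1] > 0, p$f_low_hz[1] < p$f_high_hz[1],
            p$f_high_hz[1] < 22050,
            p$trill_syllable_ms[1] > 0, p$trill_gap_ms[1] > 0,
            single_syllable_trill_prob >= 0, single_syllable_trill_prob <= 1)
  structure(p, class = "species_profile")
}

#' Two-species population model with a longitudinal contact zone
#'
#' The default emulates the corpus structure of the towhee analysis: a
#' western species B and an eastern species A whose ranges meet in a zone of
#' co-occurrence (default 102W--91W), with species membership drawn by
#' longitude, feature means drifting along per-species clines that converge
#' toward the zone, and a small fraction of parameter-midpoint "hybrid"
#' songs inside the zone.
#'
#' @param profile_a,profile_b [species_profile()]s for the eastern (A) and
#'   western (B) species.
#' @param range_a,range_b longitude intervals occupied by each species
#'   (degrees, west negative).
#' @param overlap_zone `c(west, east)` longitude bounds of the contact zone.
#' @param hybrid_fraction probability that an in-zone song is a hybrid
#'   (parameter-midpoint) song; default 0.025 matches the in-zone sighting
#'   estimate of roughly 2.3--2.6%.
#' @param n_recordings default number of recordings drawn by
#'   [sample_population()].
#' @param noise_floor_db additive white-noise level relative to peak syllable
#'   amplitude, in dB (negative).
#' @param off_season_fraction fraction of recording dates drawn outside the
#'   April--August breeding season (default 0: all in season).
#' @return an object of class `population_model`.
#' @export
population_model <- function(profile_a = default_profile_a(),
                             profile_b = default_profile_b(),
                             range_a = c(-102, -67),
                             range_b = c(-125, -91),
                             overlap_zone = c(-102, -91),
                             hybrid_fraction = 0.025,
                             n_recordings = 200L,
                             noise_floor_db = -50,
                             off_season_fraction = 0) {
  m <- list(profile_a = profile_a, profile_b = profile_b,
            range_a = range_a, range_b = range_b,
            overlap_zone = overlap_zone,
            hybrid_fraction = hybrid_fraction,
            n_recordings = as.integer(n_recordings),
            noise_floor_db = noise_floor_db,
            off_season_fraction = off_season_fraction)
  stopifnot(overlap_zone[1] < overlap_zone[2],
            overlap_zone[1] >= min(range_a[1], range_b[1]),
            overlap_zone[2] <= max(range_a[2], range_b[2]),
            hybrid_fraction >= 0, hybrid_fraction <= 1,
            noise_floor_db < 0,
            off_season_fraction >= 0, off_season_fraction <= 1)
  structure(m, class = "population_model")
}

#' @rdname population_model
#' @export
default_profile_a <- function() {
  species_profile("A",
                  intro_count_range = c(2L, 4L),
                  trill_count_range = c(5L, 9L),
                  trill_syllable_ms = c(60, 8),
                  trill_gap_ms = c(45, 6),
                  f_low_hz = c(2800, 220),
                  f_high_hz = c(5800, 320),
                  cline_slope = c(trill_syllable_ms = 0.8, trill_gap_ms = 0.3,
                                  f_low_hz = 12, f_high_hz = -20),
                  ref_lon = -84.5,
                  single_syllable_trill_prob = 0)
}

#' @rdname population_model
#' @export
default_profile_b <- function() {
  species_profile("B",
                  intro_count_range = c(0L, 2L),
                  trill_count_range = c(8L, 14L),
                  trill_syllable_ms = c(40, 6),
                  trill_gap_ms = c(30, 5),
                  f_low_hz = c(3300, 220),
                  f_high_hz = c(6800, 320),
                  cline_slope = c(trill_syllable_ms = 0.4, trill_gap_ms = 0.25,
                                  f_low_hz = -10, f_high_hz = -25),
                  ref_lon = -108,
                  single_syllable_trill_prob = 0.15)
}

# Profile with means shifted along the species cline to a given longitude.
shift_profile <- function(profile, lon) {
  d <- lon - profile$ref_lon
  for (nm in names(profile$cline_slope)) {
    profile[[nm]][1] <- profile[[nm]][1] + profile$cline_slope[[nm]] * d
  }
  profile
}

# Parameter-midpoint profile for hybrid / intermediate songs.
midpoint_profile <- function(a, b) {
  mid <- function(x, y) (x + y) / 2
  species_profile("hybrid_unsure",
    intro_count_range = as.integer(round(mid(a$intro_count_range,
                                             b$intro_count_range))),
    trill_count_range = as.integer(round(mid(a$trill_count_range,
                                             b$trill_count_range))),
    trill_syllable_ms = mid(a$trill_syllable_ms, b$trill_syllable_ms),
    trill_gap_ms = mid(a$trill_gap_ms, b$trill_gap_ms),
    f_low_hz = mid(a$f_low_hz, b$f_low_hz),
    f_high_hz = mid(a$f_high_hz, b$f_high_hz),
    cline_slope = c(trill_syllable_ms = 0, trill_gap_ms = 0,
                    f_low_hz = 0, f_high_hz = 0),
    single_syllable_trill_prob = mid(a$single_syllable_trill_prob,
                                     b$single_syllable_trill_prob))
}

#' Construct a song plan (syllable-level ground truth)
#'
#' @param species species label.
#' @param longitude,latitude recording coordinates (degrees, west negative).
#' @param seed integer seed controlling the noise realization when the plan
#'   is rendered.
#' @param syllables data frame with columns `type_id`, `onset_ms`,
#'   `duration_ms`, `f_low_hz`, `f_high_hz`, `shape` (`"tone"` or `"chirp"`).
#' @param duration_ms total bout duration; defaults to last offset + 150 ms.
#' @return an object of class `song_spec`.
#' @export
song_spec <- function(species, longitude, latitude, seed, syllables,
                      duration_ms = NULL) {
  stopifnot(is.data.frame(syllables), nrow(syllables) >= 1)
  req <- c("type_id", "onset_ms", "duration_ms", "f_low_hz", "f_high_hz",
           "shape")
  if (!all(req %in% names(syllables)))
    stop_fmt("song_spec: syllables must have columns %s",
             paste(req, collapse = ", "))
  s <- syllables[order(syllables$onset_ms), , drop = FALSE]
  offs <- s$onset_ms + s$duration_ms
  if (any(diff(s$onset_ms) <= 0))
    stop_fmt("song_spec: syllable onsets must be strictly increasing")
  if (nrow(s) > 1 && any(s$onset_ms[-1] < offs[-nrow(s)]))
    stop_fmt("song_spec: syllable intervals overlap")
  ids <- as.integer(sort(unique(s$type_id)))
  if (!identical(ids, seq_along(ids) - 1L))
    stop_fmt("song_spec: type ids must be dense from 0")
  if (any(s$f_low_hz <= 0) || any(s$f_low_hz >= s$f_high_hz) ||
      any(s$f_high_hz >= 22050))
    stop_fmt("song_spec: need 0 < f_low < f_high < 22050")
  if (!all(s$shape %in% c("tone", "chirp")))
    stop_fmt("song_spec: shape must be 'tone' or 'chirp'")
  if (is.null(duration_ms)) duration_ms <- max(offs) + 150
  if (duration_ms < max(offs))
    stop_fmt("song_spec: syllables extend past requested bout duration")
  structure(list(species = species, longitude = longitude,
                 latitude = latitude, seed = as.integer(seed),
                 syllables = s, duration_ms = duration_ms),
            class = "song_spec")
}

# Draw one song plan from a (cline-shifted) profile.  Assumes the caller has
# set the RNG state; layout: 150 ms lead-in, intro notes, then the trill.
plan_song <- function(profile, species, longitude, latitude, seed) {
  rpos <- function(ms, minimum) max(minimum, rnorm(1, ms[1], ms[2]))
  n_intro <- if (profile$intro_count_range[2] > profile$intro_count_range[1])
    sample(profile$intro_count_range[1]:profile$intro_count_range[2], 1)
  else profile$intro_count_range[1]
  n_trill <- sample(profile$trill_count_range[1]:profile$trill_count_range[2],
                    1)

  rows <- list()
  t_ms <- 150
  for (i in seq_len(n_intro)) {
    dur <- rpos(c(90, 15), 40)
    ctr <- rnorm(1, (profile$f_low_hz[1] + profile$f_high_hz[1]) / 2, 500)
    bw <- max(400, rnorm(1, 1200, 250))
    f_lo <- max(600, ctr - bw / 2)
    f_hi <- min(20000, max(f_lo + 300, ctr + bw / 2))
    rows[[length(rows) + 1]] <- data.frame(
      type_id = i - 1L, onset_ms = t_ms, duration_ms = dur,
      f_low_hz = f_lo, f_high_hz = f_hi,
      shape = if (runif(1) < 0.5) "tone" else "chirp")
    t_ms <- t_ms + dur + rpos(c(80, 15), 30)
  }

  # floors keep trill structure resolvable by the analysis window
  syl <- rpos(profile$trill_syllable_ms, 20)
  gap <- rpos(profile$trill_gap_ms, 25)
  f_lo <- max(600, rnorm(1, profile$f_low_hz[1], profile$f_low_hz[2]))
  f_hi <- max(f_lo + 500,
              min(20000, rnorm(1, profile$f_high_hz[1], profile$f_high_hz[2])))
  trill_type <- n_intro
  if (runif(1) < profile$single_syllable_trill_prob) {
    # fused trill: one unbroken syllable spanning the whole trill
    rows[[length(rows) + 1]] <- data.frame(
      type_id = trill_type, onset_ms = t_ms,
      duration_ms = n_trill * syl + (n_trill - 1) * gap,
      f_low_hz = f_lo, f_high_hz = f_hi, shape = "chirp")
  } else {
    for (i in seq_len(n_trill)) {
      rows[[length(rows) + 1]] <- data.frame(
        type_id = trill_type, onset_ms = t_ms, duration_ms = syl,
        f_low_hz = f_lo, f_high_hz = f_hi, shape = "chirp")
      t_ms <- t_ms + syl + gap
    }
  }
  song_spec(species, longitude, latitude, seed, do.call(rbind, rows))
}

#' Render a song plan into a waveform
#'
#' Each planned syllable becomes a Hann-windowed constant tone (at the band
#' midpoint) or a linear chirp sweeping `f_low` to `f_high`; the rest of the
#' bout is silence plus additive white noise at `noise_floor_db` relative to
#' peak syllable amplitude.  The waveform is peak-normalized to 0.9.
#' Rendering is deterministic given the plan's seed.
#'
#' @param spec a [song_spec()].
#' @param noise_floor_db noise level in dB relative to the syllable peak.
#' @param metadata optional geographic metadata row carried along.
#' @return an object of class `synthetic_recording`: list with `waveform`,
#'   `sample_rate` (44100), `truth` (the plan) and `metadata`.
#' @export
synthesize_song <- function(spec, noise_floor_db = -50, metadata = NULL) {
  stopifnot(inherits(spec, "song_spec"), noise_floor_db < 0)
  fs <- 44100
  n <- ceiling(spec$duration_ms / 1000 * fs)
  wave <- numeric(n)
  for (i in seq_len(nrow(spec$syllables))) {
    s <- spec$syllables[i, ]
    i0 <- floor(s$onset_ms / 1000 * fs) + 1
    ns <- round(s$duration_ms / 1000 * fs)
    if (i0 + ns - 1 > n)
      stop_fmt("synthesize_song: syllable %d extends past bout duration", i)
    t <- (seq_len(ns) - 1) / fs
    phase <- if (s$shape == "tone") {
      2 * pi * ((s$f_low_hz + s$f_high_hz) / 2) * t
    } else {
      2 * pi * (s$f_low_hz * t +
                  (s$f_high_hz - s$f_low_hz) / (2 * s$duration_ms / 1000) *
                  t^2)
    }
    hann <- 0.5 * (1 - cos(2 * pi * seq(0, 1, length.out = ns)))
    wave[i0:(i0 + ns - 1)] <- wave[i0:(i0 + ns - 1)] + sin(phase) * hann
  }
  peak <- max(abs(wave))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(spec$seed)
  wave <- wave + rnorm(n, 0, peak * 10^(noise_floor_db / 20))
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  wave <- wave / max(abs(wave)) * 0.9
  structure(list(waveform = wave, sample_rate = fs, truth = spec,
                 metadata = metadata),
            class = "synthetic_recording")
}

#' Draw a geographically structured sample of song plans
#'
#' Longitude is uniform over the union of the two ranges; species west of the
#' overlap zone are pure B, east of it pure A, and inside the zone membership
#' is a longitude-linear mixture with a `hybrid_fraction` chance of a
#' parameter-midpoint hybrid song.  Profile means are shifted along each
#' species' cline before the plan is drawn.
#'
#' @param model a [population_model()].
#' @param seed integer seed.
#' @param plan_songs also draw per-song syllable plans (default TRUE);
#'   `FALSE` returns metadata only (`specs = NULL`), which is much faster
#'   for corpus-scale geographic sampling.  The metadata is identical
#'   either way.
#' @return list with `specs` (list of [song_spec()]) and `metadata`
#'   (data frame: id, species, date, latitude, longitude, recordist,
#'   conversion_status).
#' @export
sample_population <- function(model, seed, plan_songs = TRUE) {
  stopifnot(inherits(model, "population_model"))
  n <- model$n_recordings
  if (n <= 0) stop_fmt("sample_population: n_recordings must be positive")
  set.seed(seed)
  zone <- model$overlap_zone
  lon_min <- min(model$range_a[1], model$range_b[1])
  lon_max <- max(model$range_a[2], model$range_b[2])

  lon <- runif(n, lon_min, lon_max)
  lat <- runif(n, 30, 48)
  species <- character(n)
  for (i in seq_len(n)) {
    if (lon[i] < zone[1]) species[i] <- "B"
    else if (lon[i] >= zone[2]) species[i] <- "A"
    else if (runif(1) < model$hybrid_fraction) species[i] <- "hybrid_unsure"
    else {
      p_a <- (lon[i] - zone[1]) / (zone[2] - zone[1])
      species[i] <- if (runif(1) < p_a) "A" else "B"
    }
  }

  dates <- draw_dates(n, model$off_season_fraction)
  recordist <- sprintf("obs%03d", sample.int(max(3L, n %/% 4L), n,
                                             replace = TRUE))
  # western (mp3-heavy) recordings are more often format/rate converted
  p_conv <- ifelse(species == "B", 0.65, ifelse(species == "A", 0.35, 0.5))
  conversion <- ifelse(runif(n) < p_conv, "converted", "unconverted")

  song_seeds <- sample.int(2147483646L, n)
  specs <- if (plan_songs) vector("list", n) else NULL
  for (i in if (plan_songs) seq_len(n) else integer(0)) {
    prof <- switch(species[i],
      A = shift_profile(model$profile_a, lon[i]),
      B = shift_profile(model$profile_b, lon[i]),
      hybrid_unsure = midpoint_profile(shift_profile(model$profile_a, lon[i]),
                                       shift_profile(model$profile_b, lon[i])))
    specs[[i]] <- plan_song(prof, species[i], lon[i], lat[i], song_seeds[i])
  }
  metadata <- data.frame(id = sprintf("rec%05d", seq_len(n)),
                         species = species, date = dates,
                         latitude = lat, longitude = lon,
                         recordist = recordist,
                         conversion_status = conversion,
                         stringsAsFactors = FALSE)
  list(specs = specs, metadata = metadata)
}

# ISO-8601 dates, uniform over April-August (breeding season) with an
# optional off-season fraction spread over the remaining months.
draw_dates <- function(n, off_season_fraction) {
  year <- sample(2015:2023, n, replace = TRUE)
  in_season <- runif(n) >= off_season_fraction
  month <- ifelse(in_season, sample(4:8, n, replace = TRUE),
                  sample(c(1:3, 9:12), n, replace = TRUE))
  day <- sample(1:28, n, replace = TRUE)
  sprintf("%04d-%02d-%02d", year, month, day)
}

#' Generate a dataset of WAV files, metadata and truth annotations
#'
#' @param model a [population_model()].
#' @param n number of recordings (overrides `model$n_recordings`).
#' @param seed integer seed.
#' @param out_dir writable output directory (created if missing).
#' @return the metadata data frame (one row per recording, with `wav_path`
#'   and `truth_path` columns), invisibly; files are written to `out_dir`
#'   plus a `metadata.csv`.
#' @export
generate_dataset <- function(model, n = model$n_recordings, seed, out_dir) {
  model$n_recordings <- as.integer(n)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir))
    stop_fmt("generate_dataset: cannot create directory '%s'", out_dir)
  pop <- sample_population(model, seed)
  meta <- pop$metadata
  meta$wav_path <- file.path(out_dir, paste0(meta$id, ".wav"))
  meta$truth_path <- file.path(out_dir, paste0(meta$id, "_truth.json"))
  for (i in seq_len(nrow(meta))) {
    rec <- synthesize_song(pop$specs[[i]], model$noise_floor_db,
                           metadata = meta[i, ])
    write_wav(rec$waveform, meta$wav_path[i])
    s <- pop$specs[[i]]$syllables
    jsonlite::write_json(
      list(syllables = data.frame(onset_ms = s$onset_ms,
                                  offset_ms = s$onset_ms + s$duration_ms,
                                  f_low = s$f_low_hz, f_high = s$f_high_hz,
                                  type_id = s$type_id),
           duration_ms = pop$specs[[i]]$duration_ms,
           seed = pop$specs[[i]]$seed),
      meta$truth_path[i], auto_unbox = TRUE, digits = NA)
  }
  write.csv(meta, file.path(out_dir, "metadata.csv"), row.names = FALSE)
  invisible(meta)
}

#' Two-population haploid sequence model
#'
#' Synthetic stand-in for a small mitochondrial barcode alignment: two
#' populations descend from one random ancestor; `fixed_diffs` sites carry a
#' substitution fixed in all of population 2, and each individual
#' independently mutates each site with probability `within_poly_rate`.
#'
#' @param n_per_pop `c(n1, n2)` sequences per population.
#' @param seq_length alignment length in sites.
#' @param fixed_diffs number of between-population fixed differences.
#' @param within_poly_rate per-site, per-individual mutation probability.
#' @param seed integer seed.
#' @return object of class `genetic_model`.
#' @export
genetic_model <- function(n_per_pop = c(18L, 5L), seq_length = 650L,
                          fixed_diffs = 20L, within_poly_rate = 0.003,
                          seed = 1L) {
  stopifnot(length(n_per_pop) == 2, all(n_per_pop >= 1),
            fixed_diffs >= 0, within_poly_rate >= 0, within_poly_rate <= 1)
  if (fixed_diffs > seq_length)
    stop_fmt("genetic_model: fixed_diffs (%d) exceeds seq_length (%d)",
             fixed_diffs, seq_length)
  structure(list(n_per_pop = as.integer(n_per_pop),
                 seq_length = as.integer(seq_length),
                 fixed_diffs = as.integer(fixed_diffs),
                 within_poly_rate = within_poly_rate,
                 seed = as.integer(seed)),
            class = "genetic_model")
}

#' Generate a two-population alignment with known differentiation
#'
#' @param gm a [genetic_model()].
#' @param fasta_path,meta_path optional output paths; when given, the
#'   alignment is written as aligned FASTA and the labels/coordinates as a
#'   CSV sidecar (id, population, latitude, longitude).
#' @return an `alignment` object (see [read_alignment()]): list with
#'   `sequences` (character matrix, one row per sequence), `labels`,
#'   `coords`.
#' @export
generate_alignment <- function(gm, fasta_path = NULL, meta_path = NULL) {
  stopifnot(inherits(gm, "genetic_model"))
  set.seed(gm$seed)
  bases <- c("a", "c", "g", "t")
  L <- gm$seq_length
  n1 <- gm$n_per_pop[1]; n2 <- gm$n_per_pop[2]
  ancestor <- sample(bases, L, replace = TRUE)

  flip <- function(x) sample(setdiff(bases, x), 1)
  pop2_base <- ancestor
  fixed_sites <- if (gm$fixed_diffs > 0) sample.int(L, gm$fixed_diffs) else
    integer(0)
  for (s in fixed_sites) pop2_base[s] <- flip(pop2_base[s])

  seqs <- matrix("", n1 + n2, L)
  for (i in seq_len(n1 + n2)) {
    x <- if (i <= n1) ancestor else pop2_base
    mut <- which(runif(L) < gm$within_poly_rate)
    for (s in mut) x[s] <- flip(x[s])
    seqs[i, ] <- x
  }
  ids <- c(sprintf("pop1_%02d", seq_len(n1)), sprintf("pop2_%02d", seq_len(n2)))
  rownames(seqs) <- ids
  labels <- rep(c("pop1", "pop2"), c(n1, n2))
  coords <- data.frame(id = ids, population = labels,
                       latitude = runif(n1 + n2, 30, 48),
                       longitude = c(runif(n1, -125, -100),
                                     runif(n2, -95, -70)))
  aln <- structure(list(sequences = seqs, labels = labels, coords = coords),
                   class = "alignment")
  if (!is.null(fasta_path)) {
    ape::write.dna(ape::as.DNAbin(seqs), fasta_path, format = "fasta",
                   colsep = "")
    if (!is.null(meta_path)) write.csv(coords, meta_path, row.names = FALSE)
  }
  aln
}

#' Two Gaussian classes with an analytically known Bayes accuracy
#'
#' Draws two equal-sized classes from spherical Gaussians in `d` dimensions
#' whose mean separation is set so the Bayes-optimal accuracy equals
#' `bayes_accuracy`: for equal spherical covariance the optimal rule is the
#' midpoint hyperplane and its accuracy is `pnorm(delta / 2)` where `delta`
#' is the Mahalanobis distance between the means.
#'
#' @param n_per_class samples per class.
#' @param bayes_accuracy target Bayes accuracy in (0.5, 1).
#' @param d dimension (default 16, matching the song feature count).
#' @param seed integer seed.
#' @return list with `x` (matrix), `y` (factor "A"/"B"), `delta`,
#'   `bayes_accuracy`.
#' @export
two_class_gaussians <- function(n_per_class, bayes_accuracy = 0.90, d = 16L,
                                seed = 1L) {
  stopifnot(bayes_accuracy > 0.5, bayes_accuracy < 1)
  delta <- 2 * qnorm(bayes_accuracy)
  set.seed(seed)
  shift <- delta / sqrt(d)
  x <- rbind(matrix(rnorm(n_per_class * d), n_per_class, d),
             matrix(rnorm(n_per_class * d, mean = shift), n_per_class, d))
  colnames(x) <- sprintf("f%02d", seq_len(d))
  list(x = x, y = factor(rep(c("A", "B"), each = n_per_class)),
       delta = delta, bayes_accuracy = bayes_accuracy)
}
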