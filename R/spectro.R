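# Spectrogram computation and syllable segmentation: periods of sound
# separated by periods of silence, binarized from a peak-normalized
# short-time Fourier power matrix.

#' Resample a waveform to 44,100 Hz
#'
#' Bandlimited (windowed-sinc) interpolation with the anti-alias cutoff at
#' just below half of the lower of the two sampling rates, mirroring the
#' standard practice of low-pass filtering at the Nyquist frequency before
#' rate conversion.  A waveform already at 44,100 Hz is returned unchanged.
#'
#' @param waveform numeric vector.
#' @param in_rate input sampling rate (Hz).
#' @param taps half-width of the sinc kernel in input samples.
#' @return numeric vector at 44,100 Hz, length `round(n * 44100 / in_rate)`.
#' @export
resample_to_44100 <- function(waveform, in_rate, taps = 24L) {
  if (length(waveform) == 0L) stop_fmt("resample_to_44100: empty waveform")
  if (in_rate <= 0) stop_fmt("resample_to_44100: in_rate must be positive")
  if (in_rate == 44100) return(waveform)
  out_rate <- 44100
  r <- out_rate / in_rate
  n_in <- length(waveform)
  n_out <- round(n_in * r)
  # cutoff below the lower Nyquist, with a transition band
  fc <- 0.45 * min(in_rate, out_rate) / in_rate   # cycles per input sample
  x <- c(numeric(taps), waveform, numeric(taps + 1L))
  t <- (seq_len(n_out) - 1) / r                   # output times, input units
  i0 <- floor(t)
  frac <- t - i0
  out <- numeric(n_out)
  for (k in seq(-taps + 1L, taps)) {
    u <- frac - k
    h <- 2 * fc * sinc(2 * fc * u) * hann_u(u / taps)
    out <- out + waveform_at(x, i0 + k + taps + 1L) * h
  }
  out
}

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))
hann_u <- function(u) ifelse(abs(u) < 1, 0.5 * (1 + cos(pi * u)), 0)
waveform_at <- function(x, idx) x[pmin(pmax(idx, 1L), length(x))]

#' Spectrogram parameters
#'
#' @param window_samples Hann analysis window length (samples).
#' @param hop_samples hop between frames (samples); default 50% overlap
#'   would be `window_samples / 2`, but segmentation benefits from finer
#'   time resolution, so the default hop is a quarter window.
#' @param sample_rate sampling rate; inputs must be at 44,100 Hz.
#' @param hp_hz,lp_hz optional band-pass edges; power outside the band is
#'   set to the floor.
#' @param db_floor dB floor applied to the power matrix.
#' @return list of class `spectrogram_params`.
#' @export
spectrogram_params <- function(window_samples = 1024L, hop_samples = 256L,
                               sample_rate = 44100L, hp_hz = NULL,
                               lp_hz = NULL, db_floor = -100) {
  if (!is.null(hp_hz) && !is.null(lp_hz) && hp_hz >= lp_hz)
    stop_fmt("spectrogram_params: hp_hz must be below lp_hz")
  structure(list(window_samples = as.integer(window_samples),
                 hop_samples = as.integer(hop_samples),
                 sample_rate = as.integer(sample_rate),
                 hp_hz = hp_hz, lp_hz = lp_hz, db_floor = db_floor),
            class = "spectrogram_params")
}

#' Compute a normalized dB spectrogram
#'
#' The waveform is peak-normalized first (per-song amplitude normalization),
#' then short-time Fourier magnitudes are expressed in dB relative to the
#' spectrogram maximum, floored at `params$db_floor`.
#'
#' @param waveform numeric vector at 44,100 Hz.
#' @param params a [spectrogram_params()].
#' @return object of class `spectrogram`: list with `power` (freq x time
#'   dB matrix), `freq_axis` (Hz bin centers), `time_axis` (frame start,
#'   ms), `hop_ms`, and `params`.
#' @export
compute_spectrogram <- function(waveform, params = spectrogram_params()) {
  if (length(waveform) == 0L) stop_fmt("compute_spectrogram: empty waveform")
  win <- params$window_samples
  hop <- params$hop_samples
  if (win > length(waveform))
    stop_fmt("compute_spectrogram: window (%d) longer than waveform (%d)",
             win, length(waveform))
  peak <- max(abs(waveform))
  if (peak > 0) waveform <- waveform / peak
  starts <- seq(1L, length(waveform) - win + 1L, by = hop)
  hann <- 0.5 * (1 - cos(2 * pi * (seq_len(win) - 1) / (win - 1)))
  frames <- vapply(starts,
                   function(s) waveform[s:(s + win - 1L)] * hann,
                   numeric(win))
  spec <- stats::mvfft(frames)
  mag <- Mod(spec[seq_len(win %/% 2L + 1L), , drop = FALSE])
  db <- 20 * log10(mag / max(mag, .Machine$double.eps) +
                     .Machine$double.xmin)
  db <- pmax(db, params$db_floor)
  freq_axis <- (seq_len(nrow(db)) - 1) * params$sample_rate / win
  if (!is.null(params$hp_hz)) db[freq_axis < params$hp_hz, ] <-
      params$db_floor
  if (!is.null(params$lp_hz)) db[freq_axis > params$lp_hz, ] <-
      params$db_floor
  structure(list(power = db, freq_axis = freq_axis,
                 time_axis = (starts - 1 + win / 2) /
                   params$sample_rate * 1000,
                 hop_ms = hop / params$sample_rate * 1000,
                 # frame k's time cell is [(k-1) * hop + t0, k * hop + t0):
                 # hop-width cells centered on the analysis windows
                 t0_ms = (win - hop) / 2 / params$sample_rate * 1000,
                 params = params),
            class = "spectrogram")
}

#' Segmentation parameters
#'
#' @param signal_quantile fraction of spectrogram elements kept as signal
#'   (binarization keeps the top `signal_quantile` of power values).
#' @param noise_gate_db elements must additionally exceed the spectrogram
#'   median by this many dB; the median tracks the noise floor, so this
#'   gate keeps a top-quantile threshold from flagging scattered noise
#'   elements in quiet recordings (pure noise yields an empty mask).
#' @param min_syllable_ms sounds shorter than this are discarded.
#' @param min_silence_ms silences shorter than this are merged into the
#'   flanking sound.
#' @param hp_hz,lp_hz band-pass edges applied to the spectrogram.
#' @param noise_element_threshold minimum number of spectrogram elements a
#'   connected component must contain to not be discarded as noise.
#'   Species-specific defaults follow the corpus calibration: 87 for the
#'   western species (B), 70 for the eastern species (A), 65 for
#'   hybrid/unsure, 65 as the global fallback; see
#'   [noise_threshold_for_species()].
#' @return list of class `segmentation_params`.
#' @export
segmentation_params <- function(signal_quantile = 0.10, noise_gate_db = 20,
                                min_syllable_ms = 15, min_silence_ms = 10,
                                hp_hz = 500, lp_hz = 12000,
                                noise_element_threshold = 65) {
  stopifnot(signal_quantile > 0, signal_quantile < 1,
            min_syllable_ms > 0, min_silence_ms > 0, hp_hz < lp_hz,
            noise_element_threshold >= 0)
  structure(list(signal_quantile = signal_quantile,
                 noise_gate_db = noise_gate_db,
                 min_syllable_ms = min_syllable_ms,
                 min_silence_ms = min_silence_ms,
                 hp_hz = hp_hz, lp_hz = lp_hz,
                 noise_element_threshold = noise_element_threshold),
            class = "segmentation_params")
}

#' Per-species noise-element thresholds
#'
#' @param species `"A"` (eastern), `"B"` (western/spotted), anything else
#'   falls back to the hybrid/unsure value.
#' @return integer element-count threshold (B = 87, A = 70, otherwise 65).
#' @export
noise_threshold_for_species <- function(species) {
  switch(as.character(species), B = 87L, A = 70L, 65L)
}

# Binary signal mask: top-quantile power elements that also clear the noise
# gate, restricted to the band-pass.
signal_mask <- function(spec, p) {
  db <- spec$power
  band <- spec$freq_axis >= p$hp_hz & spec$freq_axis <= p$lp_hz
  db[!band, ] <- -Inf
  vals <- db[band, ]
  thr <- max(stats::quantile(vals, 1 - p$signal_quantile, names = FALSE),
             stats::median(vals) + p$noise_gate_db)
  db >= thr
}

#' Segment a spectrogram into syllable intervals
#'
#' Binarizes the band-passed spectrogram at the `(1 - signal_quantile)` power
#' quantile (plus the noise gate), column-sums the mask into a sound/silence
#' presence profile, merges silences shorter than `min_silence_ms` into the
#' flanking sound, and discards sounds shorter than `min_syllable_ms`.
#' Intervals are half-open `[onset, offset)` in ms from bout start.
#'
#' @param spec a [compute_spectrogram()] result.
#' @param p a [segmentation_params()].
#' @return data frame with columns `onset_ms`, `offset_ms` (possibly
#'   zero rows), sorted and disjoint.
#' @export
segment_syllables <- function(spec, p = segmentation_params()) {
  stopifnot(inherits(spec, "spectrogram"))
  mask <- signal_mask(spec, p)
  presence <- colSums(mask) > 0
  hop <- spec$hop_ms

  # merge interior silences shorter than min_silence_ms
  r <- rle(presence)
  if (length(r$lengths) > 2) {
    interior <- seq_along(r$values)[-c(1, length(r$values))]
    short <- interior[!r$values[interior] &
                        r$lengths[interior] * hop < p$min_silence_ms]
    r$values[short] <- TRUE
    presence <- inverse.rle(r)
    r <- rle(presence)
  }
  # discard sounds shorter than min_syllable_ms
  short <- which(r$values & r$lengths * hop < p$min_syllable_ms)
  r$values[short] <- FALSE
  presence <- inverse.rle(r)
  r <- rle(presence)

  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  data.frame(onset_ms = (starts[keep] - 1) * hop + spec$t0_ms,
             offset_ms = ends[keep] * hop + spec$t0_ms)
}

#' Remove small connected components from syllable masks
#'
#' Within each interval, 8-connected components of the binary signal mask
#' with fewer than `noise_element_threshold` elements are discarded as
#' noise.  Intervals whose mask becomes empty are dropped; surviving
#' intervals are trimmed to the columns their retained elements span and
#' re-validated against `min_syllable_ms`.
#'
#' @param spec a [compute_spectrogram()] result.
#' @param intervals data frame from [segment_syllables()].
#' @param p a [segmentation_params()].
#' @return list with `intervals` (filtered data frame, plus a
#'   `n_components` column) and `masks` (one full-height logical matrix of
#'   retained elements per interval, with the spectrogram `freq_axis` and
#'   `hop_ms` attached as attributes).
#' @export
filter_noise_components <- function(spec, intervals,
                                    p = segmentation_params()) {
  mask <- signal_mask(spec, p)
  hop <- spec$hop_ms
  keep_rows <- logical(nrow(intervals))
  masks <- vector("list", nrow(intervals))
  n_comp <- integer(nrow(intervals))
  out <- intervals
  for (i in seq_len(nrow(intervals))) {
    c0 <- floor((intervals$onset_ms[i] - spec$t0_ms) / hop) + 1L
    c0 <- max(c0, 1L)
    c1 <- ceiling((intervals$offset_ms[i] - spec$t0_ms) / hop)
    c1 <- min(c1, ncol(mask))
    sub <- mask[, c0:c1, drop = FALSE]
    lab <- cpp_label_components(sub)
    if (max(lab) > 0) {
      sizes <- tabulate(lab[lab > 0])
      drop <- which(sizes < p$noise_element_threshold)
      sub[lab %in% drop] <- FALSE
    }
    cols_on <- which(colSums(sub) > 0)
    if (length(cols_on) == 0) next
    on0 <- (c0 - 1L + min(cols_on) - 1L) * hop + spec$t0_ms
    on1 <- (c0 - 1L + max(cols_on)) * hop + spec$t0_ms
    if (on1 - on0 < p$min_syllable_ms) next
    keep_rows[i] <- TRUE
    out$onset_ms[i] <- on0
    out$offset_ms[i] <- on1
    full <- matrix(FALSE, nrow(mask), ncol(mask))
    full[, c0:c1] <- sub
    attr(full, "freq_axis") <- spec$freq_axis
    attr(full, "hop_ms") <- hop
    masks[[i]] <- full
    n_comp[i] <- sum(tabulate(cpp_label_components(sub)) > 0)
  }
  out$n_components <- n_comp
  list(intervals = out[keep_rows, , drop = FALSE],
       masks = masks[keep_rows])
}

# bilinear resize of a numeric matrix
resize_bilinear <- function(m, nr, nc) {
  sr <- seq(1, nrow(m), length.out = nr)
  sc <- seq(1, ncol(m), length.out = nc)
  r0 <- floor(sr); r1 <- pmin(r0 + 1, nrow(m)); fr <- sr - r0
  c0 <- floor(sc); c1 <- pmin(c0 + 1, ncol(m)); fc <- sc - c0
  a <- m[r0, c0, drop = FALSE] * outer(1 - fr, 1 - fc) +
    m[r1, c0, drop = FALSE] * outer(fr, 1 - fc) +
    m[r0, c1, drop = FALSE] * outer(1 - fr, fc) +
    m[r1, c1, drop = FALSE] * outer(fr, fc)
  a
}

#' Export a classifier-ready spectrogram image
#'
#' Renders the band-passed (1--10 kHz) spectrogram of a 44,100 Hz waveform
#' to a 224 x 224 RGB PNG with a fixed color map, no axes and no margins --
#' the input format of the image-based (CNN) classifier.
#'
#' @param waveform numeric vector at 44,100 Hz.
#' @param out_path output PNG path.
#' @param params spectrogram parameters; the 1--10 kHz band-pass is imposed.
#' @return `out_path` invisibly.
#' @export
export_spectrogram_image <- function(waveform, out_path,
                                     params = spectrogram_params()) {
  params$hp_hz <- 1000; params$lp_hz <- 10000
  spec <- compute_spectrogram(waveform, params)
  band <- spec$freq_axis >= 1000 & spec$freq_axis <= 10000
  img <- resize_bilinear(spec$power[band, , drop = FALSE][rev(seq_len(sum(
    band))), , drop = FALSE], 224L, 224L)
  v <- (img - min(img)) / max(max(img) - min(img), .Machine$double.eps)
  ramp <- grDevices::colorRamp(c("#000004", "#51127c", "#b63679",
                                 "#fb8861", "#fcfdbf"))   # magma-like
  rgb <- ramp(as.vector(v)) / 255
  arr <- array(rgb, dim = c(224L, 224L, 3L))
  png::writePNG(arr, out_path)
  invisible(out_path)
}

#' Load a spectrogram image as a normalized tensor
#'
#' @param path PNG written by [export_spectrogram_image()].
#' @return 224 x 224 x 3 numeric array in \[0, 1\].
#' @export
read_spectrogram_image <- function(path) {
  arr <- png::readPNG(path)
  if (length(dim(arr)) != 3 || any(dim(arr)[1:2] != 224L))
    stop_fmt("read_spectrogram_image: '%s' is not a 224x224 RGB image", path)
  arr[, , 1:3, drop = FALSE]
}
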