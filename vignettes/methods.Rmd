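---
title: "Methods: song divergence across an avian contact zone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: song divergence across an avian contact zone}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(songcline)
```

## The problem this package addresses

The Spotted towhee (*Pipilo maculatus*) and Eastern towhee
(*P. erythrophthalmus*) are recently diverged sister species whose breeding
ranges meet in the Great Plains, where they occasionally hybridize.  Both
sing a stereotyped bout — a few short introductory notes followed by a fast
trill — and the question is whether many small, individually unreliable song
differences together carry enough signal for species recognition, and
whether that signal weakens in the zone of range overlap where it would
matter most.

`songcline` re-implements this analysis chain as a tested pipeline:

1. **Synthesis** of towhee-like songs with known ground truth (`synth_song`
   functions), so every later stage can be validated without any field
   recordings.
2. **Segmentation** of spectrograms into syllables — periods of sound
   separated by periods of silence — with a connected-component noise
   filter (`compute_spectrogram()`, `segment_syllables()`,
   `filter_noise_components()`).
3. **Sixteen song features** per bout (durations, counts, rates, syllable
   typing by percent time–frequency overlap, frequency bounds and ranges;
   `song_feature_table()`).
4. **Geography**: curation rules (deduplication, April–August breeding
   season), per-degree-longitude species proportions, a formalized overlap
   zone, and WGS84 geodesic distances.
5. **Statistics**: log-link GLMs per feature, PCA, LDA, a UMAP contract,
   Procrustes concordance of trait space with geography, Spearman Mantel
   tests for isolation by distance.
6. **Classifier evaluation**: balanced 75/25 and region-stratified splits,
   random forest / gradient boosting / multilayer perceptron / LDA
   backends, label-permutation nulls, per-sample vote confidence.
7. **Population genetics**: pairwise Phi-ST via two-level AMOVA on
   mitochondrial-style haploid alignments.

## The synthetic world

Synthetic data is a *stated world*, not a tuning dial: the defaults below
were fixed once, before the test suite was frozen, and the tests interrogate
the pipeline against this world.

**Species profiles.** The literature describes the eastern species as
singing more and more-varied syllables with a slower trill, and the western
species as having few or no introductory notes, a faster trill, and trills
that occasionally fuse into a single unbroken syllable.  The defaults encode
exactly that contrast:

| parameter | A (eastern) | B (western) |
|---|---|---|
| introductory notes | 2–4 | 0–2 |
| trill repetitions | 5–9 | 8–14 |
| trill syllable (ms) | 60 ± 8 | 40 ± 6 |
| trill gap (ms) | 45 ± 6 | 30 ± 5 |
| trill band (Hz) | 2800–5800 | 3300–6800 |
| fused-trill probability | 0 | 0.15 |

No quantitative distributions for these parameters exist in the field literature; the values
are chosen to be qualitatively faithful while remaining *physically
resolvable* by the analysis window: a 1024-sample Hann window at 44.1 kHz
smears energy over ~23 ms, so trill gaps are floored at 25 ms.  (An earlier
draft used 22 ms mean gaps; fast trills then collapsed into single
intervals, which is realistic — it is why fused trills exist — but would
make ground-truth recovery untestable.  The floor was set during initial
world construction, and the fused-trill pathway is exercised separately via
`single_syllable_trill_prob`.)

**Geography.** Longitude is uniform over the union of the ranges
(125°W–67°W); west of the overlap zone (102°W–91°W) all songs are species B,
east of it species A, and inside the zone membership is a longitude-linear
mixture.  Per-species clines shift parameter means linearly with longitude,
with signs chosen so the two species *converge* toward the zone — the
mechanism behind the in-zone classification difficulty the evaluation
reproduces.  Inside the zone a song is a parameter-midpoint "hybrid" with
probability 0.025, matching the sighting-based in-zone hybridization
estimate of roughly 2.3–2.6%.  Recording dates are uniform over April–August
(an off-season fraction is configurable so the breeding-season filter can be
exercised); file-conversion status is drawn with a westward bias, emulating
the mp3-heavy western archives.

**Rendering.** Syllables are Hann-windowed constant tones (at the band
midpoint) or linear chirps sweeping the band; white noise is added at
`noise_floor_db` (default −50 dB) relative to peak syllable amplitude and
the waveform is peak-normalized to 0.9.  What the generator does **not**
emulate: harmonic stacks, reverberation and propagation effects, colored
noise, overlapping singers, amplitude modulation within syllables.  A green
segmentation test therefore establishes correctness of the sound/silence
logic on clean, additive-white-noise bouts — not robustness to field
recordings, which in the original workflow is handled by manual review.

**Sequences.** `generate_alignment()` draws two populations from a shared
random ancestor, fixes `fixed_diffs` substitutions in all of population 2,
and mutates each site independently per individual at `within_poly_rate`.
The defaults (18 + 5 sequences, 650 sites) mirror the scale of the
mitochondrial COI barcode data set the genetic stage is designed for.

## Segmentation choices

* **Threshold.** Binarization keeps the top `signal_quantile` (default 10%)
  of spectrogram power values, mirroring per-song amplitude normalization
  and making the threshold robust to recording gain.  A pure quantile rule,
  however, always marks ~10% of elements even in silence; elements must
  therefore also exceed the spectrogram median — which tracks the noise
  floor — by `noise_gate_db` (default 20 dB).  Under a Rayleigh noise
  magnitude distribution the probability of a noise element clearing a
  20 dB gate is astronomically small, so pure-noise input yields zero
  intervals while the quantile dominates in loud recordings.
* **Window and hop.** 1024-sample Hann window (43 Hz bins) with a
  256-sample hop.  A 50% hop (512) gives 11.6 ms time bins, too coarse to
  detect ~30 ms trill gaps reliably; 256 (5.8 ms) resolves them at
  negligible cost.
* **Time stamps.** Frames are stamped by window-centered hop-width cells
  (`t0_ms = (window − hop)/2`).  Stamping by window start biases onsets
  ~11 ms early because the window "looks ahead"; centering makes onset and
  offset errors small and symmetric (within ±2 hops on tone fixtures).
* **Noise filter.** Within each interval, 8-connected components of the
  binary mask with fewer than `noise_element_threshold` elements are
  discarded (per *component*, not per syllable total — the original
  tool's description does not say which; per-component is the stricter reading and
  is flagged as the deviation risk).  Species-specific defaults 87
  (western), 70 (eastern), 65 (hybrid/unsure and fallback) follow the
  corpus calibration of the original tool.
* **Interactive re-segmentation** is replaced by deterministic parameters;
  per-song overrides can be supplied programmatically, which makes the
  manual step reproducible.

## Feature measurement choices

* **Frequency bounds** use the mask elements within 35 dB of the syllable's
  own power maximum.  A noise-referenced threshold would report the
  spectral-leakage skirt of narrowband syllables (Hann sidelobes reach
  −31 dB) instead of band edges; 35 dB keeps chirp ends, whose amplitude is
  reduced by the syllable envelope, while trimming far leakage.
* **Similarity** is the maximum over integer time lags of the shared
  on-element count, normalized by the *mean* of the two element counts
  (`normalizer = "min"` is the config alternative; "percent syllable
  overlap" alone does not pin the denominator down).  The lag search spans
  every offset at which the masks overlap.
* **Typing** is greedy and founder-based: the first syllable founds type 0
  and each later syllable joins the earliest-founded type whose *founder*
  it matches at or above the threshold (inclusive at equality).
  Full-linkage clustering was rejected because its labels depend on
  presentation order under ties.
* Songs whose every syllable is removed by the noise filter are excluded
  from the feature table and listed in the `excluded` attribute, mirroring
  the manual exclusion of unusable recordings.

## Statistical choices

* **GLM family.** The analysis this mirrors states only a log link.  The
  default here is Gaussian with log link on the raw positive features
  (matching `glm` applied to raw data with `family = gaussian("log")`);
  Gamma-with-log-link is available via `family = "gamma_log"`.  IRLS for a
  Gaussian log link is fragile for skewed responses, so the fit starts from
  least squares on the log scale.
* **LDA** uses equal priors: training sets are balanced by construction.
  The same code path serves as the "simple linear classifier" on PC1/PC2
  or UMAP coordinates.
* **Mantel** uses Spearman rank correlation of lower triangles, a joint
  row/column permutation of the second matrix, the one-sided upper tail
  (positive association is the scientific direction), 999 permutations by
  default, and the add-one correction so p is never zero.  `exact = TRUE`
  enumerates all n! permutations for small n (used by the oracle tests).
* **Procrustes** fits translation, rotation and uniform scale; reflection
  is excluded by default (`allow_reflection` enables it — note the
  reference implementation in vegan permits reflection, so oracle
  comparisons set the flag).  The concordance statistic is
  `sqrt(1 − m²)`; the permutation test permutes source rows.
* **UMAP** delegates to the reference python implementation (umap-learn)
  through the interpreter on the PATH, with `random_state` fixed, because
  no R implementation is installed in the target environment.  Embedding
  coordinates have no absolute meaning; only derived statistics are
  asserted.
* **AMOVA** is the standard two-level variance partition computed from
  squared pairwise distances, with the n0 coefficient for unequal sample
  sizes.  For alignments the squared distance is the count of pairwise
  nucleotide differences.  Negative variance components are reported raw
  but floored at zero for the percentage split, the conventional practice.
  Phi-ST significance (label permutation) is provided although the original
  analysis reports point estimates only.

## Classifier backends

The evaluation harness owns splits, metrics, nulls and configuration; the
learners are pluggable.  Because no tree/boosting/neural package is
installed in the target environment, the backends are implemented in the
package behind the same contract:

* **rf** — bagged CART trees (gini splits over `mtry` random features, a
  compiled split finder), 500 trees by default, per-tree votes exposed for
  confidence maps, optional 10-fold cross-validated tuning over an
  mtry × min-node grid (10 × 16 by default).
* **gbm** — Newton-step logistic boosting (the two-class case of a softmax
  objective) with depth-3 regression trees, at most 100 rounds, early
  stopping after 10 non-improving validation rounds.
* **mlp** — 16→64→64→2 ReLU network, log-softmax output, unweighted
  cross-entropy, Adam at 0.001, batch 32, up to 100 epochs.  **Deviation:**
  training stops early when cross-entropy on a 15% validation split fails
  to improve for 10 epochs, restoring the best weights.  The original
  configuration trains a fixed 100 epochs; on the synthetic Gaussian
  benchmark that overtrains badly (train accuracy 1.0 while test accuracy
  decays from ~0.864 at epoch 20 to ~0.844 at epoch 100, against a Bayes
  bound of 0.90) and the implementation is gradient-checked, so the gap is
  overfitting, not a bug.  Early stopping mirrors what the workflow
  already applies to its GBM; `early_stopping = FALSE` restores the
  literal fixed-epoch schedule.
* **cnn** — the 224×224×3 image pipeline (band-passed 1–10 kHz
  spectrograms rendered to PNG), the reference architecture echo
  (32/128/128/128 3×3 filters, 2×2 pooling, dense 1024, softmax-2,
  inputs scaled by 1/255) and the input-shape contract are implemented,
  but no deep-learning engine exists in the target environment, so
  `train_classifier` raises an explicit error for this backend.  The
  image-input route is therefore validated structurally, not trained.

The permutation null refits with fixed hyperparameters across replicates
(the cheaper and conservative reading of the original procedure).

## Numerical notes and degenerate inputs

* Permutation p-values always use the add-one correction; exact enumeration
  counts the identity permutation, so p ≥ 1/n! and never zero.
* Cohen's kappa with degenerate marginals (chance agreement 1) is reported
  as `NA` with a warning rather than a division by zero.
* A single fused trill yields `n = 1`, one type, repetition 1, and bout
  duration equal to that syllable's duration — the degenerate case is a
  legitimate song, not an error.
* Vincenty's inverse geodesic iterates to 1e−12; the rare near-antipodal
  non-convergence falls back to the spherical great circle on the
  mean-radius sphere (error below 0.6%, documented).
* Zone finding formalizes the original by-inspection choice as the widest
  contiguous run of one-degree bins where both species hold at least
  `min_count` records and `min_prop` (default 1 and 0.05) of the bin;
  half-open bins are labeled by the western edge and ties go west.  On the
  default synthetic world this recovers the configured zone within ±1° at
  corpus scale (~10⁴ records); at a few hundred records the edge bins often
  lack the minority species entirely, so the detected zone is narrower —
  a sampling property, not an implementation artifact.

## Known limitations

* The synthetic world has linear clines and parameter-midpoint hybrids;
  real intermediate songs are described qualitatively, not parameterized,
  in the source material.
* Real-corpus headline numbers (classifier accuracies near 90%, GLM
  t-values, Mantel r's, a COI Phi-ST near 0.64) depend on the external
  recording corpus and sequence archives and are deliberately out of
  scope; the tests assert the self-contained worked values and
  property-based behavior instead.
* The CNN backend cannot be trained in this environment (see above).
* Segmentation quality on real field recordings with structured background
  noise is untested by design; the quantile + gate + component filter is
  calibrated on the synthetic world.
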