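# songcline

Song divergence, species classification and genetic differentiation across
an avian contact zone.

## What this is for

The Spotted towhee (*Pipilo maculatus*) and Eastern towhee
(*P. erythrophthalmus*) are sister songbird species whose ranges meet in a
longitudinal contact zone (about 102°W–91°W) where they occasionally
hybridize. Their songs — short introductory notes followed by a fast
trill — differ in many small ways but in no single reliable feature. The
scientific questions are (i) whether the joint signal of many song features
is sufficient for species recognition, and (ii) whether that signal weakens
inside the zone of overlap, where it would matter most for premating
isolation.

`songcline` packages that analysis chain for anyone studying song
divergence across a contact zone, with a synthetic-data module so the whole
pipeline is testable without any field recordings:

* **Synthesis** — towhee-like bouts (tones and linear chirps, additive
  white noise) with exact ground-truth syllable intervals, frequencies and
  types; a two-species population model with longitude-linear clines and a
  2.5% in-zone hybrid fraction; two-population haploid alignments with
  tunable between/within diversity.
* **Segmentation** — normalized dB spectrograms; syllables as periods of
  sound separated by periods of silence, binarized at a power quantile
  with a noise gate; an 8-connected-component noise filter with
  species-specific element thresholds (87/70/65).
* **Features** — the 16 per-bout song features: bout duration, syllable
  count and rate, smallest/largest/mean syllable duration, unique-syllable
  count, degree of repetition (n/n_unique), average upper/lower frequency,
  max/min frequency, overall range (max − min) and
  largest/smallest/average per-syllable range. Syllable types come from
  percent time–frequency mask overlap with species thresholds
  (26.6/25.5/25.0).
* **Geography** — deduplication by (recordist, date, location) and
  (date, lat, lon), the April–August breeding-season filter, per-degree
  species proportions, formalized overlap-zone detection, hybrid-rate
  arithmetic, WGS84 (Vincenty) geodesic distance matrices.
* **Statistics** — Gaussian log-link GLMs per feature (`y ~ scaled lon +
  scaled lat + species + conversion`), PCA, LDA (equal priors), UMAP via
  the python umap-learn reference backend, Procrustes superimposition with
  a permutation test (statistic `sqrt(1 − m²)`), Spearman Mantel tests
  (999 permutations, add-one correction).
* **Classifier evaluation** — balanced 75/25 splits (`floor(0.75 N)`
  training; 2785 records give a 697-record test set), region-stratified
  splits trained only outside the zone, in-package random forest /
  gradient boosting / MLP / LDA backends, label-permutation nulls,
  per-tree vote-confidence maps, multi-seed confidence intervals.
* **Population genetics** — aligned FASTA input, haploid SNP matrices,
  sqrt-mismatch distances, two-level AMOVA with Phi-ST
  (`σ²_among / (σ²_among + σ²_within)`) and a label-permutation test.

## Worked example

```r
library(songcline)

# 1. synthesize a small two-species corpus with known ground truth
model <- population_model(n_recordings = 120)
pop   <- sample_population(model, seed = 42)
waves <- lapply(pop$specs,
                function(s) synthesize_song(s, model$noise_floor_db)$waveform)

# 2. segment syllables and compute the 16 song features per bout
feats <- song_feature_table(waves, pop$metadata)
table(feats$species)
#>             A             B hybrid_unsure
#>            67            52             1

# 3. species classification with a balanced 75/25 split
two   <- feats[feats$species %in% c("A", "B"), ]
x     <- log_transform_features(two[, song_feature_names()])
split <- make_balanced_split(two, seed = 1)
rf    <- train_classifier(classifier_config("rf", n_trees = 200L),
                          x[split$train, ], two$species[split$train], seed = 1)
ev    <- evaluate_classifier(rf, x[split$test, ], two$species[split$test])
round(c(accuracy = ev$accuracy, balanced = ev$balanced_accuracy,
        kappa = ev$kappa), 3)
#> accuracy balanced    kappa
#>        1        1        1

# 4. isolation by distance: Mantel test of song vs geographic distance
mt <- mantel_test(feature_distance_matrices(two)$overall,
                  geodesic_distance_matrix(two), n_perm = 199, seed = 1)
round(c(r = mt$r, p = mt$p), 3)
#>     r     p
#> 0.541 0.005

# 5. genetic differentiation on a synthetic two-population alignment
aln <- generate_alignment(genetic_model(n_per_pop = c(18, 5),
                                        fixed_diffs = 20,
                                        within_poly_rate = 0.003, seed = 1))
am  <- amova_two_level(aln)
round(c(phi_st = am$phi_st, pct_between = am$pct_between), 3)
#>      phi_st pct_between
#>       0.828      82.847
```

What the numbers mean: at this small synthetic scale the two species are
perfectly classifiable at the range extremes (accuracy 1.0; with clines and
in-zone mixing, region-stratified evaluation shows lower in-zone accuracy —
see the acceptance tests); song distance is positively associated with
geographic distance (Mantel r = 0.54, one-sided p = 0.005); and the
20-fixed-difference alignment gives Phi-ST = 0.83 with ~83% of molecular
variance between populations. A pipeline run with clean defaults is one
call: `run_pipeline(default_config(master_seed = 1, out_dir = "run1"))`
writes a JSON results bundle plus CSV side tables.

## Layout

```
R/            implementation (synthesis, spectrograms, features, geography,
              statistics, learners, evaluation, popgen, pipeline)
src/          compiled split finder + connected-component labeling (Rcpp)
tests/        testthat suite, incl. test-acceptance.R (criteria with
              their stated tolerances)
scripts/      acceptance.R
vignettes/    methods.Rmd — model assumptions, parameter defaults and
              rationale, numerical choices, known limitations
```
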