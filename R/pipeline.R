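# Configuration and orchestration: one YAML-configurable run that chains
# synth -> segment -> features -> geo -> stats -> classify -> popgen and
# writes a single JSON results bundle with CSV side tables.  Every
# stochastic stage derives its seed from the master seed plus the stage
# name, so toggling stages never reshuffles the others.

#' Default run configuration
#'
#' @param master_seed integer master seed.
#' @param out_dir output directory for the bundle and side tables.
#' @return nested list of class `run_config`; see the fields for the
#'   tunable parameters of each stage.
#' @export
default_config <- function(master_seed = 1L, out_dir = tempfile("run")) {
  structure(list(
    master_seed = as.integer(master_seed),
    out_dir = out_dir,
    input_dir = NULL,                  # existing dataset; NULL = synthesize
    stages = list(synth = TRUE, segment = TRUE, features = TRUE,
                  geo = TRUE, stats = TRUE, classify = TRUE,
                  popgen = TRUE),
    synth = list(n_recordings = 200L, noise_floor_db = -50,
                 hybrid_fraction = 0.025, off_season_fraction = 0),
    segmentation = list(signal_quantile = 0.10, noise_gate_db = 20,
                        min_syllable_ms = 15, min_silence_ms = 10,
                        hp_hz = 500, lp_hz = 12000),
    typing = list(similarity_threshold_percent = 25.0,
                  per_species = TRUE),
    zone = list(min_prop = 0.05, min_count = 1),
    classify = list(backend = "rf", n_trees = 200L, train_frac = 0.75,
                    n_perm = 199L),
    stats = list(n_perm = 999L, glm_family = "gaussian_log"),
    popgen = list(n_per_pop = c(18L, 5L), seq_length = 650L,
                  fixed_diffs = 20L, within_poly_rate = 0.003)),
    class = "run_config")
}

#' Validate a run configuration
#'
#' Range-checks every parameter against the type invariants and rejects
#' unknown keys.
#'
#' @param config a list shaped like [default_config()].
#' @return `TRUE` invisibly, or stops with the aggregated error list.
#' @export
validate_config <- function(config) {
  errs <- character(0)
  chk <- function(ok, msg) if (!isTRUE(ok)) errs <<- c(errs, msg)
  tmpl <- default_config()
  unknown <- setdiff(names(config), names(tmpl))
  chk(length(unknown) == 0,
      sprintf("unknown key(s): %s", paste(unknown, collapse = ", ")))
  for (sec in c("stages", "synth", "segmentation", "typing", "zone",
                "classify", "stats", "popgen")) {
    u <- setdiff(names(config[[sec]]), names(tmpl[[sec]]))
    chk(length(u) == 0,
        sprintf("%s: unknown key(s): %s", sec, paste(u, collapse = ", ")))
  }
  s <- config$segmentation
  chk(s$signal_quantile > 0 && s$signal_quantile < 1,
      "segmentation: signal_quantile must be in (0,1)")
  chk(s$min_syllable_ms > 0 && s$min_silence_ms > 0,
      "segmentation: minimum durations must be positive")
  chk(s$hp_hz < s$lp_hz, "segmentation: hp_hz must be below lp_hz")
  t <- config$typing$similarity_threshold_percent
  chk(t > 0 && t < 100,
      "typing: similarity threshold must be in (0,100)")
  chk(config$synth$n_recordings > 0, "synth: n_recordings must be positive")
  chk(config$synth$noise_floor_db < 0, "synth: noise_floor_db must be < 0")
  chk(config$synth$hybrid_fraction >= 0 && config$synth$hybrid_fraction
      <= 1, "synth: hybrid_fraction must be in [0,1]")
  chk(config$classify$n_perm > 0, "classify: n_perm must be positive")
  chk(config$stats$n_perm > 0, "stats: n_perm must be positive")
  chk(config$zone$min_prop >= 0 && config$zone$min_prop < 1,
      "zone: min_prop must be in [0,1)")
  chk(config$popgen$fixed_diffs <= config$popgen$seq_length,
      "popgen: fixed_diffs cannot exceed seq_length")
  chk(is.null(config$input_dir) || isTRUE(config$stages$synth) ||
        dir.exists(config$input_dir),
      "input_dir does not exist and the synth stage is disabled")
  if (!isTRUE(config$stages$synth) && is.null(config$input_dir))
    errs <- c(errs, "no input_dir and the synth stage is disabled")
  if (length(errs))
    stop_fmt("invalid config:\n  - %s", paste(errs, collapse = "\n  - "))
  invisible(TRUE)
}

#' Read a YAML run configuration
#'
#' @param path YAML file; keys mirror [default_config()].
#' @param ... overrides.
#' @return validated `run_config`.
#' @export
read_config <- function(path, ...) {
  raw <- yaml::read_yaml(path)
  cfg <- utils::modifyList(default_config(), raw)
  cfg <- utils::modifyList(cfg, list(...))
  class(cfg) <- "run_config"
  validate_config(cfg)
  cfg
}

#' Run the pipeline
#'
#' Executes the enabled stages in order and writes `bundle.json` (plus
#' `features.csv` and `metadata.csv`) under `config$out_dir`.  The bundle
#' echoes the full configuration and all derived seeds, and is
#' byte-identical across runs with the same master seed.
#'
#' @param config a validated [default_config()]-shaped list.
#' @return the results bundle (list), invisibly.
#' @export
run_pipeline <- function(config = default_config()) {
  validate_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  bundle <- list(config = config,
                 seeds = list(),
                 versions = list(songcline =
                                   as.character(utils::packageVersion(
                                     "songcline")),
                                 r = paste(R.version$major,
                                           R.version$minor, sep = ".")))
  stage_seed <- function(stage) {
    s <- derive_seed(config$master_seed, stage)
    bundle$seeds[[stage]] <<- s
    s
  }
  run_stage <- function(stage, fn) {
    tryCatch(fn(), error = function(e) {
      flush_bundle(bundle, config$out_dir)
      stop_fmt("pipeline stage '%s' failed: %s (partial outputs in %s)",
               stage, conditionMessage(e), config$out_dir)
    })
  }

  model <- population_model(
    hybrid_fraction = config$synth$hybrid_fraction,
    n_recordings = config$synth$n_recordings,
    noise_floor_db = config$synth$noise_floor_db,
    off_season_fraction = config$synth$off_season_fraction)

  waveforms <- NULL; metadata <- NULL
  if (isTRUE(config$stages$synth)) {
    run_stage("synth", function() {
      pop <- sample_population(model, stage_seed("synth"))
      metadata <<- pop$metadata
      waveforms <<- lapply(pop$specs, function(sp)
        synthesize_song(sp, model$noise_floor_db)$waveform)
      write.csv(metadata, file.path(config$out_dir, "metadata.csv"),
                row.names = FALSE)
      bundle$synth <<- list(n = nrow(metadata),
                            species_counts =
                              as.list(table(metadata$species)))
    })
  } else {
    run_stage("load", function() {
      metadata <<- read.csv(file.path(config$input_dir, "metadata.csv"),
                            stringsAsFactors = FALSE)
      waveforms <<- lapply(metadata$wav_path,
                           function(p) read_wav(p)$waveform)
    })
  }

  seg <- segmentation_params(
    signal_quantile = config$segmentation$signal_quantile,
    noise_gate_db = config$segmentation$noise_gate_db,
    min_syllable_ms = config$segmentation$min_syllable_ms,
    min_silence_ms = config$segmentation$min_silence_ms,
    hp_hz = config$segmentation$hp_hz, lp_hz = config$segmentation$lp_hz)

  features <- NULL
  if (isTRUE(config$stages$segment) && isTRUE(config$stages$features)) {
    run_stage("features", function() {
      features <<- song_feature_table(waveforms, metadata, seg = seg,
                                      per_species =
                                        config$typing$per_species)
      write.csv(features, file.path(config$out_dir, "features.csv"),
                row.names = FALSE)
      bundle$features <<- list(n_songs = nrow(features),
                               excluded = attr(features, "excluded"))
    })
  }

  if (isTRUE(config$stages$geo)) {
    run_stage("geo", function() {
      rec <- dedupe_recordings(metadata)
      rec <- breeding_season_filter(rec)
      two <- rec[rec$species %in% c("A", "B"), , drop = FALSE]
      props <- species_proportions_by_longitude(two)
      zone <- find_overlap_zone(props, config$zone$min_prop,
                                config$zone$min_count)
      bundle$geo <<- list(n_after_curation = nrow(rec),
                          zone = unclass(zone))
    })
  }

  if (isTRUE(config$stages$stats) && !is.null(features) &&
      nrow(features) > 3) {
    run_stage("stats", function() {
      two <- features[features$species %in% c("A", "B"), , drop = FALSE]
      logf <- log_transform_features(two[, song_feature_names()])
      pca <- run_pca(logf)
      pr <- procrustes_test(pca$scores[, 1:2],
                            cbind(two$longitude, two$latitude),
                            n_perm = config$stats$n_perm,
                            seed = stage_seed("stats_procrustes"))
      geo_d <- geodesic_distance_matrix(two)
      feat_d <- feature_distance_matrices(two)
      mt <- mantel_test(feat_d$overall, geo_d,
                        n_perm = config$stats$n_perm,
                        seed = stage_seed("stats_mantel"))
      glms <- fit_all_feature_glms(two, family = config$stats$glm_family)
      bundle$stats <<- list(
        pca_var_explained = pca$var_explained[1:2],
        procrustes = list(correlation = pr$correlation_stat,
                          p = pr$p_value),
        mantel_overall = list(r = mt$r, p = mt$p),
        glm_t_values = lapply(glms, function(g)
          as.list(g$coefficients[, "t"])))
    })
  }

  if (isTRUE(config$stages$classify) && !is.null(features) &&
      nrow(features) > 20) {
    run_stage("classify", function() {
      two <- features[features$species %in% c("A", "B"), , drop = FALSE]
      x <- as.matrix(two[, song_feature_names()])
      x <- log_transform_features(x)
      sp <- make_balanced_split(two, config$classify$train_frac,
                                seed = stage_seed("classify_split"))
      cfg <- classifier_config(config$classify$backend,
                               n_trees = config$classify$n_trees)
      m <- train_classifier(cfg, x[sp$train, ], two$species[sp$train],
                            seed = stage_seed("classify_train"))
      ev <- evaluate_classifier(m, x[sp$test, ], two$species[sp$test])
      pn <- permutation_null(cfg, x[sp$train, ], two$species[sp$train],
                             x[sp$test, ], two$species[sp$test],
                             n_perm = config$classify$n_perm,
                             seed = stage_seed("classify_perm"))
      bundle$classify <<- list(accuracy = ev$accuracy,
                               balanced_accuracy = ev$balanced_accuracy,
                               kappa = ev$kappa,
                               confusion = as.list(as.data.frame(
                                 as.table(ev$confusion))),
                               perm_p = pn$perm_p)
    })
  }

  if (isTRUE(config$stages$popgen)) {
    run_stage("popgen", function() {
      gm <- genetic_model(n_per_pop = config$popgen$n_per_pop,
                          seq_length = config$popgen$seq_length,
                          fixed_diffs = config$popgen$fixed_diffs,
                          within_poly_rate =
                            config$popgen$within_poly_rate,
                          seed = stage_seed("popgen"))
      aln <- generate_alignment(gm)
      am <- amova_two_level(aln)
      bundle$popgen <<- list(phi_st = am$phi_st,
                             pct_between = am$pct_between,
                             pct_within = am$pct_within)
    })
  }

  flush_bundle(bundle, config$out_dir)
  invisible(bundle)
}

flush_bundle <- function(bundle, out_dir) {
  jsonlite::write_json(bundle, file.path(out_dir, "bundle.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE, null = "null")
}
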