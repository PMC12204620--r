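# Species-classification evaluation harness: balanced and
# region-stratified splits, metrics recomputed from the confusion table,
# label-permutation nulls, per-sample vote confidence, and multi-seed
# confidence intervals.  Learner backends are pluggable behind one
# train/predict contract.

#' Balanced 75/25 train/test split
#'
#' `floor(train_frac * N)` records are sampled without replacement for
#' training (so N = 2785 yields a 697-record test set); the majority class
#' within the training set is then randomly downsampled to the minority
#' class's training count.  The test set is untouched.
#'
#' @param records data frame with a two-level `species` column (rows are
#'   addressed by index).
#' @param train_frac training fraction (default 0.75).
#' @param seed integer seed.
#' @return object of class `split_plan`: `train` and `test` row indices,
#'   `train_counts`, `mode`, `seed`.
#' @export
make_balanced_split <- function(records, train_frac = 0.75, seed = 1L) {
  species <- factor(records$species)
  if (nlevels(droplevels(species)) != 2)
    stop_fmt("make_balanced_split: exactly two classes required")
  n <- nrow(records)
  set.seed(seed)
  train <- sort(sample.int(n, floor(train_frac * n)))
  test <- setdiff(seq_len(n), train)
  counts <- table(species[train])
  if (any(counts == 0))
    stop_fmt("make_balanced_split: a class is absent from the training set")
  k <- min(counts)
  keep <- unlist(lapply(levels(species), function(lv) {
    rows <- train[species[train] == lv]
    if (length(rows) > k) sort(sample(rows, k)) else rows
  }))
  structure(list(train = sort(keep), test = test,
                 train_counts = table(droplevels(species[sort(keep)])),
                 mode = "random_balanced", seed = seed),
            class = "split_plan")
}

#' Region-stratified split around the overlap zone
#'
#' Training records are drawn only from outside the zone of overlap
#' (balanced by downsampling); the in-zone records are one test set and an
#' equal-size random out-of-zone holdout, disjoint from training, is the
#' other.
#'
#' @param records data frame with `species` and `longitude`.
#' @param zone an `overlap_zone` (list with `west_deg`, `east_deg`) or
#'   numeric `c(west, east)`.
#' @param seed integer seed.
#' @return object of class `split_plan` with `train`, `test_in_zone`,
#'   `test_out_zone`; `test` equals `test_in_zone` for compatibility.
#' @export
make_region_split <- function(records, zone, seed = 1L) {
  if (is.list(zone)) zone <- c(zone$west_deg, zone$east_deg)
  species <- factor(records$species)
  in_zone <- which(records$longitude >= zone[1] &
                     records$longitude < zone[2])
  out_zone <- setdiff(seq_len(nrow(records)), in_zone)
  if (length(in_zone) == 0 || length(out_zone) == 0)
    stop_fmt("make_region_split: both regions must be non-empty")
  set.seed(seed)
  n_hold <- length(in_zone)
  if (n_hold >= length(out_zone))
    stop_fmt("make_region_split: in-zone count (%d) exceeds available %s",
             n_hold, "out-of-zone records")
  test_out <- sort(sample(out_zone, n_hold))
  pool <- setdiff(out_zone, test_out)
  counts <- table(droplevels(species[pool]))
  if (length(counts) < 2 || any(counts == 0))
    stop_fmt("make_region_split: a class is absent from the training pool")
  k <- min(counts)
  train <- unlist(lapply(names(counts), function(lv) {
    rows <- pool[species[pool] == lv]
    if (length(rows) > k) sort(sample(rows, k)) else rows
  }))
  structure(list(train = sort(train), test = in_zone,
                 test_in_zone = in_zone, test_out_zone = test_out,
                 train_counts = table(droplevels(species[sort(train)])),
                 mode = "region_stratified", seed = seed),
            class = "split_plan")
}

#' Balanced accuracy from a 2 x 2 confusion table
#'
#' Mean of the two per-class recalls (rows = truth, columns = prediction).
#'
#' @param confusion 2 x 2 count matrix.
#' @return fraction in \[0, 1\].
#' @export
balanced_accuracy <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (any(rowSums(confusion) == 0))
    stop_fmt("balanced_accuracy: empty class row")
  mean(diag(confusion) / rowSums(confusion))
}

#' Cohen's kappa from a confusion table
#'
#' `(p_o - p_e) / (1 - p_e)` with observed agreement `p_o` and chance
#' agreement `p_e` from the marginals.
#'
#' @param confusion square count matrix (rows = truth).
#' @return kappa, or `NA` with a warning when the marginals are degenerate
#'   (`p_e` = 1).
#' @export
cohen_kappa <- function(confusion) {
  confusion <- as.matrix(confusion)
  n <- sum(confusion)
  if (n == 0) stop_fmt("cohen_kappa: empty confusion table")
  p_o <- sum(diag(confusion)) / n
  p_e <- sum(rowSums(confusion) * colSums(confusion)) / n^2
  if (abs(1 - p_e) < .Machine$double.eps^0.5) {
    warning("cohen_kappa: degenerate marginals (p_e = 1); kappa undefined",
            call. = FALSE)
    return(NA_real_)
  }
  (p_o - p_e) / (1 - p_e)
}

#' Classifier configuration
#'
#' Captures the backend and its hyperparameters; the config is echoed into
#' every evaluation result.  Defaults mirror the original workflow's setups:
#' 500-tree random forest (10-fold CV over a 10 x 16 tuning grid when
#' `tune`), gradient boosting with at most 100 rounds and early stopping
#' after 10, a 16-64-64-2 ReLU perceptron trained with Adam (lr 0.001,
#' batch 32, 100 epochs), and a 224 x 224 x 3 image CNN spec (four
#' convolution blocks of 32/128/128/128 3x3 filters, 2x2 max pooling,
#' dense 1024, softmax-2).
#'
#' @param backend one of `"rf"`, `"gbm"`, `"mlp"`, `"cnn"`, `"lda"`.
#' @param ... overrides of the backend defaults.
#' @return list of class `classifier_config`.
#' @export
classifier_config <- function(backend = c("rf", "gbm", "mlp", "cnn",
                                          "lda"), ...) {
  backend <- match.arg(backend)
  defaults <- switch(backend,
    rf = list(n_trees = 500L, min_node = 5L, mtry = NULL, tune = FALSE,
              cv_folds = 10L, grid_dim = c(10L, 16L)),
    gbm = list(n_rounds = 100L, early_stopping_rounds = 10L,
               learning_rate = 0.3, max_depth = 3L),
    mlp = list(layer_sizes = c(16L, 64L, 64L, 2L), epochs = 100L,
               batch_size = 32L, learning_rate = 0.001,
               early_stopping = TRUE),
    cnn = list(input_shape = c(224L, 224L, 3L),
               filters = c(32L, 128L, 128L, 128L), kernel = 3L,
               pool = 2L, dense = 1024L, epochs = 10L, batch_size = 32L,
               rescale = 1 / 255),
    lda = list())
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad))
    stop_fmt("classifier_config: unknown %s option(s): %s", backend,
             paste(bad, collapse = ", "))
  structure(c(list(backend = backend), utils::modifyList(defaults, over)),
            class = "classifier_config")
}

#' Train a classifier backend
#'
#' The feature backends (rf, gbm, mlp, lda) take the 16-feature table;
#' gbm and mlp inputs are centered and scaled internally using training
#' statistics.  The cnn backend validates its 224 x 224 x 3 input contract
#' but has no training engine in this environment (no deep-learning
#' framework is installed) and stops with an explicit error.
#'
#' @param config a [classifier_config()].
#' @param x training features (matrix) or, for cnn, an array
#'   n x 224 x 224 x 3.
#' @param y two-level factor of training labels.
#' @param seed integer seed.
#' @return object of class `fitted_classifier`.
#' @export
train_classifier <- function(config, x, y, seed = 1L) {
  stopifnot(inherits(config, "classifier_config"))
  y <- factor(y)
  if (config$backend == "cnn") {
    dm <- dim(x)
    if (length(dm) != 4 || !all(dm[2:4] == config$input_shape))
      stop_fmt("train_classifier: cnn accepts only %s inputs",
               paste(config$input_shape, collapse = "x"))
    stop_fmt("train_classifier: the cnn backend requires a deep-learning %s",
             "engine (none is installed in this environment)")
  }
  if (length(dim(x)) != 2)
    stop_fmt("train_classifier: feature backends need a 2-D matrix")
  x <- as.matrix(x)
  center <- NULL; scale <- NULL
  if (config$backend %in% c("gbm", "mlp")) {
    center <- colMeans(x)
    scale <- pmax(apply(x, 2, sd), .Machine$double.eps)
    x <- sweep(sweep(x, 2, center), 2, scale, "/")
  }
  fit <- switch(config$backend,
    rf = if (isTRUE(config$tune))
      rf_tune(x, y, cv_folds = config$cv_folds,
              n_trees = config$n_trees, seed = seed)$model
    else rf_train(x, y, n_trees = config$n_trees, mtry = config$mtry,
                  min_node = config$min_node, seed = seed),
    gbm = gbm_train(x, y, n_rounds = config$n_rounds,
                    learning_rate = config$learning_rate,
                    max_depth = config$max_depth,
                    early_stopping_rounds = config$early_stopping_rounds,
                    seed = seed),
    mlp = mlp_train(x, y,
                    hidden = config$layer_sizes[-c(1,
                      length(config$layer_sizes))],
                    epochs = config$epochs,
                    batch_size = config$batch_size,
                    learning_rate = config$learning_rate,
                    early_stopping = config$early_stopping, seed = seed),
    lda = MASS::lda(x, grouping = y, prior = c(0.5, 0.5)))
  structure(list(config = config, fit = fit, levels = levels(y),
                 center = center, scale = scale, seed = seed),
            class = "fitted_classifier")
}

#' @rdname train_classifier
#' @param object a `fitted_classifier`.
#' @param newdata test features.
#' @param type `"class"` or (rf only) `"votes"`.
#' @param ... unused.
#' @export
predict.fitted_classifier <- function(object, newdata,
                                      type = c("class", "votes"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (!is.null(object$center))
    newdata <- sweep(sweep(newdata, 2, object$center), 2, object$scale,
                     "/")
  if (type == "votes") {
    if (object$config$backend != "rf")
      stop_fmt("predict: per-tree votes unsupported for backend '%s'",
               object$config$backend)
    return(predict(object$fit, newdata, type = "votes"))
  }
  switch(object$config$backend,
    rf = predict(object$fit, newdata),
    gbm = predict(object$fit, newdata),
    mlp = predict(object$fit, newdata),
    lda = predict(object$fit, newdata)$class)
}

#' Evaluate a fitted classifier on a test set
#'
#' @param model a `fitted_classifier`.
#' @param x_test,y_test test features and labels.
#' @return object of class `eval_result`: `accuracy`,
#'   `balanced_accuracy`, `kappa`, `confusion` (rows = truth),
#'   `predicted`, and for rf `vote_confidence` (fraction of trees voting
#'   the true class per sample).
#' @export
evaluate_classifier <- function(model, x_test, y_test) {
  y_test <- factor(y_test, levels = model$levels)
  pred <- predict(model, x_test)
  confusion <- table(truth = y_test, predicted = factor(pred,
                                                        levels =
                                                          model$levels))
  res <- list(accuracy = sum(diag(confusion)) / sum(confusion),
              balanced_accuracy = balanced_accuracy(confusion),
              kappa = cohen_kappa(confusion),
              confusion = confusion, predicted = pred,
              config = model$config)
  if (model$config$backend == "rf") {
    v2 <- predict(model, x_test, type = "votes")  # votes for level 2
    res$vote_confidence <- ifelse(y_test == model$levels[2], v2, 1 - v2)
  }
  structure(res, class = "eval_result")
}

#' Label-permutation null for a classifier's test accuracy
#'
#' Refits the backend `n_perm` times with shuffled training labels (fixed
#' hyperparameters), records each permuted test accuracy, and returns
#' `p = (1 + #\{permuted >= observed\}) / (n_perm + 1)`.
#'
#' @param config a [classifier_config()].
#' @param x_train,y_train,x_test,y_test data (already split).
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed.
#' @return list: `observed` accuracy, `perm_accuracy` vector, `perm_p`.
#' @export
permutation_null <- function(config, x_train, y_train, x_test, y_test,
                             n_perm = 1000L, seed = 1L) {
  if (n_perm < 1) stop_fmt("permutation_null: n_perm must be >= 1")
  fit_acc <- function(labels, s) {
    m <- tryCatch(train_classifier(config, x_train, labels, seed = s),
                  error = function(e) NULL)
    if (is.null(m))   # one retry, then abort
      m <- train_classifier(config, x_train, labels, seed = s + 1L)
    mean(predict(m, x_test) == y_test)
  }
  observed <- fit_acc(y_train, seed)
  set.seed(seed)
  perms <- replicate(n_perm, sample(y_train), simplify = FALSE)
  perm_acc <- vapply(seq_len(n_perm),
                     function(b) fit_acc(perms[[b]], seed + b),
                     numeric(1))
  list(observed = observed, perm_accuracy = perm_acc,
       perm_p = (1 + sum(perm_acc >= observed)) / (n_perm + 1))
}

#' Per-sample vote-confidence map from a random forest
#'
#' @param model a `fitted_classifier` with rf backend.
#' @param x_test test features.
#' @param y_test true labels.
#' @param coords data frame with `longitude`, `latitude` per test sample.
#' @return data frame: `confidence` (fraction of trees voting the true
#'   class), `correct`, `longitude`, `latitude`.  In the binary case
#'   confidence below 0.5 is equivalent to misclassification.
#' @export
rf_vote_confidence <- function(model, x_test, y_test, coords) {
  if (model$config$backend != "rf")
    stop_fmt("rf_vote_confidence: backend '%s' has no per-tree votes",
             model$config$backend)
  y_test <- factor(y_test, levels = model$levels)
  v2 <- predict(model, x_test, type = "votes")
  conf <- ifelse(y_test == model$levels[2], v2, 1 - v2)
  data.frame(confidence = conf,
             correct = predict(model, x_test) == y_test,
             longitude = coords$longitude, latitude = coords$latitude)
}

#' Repeat split + train + test over many seeds
#'
#' @param records data frame with `species` and feature columns.
#' @param feature_cols names of the feature columns.
#' @param config a [classifier_config()].
#' @param n_seeds number of repetitions (default 100).
#' @param train_frac passed to [make_balanced_split()].
#' @param base_seed seeds used are `base_seed + 1:n_seeds`.
#' @return list: `mean_accuracy`, `ci95` (normal approximation),
#'   `accuracies` (all per-seed values), `seeds`.
#' @export
repeat_over_seeds <- function(records, feature_cols, config,
                              n_seeds = 100L, train_frac = 0.75,
                              base_seed = 0L) {
  if (n_seeds < 2) stop_fmt("repeat_over_seeds: need n_seeds >= 2")
  seeds <- base_seed + seq_len(n_seeds)
  acc <- vapply(seeds, function(s) {
    sp <- make_balanced_split(records, train_frac, seed = s)
    x <- as.matrix(records[, feature_cols])
    m <- train_classifier(config, x[sp$train, , drop = FALSE],
                          records$species[sp$train], seed = s)
    mean(predict(m, x[sp$test, , drop = FALSE]) ==
           records$species[sp$test])
  }, numeric(1))
  half <- 1.96 * sd(acc) / sqrt(n_seeds)
  list(mean_accuracy = mean(acc),
       ci95 = c(mean(acc) - half, mean(acc) + half),
       accuracies = acc, seeds = seeds)
}
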