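# classify_eval: splits, metrics, permutation nulls, confidence maps,
# multi-seed repetition, backend contract.

test_that("balanced split arithmetic matches the reference corpus counts", {
  rec <- data.frame(species = rep(c("A", "B"), c(1718, 1067)))
  sp <- make_balanced_split(rec, 0.75, seed = 1)
  expect_equal(length(sp$test), 697)                  # N = 2785 case
  expect_equal(length(intersect(sp$train, sp$test)), 0)
  expect_equal(unname(diff(range(sp$train_counts))), 0)  # balanced
  # balanced input stays balanced by construction
  rec2 <- data.frame(species = rep(c("A", "B"), each = 200))
  sp2 <- make_balanced_split(rec2, 0.75, seed = 2)
  expect_equal(length(sp2$train) + length(sp2$test) >= 400 * 0.25, TRUE)
  # same seed -> identical plan
  expect_identical(make_balanced_split(rec, 0.75, seed = 9),
                   make_balanced_split(rec, 0.75, seed = 9))
})

test_that("region split keeps training out of the zone, equal test sizes", {
  set.seed(1)
  rec <- data.frame(species = sample(c("A", "B"), 600, TRUE),
                    longitude = runif(600, -120, -70))
  sp <- make_region_split(rec, c(-102, -91), seed = 4)
  expect_true(all(rec$longitude[sp$train] < -102 |
                    rec$longitude[sp$train] >= -91))
  expect_equal(length(sp$test_in_zone), length(sp$test_out_zone))
  expect_equal(length(intersect(sp$train, sp$test_out_zone)), 0)
  expect_equal(unname(diff(range(sp$train_counts))), 0)
  # in-zone larger than available out-of-zone -> error
  rec3 <- data.frame(species = rep(c("A", "B"), 50),
                     longitude = c(runif(95, -100, -95),
                                   runif(5, -80, -70)))
  expect_error(make_region_split(rec3, c(-102, -91), seed = 1), "exceeds")
})

test_that("balanced accuracy and kappa match hand-computed tables", {
  expect_equal(balanced_accuracy(matrix(c(40, 20, 10, 30), 2)), 0.7)
  expect_equal(balanced_accuracy(diag(c(13, 57))), 1)
  expect_equal(balanced_accuracy(matrix(c(0, 0, 10, 30), 2)), 0.5)
  expect_equal(cohen_kappa(matrix(c(50, 0, 0, 50), 2)), 1)
  expect_equal(cohen_kappa(matrix(c(40, 10, 10, 40), 2)), 0.6)
  expect_warning(k <- cohen_kappa(matrix(c(10, 0, 0, 0), 2)),
                 "degenerate")
  expect_true(is.na(k))
  expect_error(balanced_accuracy(matrix(c(0, 5, 0, 5), 2)), "empty")
})

test_that("eval metrics are reproducible from the confusion table", {
  g <- two_class_gaussians(150, 0.9, d = 6, seed = 3)
  ht <- two_class_gaussians(80, 0.9, d = 6, seed = 8)
  m <- train_classifier(classifier_config("rf", n_trees = 60L),
                        g$x, g$y, seed = 2)
  ev <- evaluate_classifier(m, ht$x, ht$y)
  cm <- ev$confusion
  expect_equal(ev$accuracy, sum(diag(cm)) / sum(cm))
  expect_equal(ev$balanced_accuracy, balanced_accuracy(cm))
  expect_equal(ev$kappa, cohen_kappa(cm))
  # binary case: vote confidence below one half iff misclassified
  correct <- ev$predicted == factor(ht$y, levels = m$levels)
  expect_equal(ev$vote_confidence > 0.5, unname(correct))
})

test_that("rf_vote_confidence joins votes to coordinates", {
  g <- two_class_gaussians(100, 0.95, d = 4, seed = 5)
  m <- train_classifier(classifier_config("rf", n_trees = 40L),
                        g$x, g$y, seed = 1)
  coords <- data.frame(longitude = runif(200, -120, -70),
                       latitude = runif(200, 30, 48))
  cm <- rf_vote_confidence(m, g$x, g$y, coords)
  expect_equal(nrow(cm), 200)
  expect_equal(cm$correct, cm$confidence > 0.5)
  expect_equal(cm$longitude, coords$longitude)
  m2 <- train_classifier(classifier_config("lda"), g$x, g$y)
  expect_error(rf_vote_confidence(m2, g$x, g$y, coords), "votes")
})

test_that("permutation null attains its minimum p on separable data", {
  set.seed(6)
  n <- 80
  # separable along x1 by a wide gap; the high-variance noise dimensions
  # dominate any label-permuted fit, so permuted models cannot classify
  # the gap perfectly by accident
  x <- cbind(c(runif(n, 0, 1), runif(n, 3, 4)),
             matrix(rnorm(2 * n * 9, sd = 5), 2 * n, 9))
  y <- factor(rep(c("A", "B"), each = n))
  idx <- sample(rep(c(TRUE, FALSE), c(120, 40)))
  pn <- permutation_null(classifier_config("lda"), x[idx, ], y[idx],
                         x[!idx, ], y[!idx], n_perm = 99, seed = 3)
  expect_equal(pn$observed, 1)
  expect_equal(pn$perm_p, 1 / 100)
  expect_length(pn$perm_accuracy, 99)
  expect_error(permutation_null(classifier_config("lda"), x, y, x, y,
                                n_perm = 0), "n_perm")
})

test_that("repeat_over_seeds reports all seeds and a sane CI", {
  rec <- cbind(toy_feature_table(120, seed = 3))
  # deterministic perfect separation with within-class spread
  rec$bout_duration_ms <- ifelse(rec$species == "A", 10, 2000) *
    runif(120, 0.8, 1.2)
  out <- repeat_over_seeds(rec, song_feature_names(),
                           classifier_config("lda"), n_seeds = 8)
  expect_length(out$accuracies, 8)
  expect_equal(out$mean_accuracy, 1)
  expect_equal(unname(diff(out$ci95)), 0)
  expect_error(repeat_over_seeds(rec, song_feature_names(),
                                 classifier_config("lda"), n_seeds = 1),
               "n_seeds")
})

test_that("classifier config validates and cnn enforces its input shape", {
  expect_error(classifier_config("rf", bogus = 1), "unknown")
  cfg <- classifier_config("cnn")
  expect_equal(cfg$input_shape, c(224L, 224L, 3L))
  expect_equal(cfg$filters, c(32L, 128L, 128L, 128L))
  y <- factor(rep(c("A", "B"), 8))
  bad <- array(0, c(16, 100, 100, 3))
  expect_error(train_classifier(cfg, bad, y), "224x224x3")
  ok_shape <- array(0, c(16, 224, 224, 3))
  expect_error(train_classifier(cfg, ok_shape, y), "engine")
})

test_that("gbm/mlp centering-scaling is internal and round-trips", {
  g <- two_class_gaussians(200, 0.9, d = 5, seed = 7)
  shifted <- g$x * 100 + 5000     # wildly unscaled inputs
  m <- train_classifier(classifier_config("gbm"), shifted, g$y, seed = 1)
  expect_gt(mean(predict(m, shifted) == g$y), 0.8)
})
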