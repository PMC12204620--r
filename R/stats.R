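# The statistical suite: per-feature log-link GLMs, PCA, Fisher LDA (also
# used as the 2-D "simple linear classifier" on ordination coordinates),
# a UMAP contract backed by the python umap-learn implementation, and
# Procrustes / Mantel permutation tests.

#' Fit a log-link GLM for one song feature
#'
#' Models the raw (positive) feature as Gaussian with a log link on scaled
#' longitude, scaled latitude, a species indicator and a file-conversion
#' indicator.  Longitude and latitude are standardized to mean 0, SD 1
#' before fitting.  A Gamma family with log link is available as an
#' alternative.
#'
#' @param y positive numeric feature values (raw scale).
#' @param covariates data frame with `longitude`, `latitude`, `species`,
#'   `conversion_status`.
#' @param family `"gaussian_log"` (default) or `"gamma_log"`.
#' @return object of class `glm_fit`: coefficient table (estimate, SE,
#'   t value, p value per term) plus the fitted `model`.
#' @export
fit_feature_glm <- function(y, covariates, family = c("gaussian_log",
                                                      "gamma_log")) {
  family <- match.arg(family)
  if (any(y <= 0)) stop_fmt("fit_feature_glm: feature must be positive")
  if (anyNA(covariates)) stop_fmt("fit_feature_glm: incomplete covariates")
  dat <- data.frame(y = y,
                    lon_s = as.numeric(scale(covariates$longitude)),
                    lat_s = as.numeric(scale(covariates$latitude)),
                    species = factor(covariates$species),
                    conversion = factor(covariates$conversion_status))
  for (v in c("lon_s", "lat_s"))
    if (!is.finite(sd(dat[[v]])) || sd(dat[[v]]) == 0)
      stop_fmt("fit_feature_glm: constant covariate '%s' (singular design)",
               v)
  if (nlevels(dat$species) < 2 || nlevels(dat$conversion) < 2)
    stop_fmt("fit_feature_glm: species/conversion must each have 2 levels")
  fam <- if (family == "gaussian_log") gaussian(link = "log") else
    stats::Gamma(link = "log")
  # a least-squares fit on the log scale provides a stable starting point
  # for the log-link IRLS, which is otherwise fragile for skewed features
  start <- coef(lm(log(y) ~ lon_s + lat_s + species + conversion,
                   data = dat))
  fit <- glm(y ~ lon_s + lat_s + species + conversion, data = dat,
             family = fam, start = start,
             control = list(maxit = 100))
  if (!fit$converged)
    stop_fmt("fit_feature_glm: IRLS did not converge")
  tab <- coef(summary(fit))
  colnames(tab) <- c("estimate", "se", "t", "p")
  structure(list(coefficients = tab, family = family, model = fit),
            class = "glm_fit")
}

#' Fit the log-link GLM for every feature in a table
#'
#' @param features data frame containing the [song_feature_names()] columns
#'   plus `longitude`, `latitude`, `species`, `conversion_status`.
#' @param ... passed to [fit_feature_glm()].
#' @return named list of `glm_fit` objects.
#' @export
fit_all_feature_glms <- function(features, ...) {
  out <- list()
  for (f in intersect(song_feature_names(), names(features))) {
    out[[f]] <- tryCatch(fit_feature_glm(features[[f]], features, ...),
                         error = function(e)
                           stop_fmt("GLM for '%s': %s", f,
                                    conditionMessage(e)))
  }
  out
}

#' Principal component analysis of a feature table
#'
#' Columns are centered and scaled to unit variance (so the decomposition
#' is of the correlation structure).
#'
#' @param x numeric matrix or data frame (samples x features), no missing
#'   values.
#' @param scale. scale columns to unit variance (default TRUE).
#' @return object of class `pca_result`: `scores`, `loadings`,
#'   `var_explained` (fraction per component, non-increasing).
#' @export
run_pca <- function(x, scale. = TRUE) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop_fmt("run_pca: need at least 2 samples")
  if (anyNA(x)) stop_fmt("run_pca: missing values")
  sds <- apply(x, 2, sd)
  if (scale. && any(sds == 0))
    stop_fmt("run_pca: zero-variance column(s): %s",
             paste(colnames(x)[sds == 0], collapse = ", "))
  p <- prcomp(x, center = TRUE, scale. = scale.)
  structure(list(scores = p$x, loadings = p$rotation,
                 var_explained = p$sdev^2 / sum(p$sdev^2)),
            class = "pca_result")
}

#' Train a linear discriminant classifier and predict
#'
#' Fisher LDA with equal priors (training sets are balanced by
#' construction).  Works on the full 16-feature table or on any
#' two-column ordination (PC1/PC2, UMAP coordinates) as the "simple
#' linear classifier".
#'
#' @param x_train,x_test numeric matrices with matching columns.
#' @param y_train factor with exactly two levels present.
#' @return list with `predicted` (factor), `scores` (1-D discriminant
#'   values for the test set), and the fitted `model`.
#' @export
lda_train_predict <- function(x_train, y_train, x_test) {
  y_train <- factor(y_train)
  if (nlevels(droplevels(y_train)) < 2)
    stop_fmt("lda_train_predict: both classes must be present in training")
  fit <- MASS::lda(as.matrix(x_train), grouping = y_train,
                   prior = c(0.5, 0.5))
  pr <- predict(fit, as.matrix(x_test))
  list(predicted = pr$class, scores = as.numeric(pr$x[, 1]), model = fit)
}

#' Two-dimensional UMAP embedding
#'
#' Delegates to the reference umap-learn implementation through the
#' `python` interpreter on the PATH; the embedding is deterministic under a
#' fixed seed.  Embedding coordinates carry no absolute meaning -- only
#' downstream statistics (e.g. a 2-D linear-partition accuracy) should be
#' interpreted.
#'
#' @param x numeric matrix (samples x features).
#' @param n_neighbors,min_dist UMAP parameters (defaults 15 and 0.1).
#' @param seed integer random seed.
#' @return n x 2 matrix of embedding coordinates.
#' @export
run_umap <- function(x, n_neighbors = 15, min_dist = 0.1, seed = 42) {
  run_umap_sweep(x, data.frame(n_neighbors = n_neighbors,
                               min_dist = min_dist), seed)[[1]]
}

#' @rdname run_umap
#' @param settings data frame with columns `n_neighbors` and `min_dist`,
#'   one embedding per row (computed in a single interpreter run; useful
#'   for parameter sweeps).
#' @return for `run_umap_sweep`, a list of n x 2 matrices.
#' @export
run_umap_sweep <- function(x, settings, seed = 42) {
  x <- as.matrix(x)
  if (nrow(x) < max(settings$n_neighbors) + 1)
    stop_fmt("run_umap: need more samples than n_neighbors")
  dir <- tempfile("umap")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  write.csv(x, file.path(dir, "x.csv"), row.names = FALSE)
  write.csv(settings, file.path(dir, "settings.csv"), row.names = FALSE)
  script <- file.path(dir, "run_umap.py")
  writeLines(c(
    "import sys, warnings",
    "warnings.filterwarnings('ignore')",
    "import numpy as np",
    "import umap",
    "d = sys.argv[1]; seed = int(sys.argv[2])",
    "x = np.loadtxt(d + '/x.csv', delimiter=',', skiprows=1, ndmin=2)",
    "s = np.loadtxt(d + '/settings.csv', delimiter=',', skiprows=1,",
    "               ndmin=2)",
    "for i, (nn, md) in enumerate(s):",
    "    emb = umap.UMAP(n_neighbors=int(nn), min_dist=float(md),",
    "                    random_state=seed).fit_transform(x)",
    "    np.savetxt(d + '/emb%d.csv' % i, emb, delimiter=',')"),
    script)
  status <- system2("python", c(script, dir, as.integer(seed)),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0)
    stop_fmt("run_umap: python umap-learn backend failed (status %d)",
             status)
  lapply(seq_len(nrow(settings)) - 1, function(i) {
    as.matrix(read.csv(file.path(dir, sprintf("emb%d.csv", i)),
                       header = FALSE))
  })
}

#' Procrustes superimposition with a permutation test
#'
#' Least-squares similarity transform (translation, rotation, uniform
#' scale; no reflection unless `allow_reflection`) of the source
#' configuration onto the target.  The concordance statistic is
#' `sqrt(1 - m2)` where `m2` is the residual sum of squares normalized by
#' the target's centered sum of squares; significance is assessed by
#' permuting the rows of the source.
#'
#' @param source n x 2 matrix (e.g. PC scores).
#' @param target n x 2 matrix (e.g. longitude/latitude).
#' @param n_perm number of row permutations (default 999).
#' @param seed integer seed.
#' @param allow_reflection permit an improper rotation.
#' @param exact enumerate all `n!` row permutations instead of sampling
#'   (n <= 8 only); the p-value is then the exact fraction of
#'   permutations, identity included, with a statistic at least the
#'   observed one.
#' @return object of class `procrustes_result`: `rotation`, `scale`,
#'   `translation`, `ss_residual`, `correlation_stat`, `p_value`, `n_perm`.
#' @export
procrustes_test <- function(source, target, n_perm = 999, seed = 1,
                            allow_reflection = FALSE, exact = FALSE) {
  source <- as.matrix(source); target <- as.matrix(target)
  if (nrow(source) != nrow(target))
    stop_fmt("procrustes_test: row counts differ")
  if (nrow(source) < 3) stop_fmt("procrustes_test: need n >= 3")
  if (any(apply(target, 2, sd) == 0) || qr(scale(target, scale = FALSE))$rank
      < 2)
    stop_fmt("procrustes_test: degenerate (collinear/constant) target")
  fit <- procrustes_fit(source, target, allow_reflection)
  obs <- fit$correlation_stat
  if (exact) {
    if (nrow(source) > 8) stop_fmt("procrustes_test: exact only for n <= 8")
    perms <- all_permutations(nrow(source))
    stats <- vapply(perms, function(pm)
      procrustes_fit(source[pm, , drop = FALSE], target,
                     allow_reflection)$correlation_stat, numeric(1))
    return(structure(c(fit, list(p_value = mean(stats >= obs - 1e-12),
                                 n_perm = length(perms))),
                     class = "procrustes_result"))
  }
  set.seed(seed)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    perm <- source[sample.int(nrow(source)), , drop = FALSE]
    if (procrustes_fit(perm, target, allow_reflection)$correlation_stat >=
        obs) exceed <- exceed + 1L
  }
  structure(c(fit, list(p_value = (1 + exceed) / (n_perm + 1),
                        n_perm = n_perm)),
            class = "procrustes_result")
}

procrustes_fit <- function(source, target, allow_reflection = FALSE) {
  mx <- colMeans(target); my <- colMeans(source)
  xc <- sweep(target, 2, mx); yc <- sweep(source, 2, my)
  s <- svd(crossprod(xc, yc))
  rot <- s$v %*% t(s$u)
  dsum <- sum(s$d)
  if (!allow_reflection && det(rot) < 0) {
    v <- s$v; v[, ncol(v)] <- -v[, ncol(v)]
    rot <- v %*% t(s$u)
    dsum <- sum(s$d[-length(s$d)]) - s$d[length(s$d)]
  }
  ssy <- sum(yc^2); ssx <- sum(xc^2)
  scale <- dsum / ssy
  ss_res <- ssx - dsum^2 / ssy
  m2 <- ss_res / ssx
  list(rotation = rot, scale = scale,
       translation = mx - scale * as.numeric(my %*% rot),
       ss_residual = ss_res,
       correlation_stat = sqrt(pmax(0, 1 - m2)))
}

#' Mantel test with Spearman rank correlation
#'
#' Correlates the lower triangles of two distance matrices; the null is
#' built by simultaneous row/column permutation of the second matrix.
#' One-sided upper-tail p with the add-one correction.
#'
#' @param d1,d2 symmetric distance matrices with zero diagonals.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed.
#' @param method correlation type (default `"spearman"`).
#' @param exact enumerate all `n!` joint row/column permutations (n <= 8);
#'   the p-value is the exact upper-tail fraction, identity included.
#' @return object of class `mantel_result`: `r`, `p`, `n_perm`.
#' @export
mantel_test <- function(d1, d2, n_perm = 999, seed = 1,
                        method = c("spearman", "pearson"),
                        exact = FALSE) {
  method <- match.arg(method)
  d1 <- as.matrix(d1); d2 <- as.matrix(d2)
  if (!all(dim(d1) == dim(d2)))
    stop_fmt("mantel_test: dimension mismatch")
  if (any(abs(d1 - t(d1)) > 1e-8) || any(abs(d2 - t(d2)) > 1e-8) ||
      any(diag(d1) != 0) || any(diag(d2) != 0))
    stop_fmt("mantel_test: matrices must be symmetric with zero diagonals")
  lt <- lower.tri(d1)
  v1 <- d1[lt]
  if (sd(v1) == 0 || sd(d2[lt]) == 0)
    stop_fmt("mantel_test: constant distance vector (undefined ranks)")
  r_obs <- cor(v1, d2[lt], method = method)
  n <- nrow(d1)
  if (exact) {
    if (n > 8) stop_fmt("mantel_test: exact only for n <= 8")
    stats <- vapply(all_permutations(n), function(pm)
      cor(v1, d2[pm, pm][lt], method = method), numeric(1))
    return(structure(list(r = r_obs, p = mean(stats >= r_obs - 1e-12),
                          n_perm = length(stats)),
                     class = "mantel_result"))
  }
  set.seed(seed)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    pm <- sample.int(n)
    if (cor(v1, d2[pm, pm][lt], method = method) >= r_obs)
      exceed <- exceed + 1L
  }
  structure(list(r = r_obs, p = (1 + exceed) / (n_perm + 1),
                 n_perm = n_perm),
            class = "mantel_result")
}

# all permutations of 1:n, lexicographic
all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    rest <- all_permutations(n - 1L)
    for (r in rest) out[[length(out) + 1L]] <-
        c(i, setdiff(seq_len(n), i)[r])
  }
  out
}

#' Overall and per-feature distance matrices from a feature table
#'
#' The overall matrix is the Euclidean distance over the 16 raw features;
#' per-feature matrices are absolute differences of single features (for
#' per-feature isolation-by-distance tests).
#'
#' @param features data frame containing the [song_feature_names()]
#'   columns.
#' @return list with `overall` (matrix) and `per_feature` (named list of
#'   matrices).
#' @export
feature_distance_matrices <- function(features) {
  cols <- intersect(song_feature_names(), names(features))
  x <- as.matrix(features[, cols, drop = FALSE])
  if (anyNA(x)) stop_fmt("feature_distance_matrices: missing values")
  per <- lapply(cols, function(f) {
    v <- x[, f]
    abs(outer(v, v, "-"))
  })
  names(per) <- cols
  list(overall = as.matrix(dist(x)), per_feature = per)
}
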