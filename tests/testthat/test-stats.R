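# species_stats: GLMs, PCA, LDA, Procrustes and Mantel permutation
# machinery (with exhaustive oracles at n = 4), distance matrices.

local_perms <- function(n) {
  # independent permutation enumerator for the oracles below
  if (n == 1) return(list(1L))
  do.call(c, lapply(seq_len(n), function(i)
    lapply(local_perms(n - 1L), function(r)
      c(i, setdiff(seq_len(n), i)[r]))))
}

test_that("log-link GLM recovers simulated effects within 2 SE", {
  set.seed(18)
  n <- 600
  cov <- data.frame(longitude = rnorm(n, -95, 10),
                    latitude = rnorm(n, 40, 4),
                    species = sample(c("A", "B"), n, TRUE),
                    conversion_status = sample(c("converted",
                                                 "unconverted"), n, TRUE))
  lon_s <- as.numeric(scale(cov$longitude))
  y <- exp(1 + 0.5 * lon_s - 0.3 * (cov$species == "B")) +
    rnorm(n, 0, 0.05)
  fit <- fit_feature_glm(y, cov)
  co <- fit$coefficients
  expect_lt(abs(co["lon_s", "estimate"] - 0.5), 2 * co["lon_s", "se"])
  expect_lt(abs(co["speciesB", "estimate"] + 0.3),
            2 * co["speciesB", "se"])
  expect_equal(co[, "t"], co[, "estimate"] / co[, "se"])
  # zero-effect covariate is not significant here
  expect_gt(co["lat_s", "p"], 0.001)
  # constant covariate -> singular design rejected
  cov2 <- cov; cov2$latitude <- 40
  expect_error(fit_feature_glm(y, cov2), "singular")
})

test_that("GLM type-I error is calibrated near alpha", {
  set.seed(4)
  reject <- 0L; nsim <- 300L
  for (b in seq_len(nsim)) {
    n <- 120
    cov <- data.frame(longitude = rnorm(n), latitude = rnorm(n),
                      species = sample(c("A", "B"), n, TRUE),
                      conversion_status = sample(c("converted",
                                                   "unconverted"), n,
                                                 TRUE))
    y <- exp(1 + 0.4 * as.numeric(scale(cov$longitude))) + rnorm(n, 0, .1)
    # latitude has a true zero effect
    if (fit_feature_glm(y, cov)$coefficients["lat_s", "p"] < 0.05)
      reject <- reject + 1L
  }
  rate <- reject / nsim
  expect_lt(abs(rate - 0.05), 1.96 * sqrt(0.05 * 0.95 / nsim) + 0.01)
})

test_that("PCA matches closed-form eigenstructure and validates input", {
  set.seed(5)
  x <- cbind(rnorm(4000, sd = 2), rnorm(4000, sd = 1))
  p <- run_pca(x, scale. = FALSE)
  expect_equal(p$var_explained, c(0.8, 0.2), tolerance = 0.03)
  expect_lt(abs(abs(p$loadings[1, 1]) - 1), 0.05)   # PC1 along axis 1
  expect_equal(colMeans(p$scores), c(PC1 = 0, PC2 = 0), tolerance = 1e-12)
  expect_true(all(diff(p$var_explained) <= 1e-12))
  expect_lt(abs(sum(crossprod(p$loadings) - diag(2))), 1e-8)
  x2 <- cbind(x, 1)
  colnames(x2) <- c("a", "b", "const")
  expect_error(run_pca(x2), "const")
})

test_that("LDA hits the analytic Bayes rate on known Gaussians", {
  g <- two_class_gaussians(1000, 0.85, d = 4, seed = 12)
  ht <- two_class_gaussians(1000, 0.85, d = 4, seed = 77)
  fit <- lda_train_predict(g$x, g$y, ht$x)
  expect_lt(abs(mean(fit$predicted == ht$y) - 0.85), 0.03)
  expect_length(fit$scores, 2000)
  # identical class distributions: chance accuracy
  set.seed(3)
  xr <- matrix(rnorm(400 * 3), 400, 3)
  yr <- factor(rep(c("A", "B"), 200))
  fit2 <- lda_train_predict(xr[1:300, ], yr[1:300], xr[301:400, ])
  expect_lt(abs(mean(fit2$predicted == yr[301:400]) - 0.5), 0.15)
  expect_error(lda_train_predict(xr, factor(rep("A", 400)), xr), "classes")
})

test_that("procrustes is exact on similarity transforms and matches vegan", {
  set.seed(9)
  src <- matrix(rnorm(24), 12, 2)
  theta <- 0.7
  rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  tgt <- 2.5 * src %*% rot + matrix(c(3, -1), 12, 2, byrow = TRUE)
  fit <- songcline:::procrustes_fit(src, tgt)
  expect_lt(fit$ss_residual, 1e-18)
  expect_equal(fit$correlation_stat, 1)
  expect_equal(crossprod(fit$rotation), diag(2), tolerance = 1e-12)
  # correlation_stat invariant to similarity transforms of the source
  src2 <- 0.3 * src %*% rot + 5
  tgt2 <- matrix(rnorm(24), 12, 2)
  expect_equal(songcline:::procrustes_fit(src, tgt2)$correlation_stat,
               songcline:::procrustes_fit(src2, tgt2)$correlation_stat,
               tolerance = 1e-9)
  # agreement with vegan's statistic (vegan permits reflection)
  s1 <- songcline:::procrustes_fit(src, tgt2, allow_reflection = TRUE)
  v <- vegan::procrustes(tgt2, src, symmetric = FALSE)
  expect_equal(s1$ss_residual, v$ss, tolerance = 1e-9)
  expect_error(procrustes_test(src, cbind(1:12, 2 * (1:12))),
               "degenerate")
})

test_that("procrustes exact p at n = 4 equals the exhaustive oracle", {
  set.seed(21)
  for (rep in 1:3) {
    src <- matrix(rnorm(8), 4, 2)
    tgt <- matrix(rnorm(8), 4, 2)
    res <- procrustes_test(src, tgt, exact = TRUE,
                           allow_reflection = TRUE)
    # oracle: enumerate all 24 row permutations, statistic via vegan
    stats <- vapply(local_perms(4), function(pm) {
      v <- vegan::procrustes(tgt, src[pm, , drop = FALSE],
                             symmetric = TRUE)
      sqrt(1 - v$ss)
    }, numeric(1))
    obs <- sqrt(1 - vegan::procrustes(tgt, src, symmetric = TRUE)$ss)
    expect_equal(res$p_value, mean(stats >= obs - 1e-12))
  }
})

test_that("mantel matches vegan and its exhaustive oracle", {
  set.seed(14)
  c1 <- matrix(rnorm(24), 12, 2)
  c2 <- c1 + matrix(rnorm(24, 0, 0.4), 12, 2)
  d1 <- as.matrix(dist(c1)); d2 <- as.matrix(dist(c2))
  mt <- mantel_test(d1, d2, n_perm = 999, seed = 2)
  mv <- vegan::mantel(d1, d2, method = "spearman", permutations = 99)
  expect_equal(mt$r, mv$statistic)
  expect_equal(mantel_test(d1, d1, n_perm = 9, seed = 1)$r, 1)
  expect_gt(mt$p, 0)                       # +1 correction: never zero

  # exact p at n = 4 against an independent enumeration
  for (rep in 1:3) {
    a <- as.matrix(dist(matrix(rnorm(8), 4, 2)))
    b <- as.matrix(dist(matrix(rnorm(8), 4, 2)))
    res <- mantel_test(a, b, exact = TRUE)
    lt <- lower.tri(a)
    stats <- vapply(local_perms(4), function(pm)
      cor(a[lt], b[pm, pm][lt], method = "spearman"), numeric(1))
    expect_equal(res$p, mean(stats >= res$r - 1e-12))
  }

  # unrelated point sets: r near zero
  set.seed(15)
  da <- as.matrix(dist(matrix(rnorm(60), 30, 2)))
  db <- as.matrix(dist(matrix(rnorm(60), 30, 2)))
  expect_lt(abs(mantel_test(da, db, n_perm = 99)$r), 0.25)
  expect_error(mantel_test(da[1:3, 1:3] * 0, db[1:3, 1:3]), "constant")
})

test_that("permutation p-values are uniform under the null", {
  set.seed(33)
  ps <- vapply(1:400, function(b) {
    d1 <- as.matrix(dist(matrix(rnorm(12), 6, 2)))
    d2 <- as.matrix(dist(matrix(rnorm(12), 6, 2)))
    mantel_test(d1, d2, n_perm = 99, seed = b)$p
  }, numeric(1))
  expect_true(all(ps > 0))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("feature distance matrices match hand arithmetic", {
  tab <- toy_feature_table(3, seed = 8)
  tab[2, song_feature_names()] <- tab[1, song_feature_names()]
  tab[3, song_feature_names()] <- tab[1, song_feature_names()]
  tab[3, "max_freq_hz"] <- tab[3, "max_freq_hz"] + 7
  fd <- feature_distance_matrices(tab)
  expect_equal(fd$overall[1, 2], 0)
  expect_equal(fd$overall[1, 3], 7)
  expect_equal(fd$per_feature$max_freq_hz[1, 3], 7)
  expect_equal(fd$per_feature$bout_duration_ms[1, 3], 0)
  # 3x3 hand example on one feature
  v <- as.numeric(tab$n_syllables)
  expect_equal(fd$per_feature$n_syllables,
               abs(outer(v, v, "-")))
})
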