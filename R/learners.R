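# Self-contained learners used as classifier backends: a CART-style tree
# (gini for classification, variance for regression) grown on a compiled
# split finder, a bagged random forest exposing per-tree votes, a logistic
# gradient-boosting machine with early stopping, and a two-hidden-layer
# multilayer perceptron trained with Adam.  The external packages these
# mirror (ranger, xgboost, torch) are not available in the target
# environment, so the algorithms are implemented here behind the same
# evaluation contract.

# ---- CART tree ------------------------------------------------------------

# Grow one tree; y is numeric (0/1 for classification).  Returns a flat
# node table: feature (0 = leaf), threshold, left/right child, value
# (class-1 fraction or mean response).
grow_tree <- function(x, y, idx, mtry, min_node, max_depth, classify) {
  nodes <- list()
  grow <- function(idx, depth) {
    value <- mean(y[idx + 1L])
    node <- list(feature = 0L, threshold = NA_real_, left = 0L, right = 0L,
                 value = value)
    if (length(idx) >= 2L * min_node && depth < max_depth &&
        (!classify || (value > 0 && value < 1))) {
      feats <- sample.int(ncol(x), mtry) - 1L
      sp <- cpp_best_split(x, y, idx, feats, min_node, classify)
      if (sp$feature >= 0L) {
        go_left <- x[idx + 1L, sp$feature + 1L] <= sp$threshold
        node$feature <- sp$feature + 1L
        node$threshold <- sp$threshold
        nodes[[length(nodes) + 1L]] <<- node     # placeholder, patched below
        me <- length(nodes)
        nodes[[me]]$left <<- grow(idx[go_left], depth + 1L)
        nodes[[me]]$right <<- grow(idx[!go_left], depth + 1L)
        return(me)
      }
    }
    nodes[[length(nodes) + 1L]] <<- node
    length(nodes)
  }
  root <- grow(idx, 0L)
  tab <- do.call(rbind, lapply(nodes, function(n)
    c(n$feature, n$threshold, n$left, n$right, n$value)))
  colnames(tab) <- c("feature", "threshold", "left", "right", "value")
  list(nodes = tab, root = root)
}

# Vectorized prediction: route all rows down the tree together.
predict_tree <- function(tree, x) {
  out <- numeric(nrow(x))
  route <- function(node, rows) {
    nd <- tree$nodes[node, ]
    if (nd["feature"] == 0) {
      out[rows] <<- nd["value"]
      return(invisible())
    }
    left <- x[rows, nd["feature"]] <= nd["threshold"]
    if (any(left)) route(nd["left"], rows[left])
    if (any(!left)) route(nd["right"], rows[!left])
  }
  route(tree$root, seq_len(nrow(x)))
  out
}

# ---- random forest --------------------------------------------------------

#' Random forest classifier with per-tree votes
#'
#' Bagged CART trees with gini splits on a random feature subset per node.
#'
#' @param x numeric matrix (samples x features).
#' @param y two-level factor.
#' @param n_trees number of trees (default 500).
#' @param mtry features tried per split (default `floor(sqrt(p))`).
#' @param min_node minimum samples per leaf (default 5).
#' @param max_depth maximum tree depth.
#' @param seed integer seed.
#' @return object of class `rf_model`.
#' @export
rf_train <- function(x, y, n_trees = 500L, mtry = NULL, min_node = 5L,
                     max_depth = 30L, seed = 1L) {
  x <- as.matrix(x)
  y <- factor(y)
  stopifnot(nlevels(y) == 2)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x))))
  y01 <- as.numeric(y) - 1
  set.seed(seed)
  trees <- vector("list", n_trees)
  for (b in seq_len(n_trees)) {
    boot <- sample.int(nrow(x), replace = TRUE) - 1L
    trees[[b]] <- grow_tree(x, y01, boot, mtry, min_node, max_depth, TRUE)
  }
  structure(list(trees = trees, levels = levels(y), mtry = mtry,
                 min_node = min_node, n_trees = n_trees),
            class = "rf_model")
}

#' @rdname rf_train
#' @param object fitted `rf_model`.
#' @param newdata matrix of test samples.
#' @param type `"class"` for labels, `"votes"` for the per-sample fraction
#'   of trees voting the second level.
#' @param ... unused.
#' @export
predict.rf_model <- function(object, newdata, type = c("class", "votes"),
                             ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  votes <- rowMeans(vapply(object$trees,
                           function(tr) as.numeric(predict_tree(tr,
                                                                newdata) >
                                                     0.5),
                           numeric(nrow(newdata))))
  if (type == "votes") return(votes)
  factor(object$levels[1 + (votes > 0.5)], levels = object$levels)
}

#' Tune a random forest over an mtry x min_node grid by k-fold CV
#'
#' Evaluates every combination of `mtry_grid` and `min_node_grid` (the
#' default grid is 10 x 16 over the number of candidate predictors per
#' split and the minimum node size) by cross-validated accuracy and
#' refits on the full data with the best pair.
#'
#' @inheritParams rf_train
#' @param mtry_grid,min_node_grid candidate values.
#' @param cv_folds number of folds (default 10).
#' @return list: `model` (fitted on all data), `best` (chosen pair),
#'   `cv_accuracy` (grid matrix).
#' @export
rf_tune <- function(x, y, mtry_grid = NULL, min_node_grid = NULL,
                    cv_folds = 10L, n_trees = 100L, seed = 1L) {
  x <- as.matrix(x); y <- factor(y)
  if (is.null(mtry_grid))
    mtry_grid <- unique(pmax(1L, round(seq(1, ncol(x), length.out = 10))))
  if (is.null(min_node_grid)) min_node_grid <- unique(round(seq(1, 31,
                                                                2)))
  set.seed(seed)
  fold <- sample(rep_len(seq_len(cv_folds), nrow(x)))
  acc <- matrix(NA_real_, length(mtry_grid), length(min_node_grid),
                dimnames = list(mtry_grid, min_node_grid))
  for (i in seq_along(mtry_grid)) for (j in seq_along(min_node_grid)) {
    hits <- 0L
    for (k in seq_len(cv_folds)) {
      tr <- fold != k
      m <- rf_train(x[tr, , drop = FALSE], y[tr], n_trees = n_trees,
                    mtry = mtry_grid[i], min_node = min_node_grid[j],
                    seed = seed + k)
      hits <- hits + sum(predict(m, x[!tr, , drop = FALSE]) == y[!tr])
    }
    acc[i, j] <- hits / nrow(x)
  }
  best <- which(acc == max(acc), arr.ind = TRUE)[1, ]
  list(model = rf_train(x, y, n_trees = n_trees,
                        mtry = mtry_grid[best[1]],
                        min_node = min_node_grid[best[2]], seed = seed),
       best = c(mtry = mtry_grid[best[1]],
                min_node = min_node_grid[best[2]]),
       cv_accuracy = acc)
}

# ---- gradient boosting ----------------------------------------------------

#' Gradient boosting machine for binary classification
#'
#' Newton-step logistic boosting with depth-limited regression trees, a
#' softmax/log-loss objective (the two-class case of the multiclass
#' softmax), a maximum of `n_rounds` boosting iterations, and early
#' stopping when the validation log loss fails to improve for
#' `early_stopping_rounds` consecutive rounds.
#'
#' @param x numeric matrix (callers should center and scale).
#' @param y two-level factor.
#' @param n_rounds maximum boosting iterations (default 100).
#' @param learning_rate shrinkage (default 0.3).
#' @param max_depth tree depth (default 3).
#' @param early_stopping_rounds patience on validation log loss
#'   (default 10).
#' @param validation_frac fraction held out for early stopping.
#' @param seed integer seed.
#' @return object of class `gbm_model`.
#' @export
gbm_train <- function(x, y, n_rounds = 100L, learning_rate = 0.3,
                      max_depth = 3L, early_stopping_rounds = 10L,
                      validation_frac = 0.2, seed = 1L) {
  x <- as.matrix(x); y <- factor(y)
  stopifnot(nlevels(y) == 2)
  y01 <- as.numeric(y) - 1
  set.seed(seed)
  val <- sample.int(nrow(x), max(1L, round(validation_frac * nrow(x))))
  tr <- setdiff(seq_len(nrow(x)), val)
  f_tr <- rep(0, length(tr)); f_val <- rep(0, length(val))
  f0 <- stats::qlogis(mean(pmin(pmax(y01[tr], 1e-3), 1 - 1e-3)))
  f_tr <- f_tr + f0; f_val <- f_val + f0
  trees <- list()
  best_ll <- Inf; best_round <- 0L; stale <- 0L
  for (m in seq_len(n_rounds)) {
    p <- stats::plogis(f_tr)
    grad <- y01[tr] - p
    tree <- grow_tree(x[tr, , drop = FALSE], grad,
                      seq_along(tr) - 1L, mtry = ncol(x),
                      min_node = 10L, max_depth = max_depth,
                      classify = FALSE)
    # Newton leaf values: sum(grad) / sum(p (1 - p)) per leaf
    leaf_tr <- leaf_of(tree, x[tr, , drop = FALSE])
    hess <- p * (1 - p)
    num <- tapply(grad, leaf_tr, sum)
    den <- tapply(hess, leaf_tr, sum)
    gamma <- num / pmax(den, 1e-12)
    tree$nodes[as.integer(names(gamma)), "value"] <- gamma
    trees[[m]] <- tree
    f_tr <- f_tr + learning_rate * gamma[as.character(leaf_tr)]
    f_val <- f_val + learning_rate *
      tree_leaf_values(tree, x[val, , drop = FALSE])
    pv <- stats::plogis(f_val)
    ll <- -mean(y01[val] * log(pmax(pv, 1e-12)) +
                  (1 - y01[val]) * log(pmax(1 - pv, 1e-12)))
    if (ll < best_ll - 1e-8) { best_ll <- ll; best_round <- m; stale <- 0L }
    else {
      stale <- stale + 1L
      if (stale >= early_stopping_rounds) break
    }
  }
  structure(list(trees = trees[seq_len(best_round)], f0 = f0,
                 learning_rate = learning_rate, levels = levels(y),
                 best_round = best_round, val_logloss = best_ll),
            class = "gbm_model")
}

leaf_of <- function(tree, x) {
  leaf <- integer(nrow(x))
  route <- function(node, rows) {
    nd <- tree$nodes[node, ]
    if (nd["feature"] == 0) { leaf[rows] <<- node; return(invisible()) }
    left <- x[rows, nd["feature"]] <= nd["threshold"]
    if (any(left)) route(nd["left"], rows[left])
    if (any(!left)) route(nd["right"], rows[!left])
  }
  route(tree$root, seq_len(nrow(x)))
  leaf
}

tree_leaf_values <- function(tree, x) {
  tree$nodes[leaf_of(tree, x), "value"]
}

#' @rdname gbm_train
#' @param object fitted `gbm_model`.
#' @param newdata matrix of test samples.
#' @param type `"class"` or `"prob"` (probability of the second level).
#' @param ... unused.
#' @export
predict.gbm_model <- function(object, newdata, type = c("class", "prob"),
                              ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  f <- rep(object$f0, nrow(newdata))
  for (tree in object$trees)
    f <- f + object$learning_rate * tree_leaf_values(tree, newdata)
  p <- stats::plogis(f)
  if (type == "prob") return(p)
  factor(object$levels[1 + (p > 0.5)], levels = object$levels)
}

# ---- multilayer perceptron ------------------------------------------------

#' Multilayer perceptron classifier (16 -> 64 -> 64 -> 2)
#'
#' Fully connected feedforward network with two ReLU hidden layers of 64
#' units, a log-softmax output, unweighted cross-entropy loss, and the
#' Adam optimizer at learning rate 0.001, batch size 32, up to 100
#' epochs.  By default training stops early (weights restored to the
#' best epoch) when the cross-entropy on a held-out validation fraction
#' stops improving for `patience` epochs; without it the network
#' overtrains badly on noisy features.  Set `early_stopping = FALSE` for
#' the literal fixed-epoch schedule.  Callers should center and scale
#' the inputs.
#'
#' @param x numeric matrix.
#' @param y two-level factor.
#' @param hidden hidden layer widths (default `c(64, 64)`).
#' @param epochs maximum training epochs (default 100).
#' @param batch_size minibatch size (default 32).
#' @param learning_rate Adam step size (default 0.001).
#' @param early_stopping monitor a validation split (default TRUE).
#' @param val_frac validation fraction for early stopping.
#' @param patience epochs without validation improvement before stopping.
#' @param seed integer seed (weights, validation split and batch order).
#' @return object of class `mlp_model` (weights plus the layer sizes echo).
#' @export
mlp_train <- function(x, y, hidden = c(64L, 64L), epochs = 100L,
                      batch_size = 32L, learning_rate = 0.001,
                      early_stopping = TRUE, val_frac = 0.15,
                      patience = 10L, seed = 1L) {
  x <- as.matrix(x); y <- factor(y)
  stopifnot(nlevels(y) == 2)
  yi <- as.integer(y)                     # 1 or 2
  sizes <- c(ncol(x), hidden, 2L)
  set.seed(seed)
  if (early_stopping) {
    val <- sample.int(nrow(x), max(2L, round(val_frac * nrow(x))))
    tr_rows <- setdiff(seq_len(nrow(x)), val)
  } else {
    val <- integer(0)
    tr_rows <- seq_len(nrow(x))
  }
  W <- list(); b <- list()
  for (l in seq_len(length(sizes) - 1L)) {
    W[[l]] <- matrix(rnorm(sizes[l] * sizes[l + 1],
                           sd = sqrt(2 / sizes[l])),
                     sizes[l], sizes[l + 1])
    b[[l]] <- rep(0, sizes[l + 1])
  }
  mW <- lapply(W, function(w) w * 0); vW <- mW
  mb <- lapply(b, function(v) v * 0); vb <- mb
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0L
  nl <- length(W)
  fwd <- function(W, b, a) {
    for (l in seq_len(nl)) {
      z <- sweep(a %*% W[[l]], 2, b[[l]], "+")
      a <- if (l < nl) pmax(z, 0) else z
    }
    a
  }
  best_loss <- Inf; best_W <- W; best_b <- b; stale <- 0L
  for (ep in seq_len(epochs)) {
    ord <- sample(tr_rows)
    for (start in seq(1L, length(ord), by = batch_size)) {
      rows <- ord[start:min(start + batch_size - 1L, length(ord))]
      a <- list(x[rows, , drop = FALSE])
      for (l in seq_len(nl)) {
        z <- sweep(a[[l]] %*% W[[l]], 2, b[[l]], "+")
        a[[l + 1]] <- if (l < nl) pmax(z, 0) else z
      }
      logits <- a[[nl + 1]]
      pm <- exp(logits - apply(logits, 1, max))
      pm <- pm / rowSums(pm)
      delta <- pm
      delta[cbind(seq_along(rows), yi[rows])] <-
        delta[cbind(seq_along(rows), yi[rows])] - 1
      delta <- delta / length(rows)
      step <- step + 1L
      for (l in rev(seq_len(nl))) {
        gW <- crossprod(a[[l]], delta)
        gb <- colSums(delta)
        if (l > 1) delta <- (delta %*% t(W[[l]])) * (a[[l]] > 0)
        mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
        vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
        mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
        vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
        corr1 <- 1 - beta1^step; corr2 <- 1 - beta2^step
        W[[l]] <- W[[l]] - learning_rate * (mW[[l]] / corr1) /
          (sqrt(vW[[l]] / corr2) + eps)
        b[[l]] <- b[[l]] - learning_rate * (mb[[l]] / corr1) /
          (sqrt(vb[[l]] / corr2) + eps)
      }
    }
    if (early_stopping) {
      logits <- fwd(W, b, x[val, , drop = FALSE])
      pm <- exp(logits - apply(logits, 1, max))
      pm <- pm / rowSums(pm)
      vloss <- -mean(log(pmax(pm[cbind(seq_along(val), yi[val])],
                              1e-12)))
      if (vloss < best_loss - 1e-6) {
        best_loss <- vloss; best_W <- W; best_b <- b; stale <- 0L
      } else {
        stale <- stale + 1L
        if (stale >= patience) break
      }
    }
  }
  if (early_stopping) { W <- best_W; b <- best_b }
  structure(list(W = W, b = b, levels = levels(y),
                 layer_sizes = sizes, epochs_run = ep),
            class = "mlp_model")
}

#' @rdname mlp_train
#' @param object fitted `mlp_model`.
#' @param newdata matrix of test samples.
#' @param type `"class"` or `"prob"`.
#' @param ... unused.
#' @export
predict.mlp_model <- function(object, newdata, type = c("class", "prob"),
                              ...) {
  type <- match.arg(type)
  a <- as.matrix(newdata)
  nl <- length(object$W)
  for (l in seq_len(nl)) {
    z <- sweep(a %*% object$W[[l]], 2, object$b[[l]], "+")
    a <- if (l < nl) pmax(z, 0) else z
  }
  pm <- exp(a - apply(a, 1, max))
  pm <- pm / rowSums(pm)
  if (type == "prob") return(pm[, 2])
  factor(object$levels[max.col(pm)], levels = object$levels)
}
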