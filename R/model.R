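# Class-balanced random forest.
#
# Each of the B trees is grown on a small bootstrap (a fraction of the
# training instances, drawn with replacement) in which the minority class
# is then oversampled to an exact 50/50 balance. Trees are unpruned CART
# trees (Gini impurity) choosing from a random feature subset at every
# split. The fraction of trees voting positive is the predicted rearrest
# likelihood. Out-of-bag (OOB) sets -- instances absent from the
# pre-oversampling bootstrap -- support permutation importance.
#
# The trees are grown by the package itself: off-the-shelf forests do not
# expose the tiny-bootstrap-then-balance scheme or its OOB bookkeeping.

#' Random forest configuration
#'
#' @param n_trees Number of trees B.
#' @param per_tree_fraction Fraction of the training set drawn (with
#'   replacement) for each tree before balancing.
#' @param features_per_split Features considered at each split; default
#'   `ceiling(sqrt(p))` chosen at fit time.
#' @param nf Number of most-important features kept by the two-stage
#'   selection ([select_and_retrain()]); default all.
#' @param seed Integer seed.
#' @return An object of class `rf_config`.
#' @export
rf_config <- function(n_trees = 300L, per_tree_fraction = 0.05,
                      features_per_split = NULL, nf = NULL, seed = 1L) {
  assert_that(n_trees >= 1, "n_trees must be at least 1")
  assert_that(per_tree_fraction > 0 && per_tree_fraction <= 1,
              "per_tree_fraction must lie in (0, 1]")
  structure(list(n_trees = as.integer(n_trees),
                 per_tree_fraction = per_tree_fraction,
                 features_per_split = features_per_split,
                 nf = nf, seed = as.integer(seed)),
            class = "rf_config")
}

# grow one unpruned CART tree (Gini) with random feature subsets per split;
# nodes are stored in parallel vectors, children after parents, so a single
# forward pass suffices for prediction. Leaf ties predict the negative class.
grow_tree <- function(X, y, mtry) {
  feature <- integer(0)
  thresh <- numeric(0)
  left <- integer(0)
  right <- integer(0)
  pred <- integer(0)
  new_node <- function() {
    feature[length(feature) + 1L] <<- NA_integer_
    thresh[length(thresh) + 1L] <<- NA_real_
    left[length(left) + 1L] <<- NA_integer_
    right[length(right) + 1L] <<- NA_integer_
    pred[length(pred) + 1L] <<- NA_integer_
    length(feature)
  }
  p <- ncol(X)
  grow <- function(rows) {
    id <- new_node()
    yy <- y[rows]
    n1 <- sum(yy)
    n <- length(rows)
    pred[id] <<- if (n1 * 2L > n) 1L else 0L
    if (n1 == 0L || n1 == n || n < 2L) return(id)
    feats <- if (mtry >= p) seq_len(p) else sample.int(p, mtry)
    best <- NULL
    best_gini <- (2 * n1 * (n - n1) / n)  # parent impurity * n (Gini sum)
    for (j in feats) {
      xv <- X[rows, j]
      ord <- order(xv)
      xs <- xv[ord]
      ys <- yy[ord]
      cum1 <- cumsum(ys)
      cumn <- seq_len(n)
      valid <- which(diff(xs) > 0)
      if (length(valid) == 0L) next
      nl <- cumn[valid]
      n1l <- cum1[valid]
      nr <- n - nl
      n1r <- n1 - n1l
      gini <- 2 * n1l * (nl - n1l) / nl + 2 * n1r * (nr - n1r) / nr
      k <- which.min(gini)
      if (gini[k] < best_gini - 1e-12) {
        best_gini <- gini[k]
        # threshold at the left order statistic (rule x <= thr): the tree
        # then depends on feature order only, so predictions are invariant
        # under strictly monotone feature transforms
        best <- list(j = j, thr = xs[valid[k]])
      }
    }
    if (is.null(best)) return(id)
    go_left <- X[rows, best$j] <= best$thr
    feature[id] <<- best$j
    thresh[id] <<- best$thr
    left[id] <<- grow(rows[go_left])
    right[id] <<- grow(rows[!go_left])
    id
  }
  grow(seq_along(y))
  list(feature = feature, thresh = thresh, left = left, right = right,
       pred = pred)
}

# vectorized class prediction for one tree on a feature matrix
predict_tree <- function(tree, X) {
  n <- nrow(X)
  node <- rep(1L, n)
  out <- integer(n)
  for (k in seq_along(tree$feature)) {
    rows <- which(node == k)
    if (length(rows) == 0L) next
    if (is.na(tree$feature[k])) {
      out[rows] <- tree$pred[k]
    } else {
      goes_left <- X[rows, tree$feature[k]] <= tree$thresh[k]
      node[rows[goes_left]] <- tree$left[k]
      node[rows[!goes_left]] <- tree$right[k]
    }
  }
  out
}

#' Train a class-balanced random forest
#'
#' For each tree: draw `ceiling(per_tree_fraction * n)` instances with
#' replacement, oversample the minority class within the bootstrap to an
#' exact 50/50 balance, and grow an unpruned Gini CART tree choosing from
#' `features_per_split` randomly selected features at each split. The OOB
#' set of a tree is the set of instances absent from its
#' pre-oversampling bootstrap.
#'
#' @param X Numeric feature matrix (n x p), no missing values.
#' @param y Binary labels (0/1), both classes present.
#' @param cfg An [rf_config()].
#' @return An object of class `rf_model` with fields `trees`, `oob_sets`,
#'   `boot_sets` (the balanced per-tree training index sets),
#'   `features` (column names used), `cfg`.
#' @export
train_rf <- function(X, y, cfg = rf_config()) {
  X <- as.matrix(X)
  y <- as.integer(y)
  n <- nrow(X)
  assert_that(n >= 10, "at least 10 training instances are required")
  assert_that(length(unique(y)) == 2L, "both classes must be present in y")
  assert_that(!anyNA(X), "X must not contain missing values (impute first)")
  p <- ncol(X)
  mtry <- cfg$features_per_split
  if (is.null(mtry)) mtry <- ceiling(sqrt(p))
  n_boot <- ceiling(cfg$per_tree_fraction * n)
  seeds <- spawn_seeds(cfg$seed, cfg$n_trees)
  trees <- vector("list", cfg$n_trees)
  oob_sets <- vector("list", cfg$n_trees)
  boot_sets <- vector("list", cfg$n_trees)
  for (b in seq_len(cfg$n_trees)) {
    res <- with_seed(seeds[b], {
      idx <- sample.int(n, n_boot, replace = TRUE)
      oob <- setdiff(seq_len(n), idx)
      pos <- idx[y[idx] == 1L]
      neg <- idx[y[idx] == 0L]
      resample <- function(v, k) v[sample.int(length(v), k, replace = TRUE)]
      if (length(pos) > 0L && length(neg) > 0L) {
        if (length(pos) < length(neg)) {
          pos <- c(pos, resample(pos, length(neg) - length(pos)))
        } else if (length(neg) < length(pos)) {
          neg <- c(neg, resample(neg, length(pos) - length(neg)))
        }
      }
      bal <- c(pos, neg)
      list(tree = grow_tree(X[bal, , drop = FALSE], y[bal], mtry), oob = oob,
           boot = bal)
    })
    trees[[b]] <- res$tree
    oob_sets[[b]] <- res$oob
    boot_sets[[b]] <- res$boot
  }
  structure(list(trees = trees, oob_sets = oob_sets, boot_sets = boot_sets,
                 features = colnames(X), cfg = cfg),
            class = "rf_model")
}

#' Predict rearrest likelihood with a random forest
#'
#' The likelihood is the fraction of trees voting positive (a multiple of
#' `1/B`); the majority-vote label is `score > 0.5`, with the tie at
#' exactly 0.5 resolved to the negative class.
#'
#' @param model An [rf_model][train_rf()].
#' @param X Feature matrix whose columns match the model's feature set.
#' @return Numeric vector of scores in `[0, 1]`.
#' @export
predict_likelihood <- function(model, X) {
  stopifnot(inherits(model, "rf_model"))
  X <- as.matrix(X)
  if (!is.null(model$features) && !is.null(colnames(X))) {
    assert_that(all(model$features %in% colnames(X)),
                "X is missing features used by the model")
    X <- X[, model$features, drop = FALSE]
  } else {
    assert_that(ncol(X) == length(model$features),
                "feature count mismatch between model and X")
  }
  votes <- numeric(nrow(X))
  for (tr in model$trees) votes <- votes + predict_tree(tr, X)
  votes / length(model$trees)
}

#' Out-of-bag permutation importance
#'
#' For every tree, the OOB misclassification error is computed before and
#' after permuting each feature within the OOB rows; a feature's
#' importance is the mean error increase over trees divided by its SD over
#' trees (0 when the SD is 0). The raw mean increase is also returned.
#'
#' @param model An [rf_model][train_rf()] retaining OOB sets.
#' @param X,y The training data the model was fitted on.
#' @param seed Integer seed for the permutations.
#' @return A list with `importance` (z-scored), `raw_mean`, and the
#'   per-tree increase matrix `delta` (trees x features).
#' @export
permutation_importance <- function(model, X, y, seed = 1L) {
  stopifnot(inherits(model, "rf_model"))
  X <- as.matrix(X)
  y <- as.integer(y)
  keep <- which(lengths(model$oob_sets) > 0L)
  assert_that(length(keep) > 0L, "model has no non-empty OOB sets")
  p <- ncol(X)
  delta <- matrix(0, nrow = length(keep), ncol = p)
  seeds <- spawn_seeds(seed, length(keep))
  for (ti in seq_along(keep)) {
    b <- keep[ti]
    oob <- model$oob_sets[[b]]
    tr <- model$trees[[b]]
    Xo <- X[oob, , drop = FALSE]
    yo <- y[oob]
    e0 <- mean(predict_tree(tr, Xo) != yo)
    used <- unique(tr$feature[!is.na(tr$feature)])
    with_seed(seeds[ti], {
      for (j in used) {
        Xp <- Xo
        Xp[, j] <- Xp[sample.int(nrow(Xo)), j]
        delta[ti, j] <- mean(predict_tree(tr, Xp) != yo) - e0
      }
    })
  }
  mu <- colMeans(delta)
  sdv <- apply(delta, 2L, stats::sd)
  z <- ifelse(sdv > 0, mu / sdv, 0)
  names(z) <- colnames(X)
  names(mu) <- colnames(X)
  list(importance = z, raw_mean = mu, delta = delta)
}

#' Two-stage feature selection and retraining
#'
#' Stage 1 trains a forest on all features and ranks them by OOB
#' permutation importance (ties broken toward the lower feature index);
#' stage 2 retrains on the top-`nf` features only.
#'
#' @param X,y Training data.
#' @param cfg An [rf_config()]; `cfg$nf` gives the number of retained
#'   features (default: all).
#' @return A list with `model` (the stage-2 [rf_model][train_rf()]),
#'   `ranking` (feature indices, most important first), `importance`.
#' @export
select_and_retrain <- function(X, y, cfg = rf_config()) {
  X <- as.matrix(X)
  p <- ncol(X)
  nf <- cfg$nf
  if (is.null(nf)) nf <- p
  assert_that(nf >= 1 && nf <= p, "nf must lie in [1, ncol(X)]")
  seeds <- spawn_seeds(cfg$seed, 3L)
  cfg1 <- cfg
  cfg1$seed <- seeds[1L]
  stage1 <- train_rf(X, y, cfg1)
  imp <- permutation_importance(stage1, X, y, seed = seeds[2L])
  ranking <- order(-imp$importance, seq_len(p))
  top <- sort(ranking[seq_len(nf)])
  cfg2 <- cfg
  cfg2$seed <- seeds[3L]
  model <- train_rf(X[, top, drop = FALSE], y, cfg2)
  list(model = model, ranking = ranking, importance = imp$importance,
       selected = if (!is.null(colnames(X))) colnames(X)[top] else top)
}

#' Univariate cost-sensitive logistic baseline
#'
#' Logistic regression on a single feature with class weights inversely
#' proportional to class frequencies, used to screen features one at a
#' time before building the forest.
#'
#' @param x Single feature vector.
#' @param y Binary labels (0/1), both classes present.
#' @return A list with `fit` (the glm, or `NULL` when degenerate),
#'   `scores` (in-sample scores), `degenerate` flag, and
#'   `predict(newx)`.
#' @export
fit_univariate_logistic <- function(x, y) {
  y <- as.integer(y)
  assert_that(length(unique(y)) == 2L, "both classes must be present in y")
  ok <- is.finite(x)
  if (stats::sd(x[ok]) == 0 || sum(ok) < 4L) {
    return(list(fit = NULL, scores = rep(0.5, length(x)), degenerate = TRUE,
                predict = function(newx) rep(0.5, length(newx))))
  }
  n <- sum(ok)
  w <- ifelse(y == 1L, n / (2 * sum(y[ok] == 1L)), n / (2 * sum(y[ok] == 0L)))
  df <- data.frame(x = x, y = y, w = w)
  fit <- suppressWarnings(
    stats::glm(y ~ x, family = stats::quasibinomial(), data = df[ok, ],
               weights = w))
  scores <- as.numeric(stats::predict(fit, newdata = df, type = "response"))
  list(fit = fit, scores = scores, degenerate = FALSE,
       predict = function(newx) {
         as.numeric(stats::predict(fit, newdata = data.frame(x = newx),
                                   type = "response"))
       })
}
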