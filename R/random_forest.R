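# From-scratch regression random forest: bootstrap bagging, per-node
# random feature subsetting, variance-reduction splits, minimum node
# size stopping, ensemble-average prediction, OOB error and raw
# permutation importance. The tree growing and traversal live in
# src/forest.cpp; this layer owns validation, the S4 container and
# serialization. All randomness comes from the forest's own seeded
# per-tree streams, never from R's RNG, so a fixed seed gives
# bit-identical forests regardless of n_tree extensions or call order.

.hashString <- function(s) {
  # polynomial rolling hash over the UTF-8 bytes (mod 2^31 - 1),
  # reported as hex; used to fingerprint the feature order +
  # normalization variant a forest was trained on
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

.featureHash <- function(feature_names, ss_normalize = "length") {
  .hashString(paste(c(feature_names, ss_normalize), collapse = "|"))
}

#' Fit a regression random forest
#'
#' Each tree is grown on a bootstrap sample of size n (drawn uniformly
#' with replacement); at every node \code{m_try} features are drawn at
#' random and the split maximizing the decrease in within-node sum of
#' squared deviations is taken, with thresholds at midpoints between
#' consecutive distinct sorted values and equal-gain ties resolved to the
#' lowest feature index, then lowest threshold. A node with fewer than
#' \code{node_cutoff} rows (default 5) is never split; leaves store the
#' mean response. Out-of-bag rows provide the OOB error and the raw
#' permutation importance (mean over trees of the increase in OOB MSE
#' after permuting one feature among that tree's OOB rows).
#'
#' @param X numeric matrix or data.frame, n x p.
#' @param y numeric response vector (for quality assessment: the
#'   pool-normalized TM-score in [0,1]).
#' @param n_tree number of trees (>= 1).
#' @param m_try features drawn per split, in [1, p].
#' @param node_cutoff minimum rows for a split attempt (default 5).
#' @param seed integer root seed of the deterministic per-tree streams.
#' @param bootstrap draw bootstrap samples (TRUE, standard bagging); with
#'   FALSE every tree sees all rows and no OOB statistics exist.
#' @param feature_hash fingerprint stored in the forest and checked at
#'   prediction time (defaults to the hash of \code{colnames(X)}).
#' @return a \code{\link{RegressionForest-class}}.
#' @export
fitForest <- function(X, y, n_tree, m_try, node_cutoff = 5L, seed = 1L,
                      bootstrap = TRUE, feature_hash = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  p <- ncol(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))
  if (n_tree < 1) stop("parameter error: n_tree must be >= 1")
  if (m_try < 1 || m_try > p)
    stop(sprintf("parameter error: m_try must be in [1, %d]", p))
  if (nrow(X) != length(y)) stop("X and y dimensions disagree")
  if (!all(is.finite(y))) stop("y must be finite")
  if (nrow(X) < node_cutoff)
    stop("parameter error: need at least node_cutoff training rows")
  if (is.null(feature_hash)) feature_hash <- .featureHash(colnames(X))
  trees <- .rf_fit(X, as.numeric(y), as.integer(n_tree), as.integer(m_try),
                   as.integer(node_cutoff), as.numeric(seed), bootstrap)
  if (bootstrap) {
    stats_ <- .rf_oob_stats(trees, X, as.numeric(y), as.numeric(seed))
    skipped <- stats_$trees_skipped
    if (skipped > 0.1 * n_tree)
      warning(sprintf("%d of %d trees had an empty OOB set", skipped, n_tree))
    imp <- stats::setNames(as.numeric(stats_$importance), colnames(X))
    oob_err <- as.numeric(stats_$oob_error)
    oob_pred <- as.numeric(stats_$oob_predictions)
  } else {
    imp <- stats::setNames(rep(NA_real_, p), colnames(X))
    oob_err <- NA_real_
    oob_pred <- rep(NA_real_, nrow(X))
  }
  new("RegressionForest", trees = trees, nTree = as.integer(n_tree),
      mTry = as.integer(m_try), nodeCutoff = as.integer(node_cutoff),
      seed = as.numeric(seed), featureNames = colnames(X),
      importance = imp, oobError = oob_err, oobPredictions = oob_pred,
      nTrain = nrow(X), featureHash = feature_hash)
}

#' Predict with a regression forest
#'
#' The ensemble average over the leaf means reached by each row; the
#' result is invariant to tree order.
#'
#' @param object a \code{RegressionForest}.
#' @param newdata numeric matrix or data.frame with the training feature
#'   columns.
#' @param n_tree_use use only the first k trees (default: all); because
#'   per-tree streams are fixed, the first k trees of a larger forest
#'   equal a forest trained with \code{n_tree = k}.
#' @param ... ignored.
#' @return numeric vector of predictions.
#' @export
setMethod("predict", "RegressionForest",
          function(object, newdata, n_tree_use = object@nTree, ...) {
  X <- as.matrix(newdata)
  storage.mode(X) <- "double"
  if (ncol(X) != length(object@featureNames))
    stop("feature count mismatch: forest expects ",
         length(object@featureNames), " features")
  if (!is.null(colnames(X)) &&
      !identical(colnames(X), object@featureNames) &&
      all(object@featureNames %in% colnames(X)))
    X <- X[, object@featureNames, drop = FALSE]
  k <- min(as.integer(n_tree_use), object@nTree)
  pm <- .rf_predict_mat(object@trees[seq_len(k)], X)
  rowMeans(pm)
})

#' Per-tree prediction matrix
#'
#' Exposes the individual tree outputs (n rows x n_tree columns), from
#' which prefix-ensemble and OOB quantities can be assembled cheaply.
#'
#' @param forest a \code{RegressionForest}.
#' @param newdata feature matrix.
#' @return numeric matrix, one column per tree.
#' @export
predictPerTree <- function(forest, newdata) {
  X <- as.matrix(newdata)
  storage.mode(X) <- "double"
  .rf_predict_mat(forest@trees, X)
}

#' Out-of-bag permutation importance
#'
#' Recomputes the raw permutation importance of a fitted forest on its
#' training data: for every tree the OOB mean squared error is measured,
#' each feature is permuted among that tree's OOB rows (deterministic
#' streams derived from the forest seed) and the error re-estimated; the
#' importance of a feature is the mean error increase over trees with a
#' nonempty OOB set.
#'
#' @param forest a \code{RegressionForest} trained with bootstrap.
#' @param X,y the training data the forest was fitted on.
#' @return named numeric vector of raw importances.
#' @export
oobImportance <- function(forest, X, y) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (nrow(X) != forest@nTrain)
    stop("X must be the forest's training matrix")
  stats_ <- .rf_oob_stats(forest@trees, X, as.numeric(y), forest@seed)
  if (stats_$trees_skipped > 0.1 * forest@nTree)
    warning(sprintf("%d of %d trees had an empty OOB set",
                    stats_$trees_skipped, forest@nTree))
  stats::setNames(as.numeric(stats_$importance), forest@featureNames)
}

#' Serialize a forest to JSON
#'
#' Flattened node arrays per tree plus the hyperparameters, seed and
#' feature fingerprint, so a saved model refuses to rank feature tables
#' with a different feature order or normalization variant.
#'
#' @param forest a \code{RegressionForest}.
#' @param path output .json path.
#' @return \code{path}, invisibly.
#' @export
writeForest <- function(forest, path) {
  obj <- list(
    format = "ForestMQA-forest-v1",
    n_tree = forest@nTree, m_try = forest@mTry,
    node_cutoff = forest@nodeCutoff, seed = forest@seed,
    feature_names = forest@featureNames,
    feature_hash = forest@featureHash,
    importance = as.list(forest@importance),
    oob_error = forest@oobError, n_train = forest@nTrain,
    trees = lapply(forest@trees, function(tr)
      tr[c("feature", "threshold", "left", "right", "value", "count", "oob",
           "bootstrap")]))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Read a forest serialized by \code{\link{writeForest}}
#'
#' @param path .json path.
#' @return a \code{RegressionForest}.
#' @export
readForest <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "ForestMQA-forest-v1"))
    stop("format error: not a serialized forest: ", path)
  trees <- lapply(seq_len(obj$n_tree), function(t) {
    tr <- lapply(obj$trees[t, , drop = FALSE], function(col) col[[1]])
    list(feature = as.integer(tr$feature),
         threshold = as.numeric(tr$threshold),
         left = as.integer(tr$left), right = as.integer(tr$right),
         value = as.numeric(tr$value), count = as.integer(tr$count),
         oob = as.integer(tr$oob), bootstrap = as.integer(tr$bootstrap))
  })
  imp <- unlist(obj$importance)
  new("RegressionForest", trees = trees, nTree = as.integer(obj$n_tree),
      mTry = as.integer(obj$m_try), nodeCutoff = as.integer(obj$node_cutoff),
      seed = as.numeric(obj$seed), featureNames = obj$feature_names,
      importance = stats::setNames(as.numeric(imp), names(imp)),
      oobError = as.numeric(obj$oob_error),
      oobPredictions = rep(NA_real_, obj$n_train),
      nTrain = as.integer(obj$n_train),
      featureHash = obj$feature_hash)
}
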