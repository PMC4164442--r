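# End-to-end training protocol: screening of training pools (top 50% by
# TM-score, exclusion of targets with mean TM < 0.3), per-pool
# normalization, target-level k-fold cross-validation with a
# hyperparameter grid search, final model fitting, and ranking of new
# pools. Screening is applied to training pools only, never at test or
# ranking time.

#' Training configuration
#'
#' Defaults follow the published protocol: keep the top 50% of each
#' training pool by TM-score, reject targets whose mean TM-score (before
#' screening) is below 0.3, 5 cross-validation folds, a grid of n_tree
#' in \{500, 1000, ..., 10000\} by m_try in \{1..7\}, node cutoff 5.
#'
#' @param screen_top_fraction fraction of top-labeled models kept for
#'   training, in (0, 1].
#' @param min_mean_tm minimum pool mean TM-score for a training target.
#' @param cv_folds number of cross-validation folds (>= 2).
#' @param n_tree_grid,m_try_grid hyperparameter grids (nonempty).
#' @param node_cutoff minimum node size for a split attempt.
#' @param seed integer root seed.
#' @param label_mode "normalized" trains on pool-normalized TM-scores
#'   (relative quality, the default); "raw" trains on raw TM-scores.
#' @param ss_normalize consistency-score normalization variant recorded
#'   in the model fingerprint.
#' @return a list of class \code{TrainingConfig}.
#' @export
trainingConfig <- function(screen_top_fraction = 0.5, min_mean_tm = 0.3,
                           cv_folds = 5L,
                           n_tree_grid = seq(500L, 10000L, by = 500L),
                           m_try_grid = 1:7, node_cutoff = 5L, seed = 1L,
                           label_mode = c("normalized", "raw"),
                           ss_normalize = "length") {
  label_mode <- match.arg(label_mode)
  if (screen_top_fraction <= 0 || screen_top_fraction > 1)
    stop("parameter error: screen_top_fraction must be in (0, 1]")
  if (cv_folds < 2) stop("parameter error: cv_folds must be >= 2")
  if (!length(n_tree_grid) || !length(m_try_grid))
    stop("parameter error: hyperparameter grids must be nonempty")
  structure(list(screen_top_fraction = screen_top_fraction,
                 min_mean_tm = min_mean_tm, cv_folds = as.integer(cv_folds),
                 n_tree_grid = as.integer(sort(n_tree_grid)),
                 m_try_grid = as.integer(sort(m_try_grid)),
                 node_cutoff = as.integer(node_cutoff),
                 seed = as.integer(seed), label_mode = label_mode,
                 ss_normalize = ss_normalize),
            class = "TrainingConfig")
}

#' Hyperparameter grid of a configuration
#'
#' @param config a \code{TrainingConfig}.
#' @return data.frame with one row per evaluated (n_tree, m_try)
#'   combination (140 rows under the default grids).
#' @export
gridCombinations <- function(config) {
  expand.grid(n_tree = config$n_tree_grid, m_try = config$m_try_grid,
              KEEP.OUT.ATTRS = FALSE)
}

#' Screen a training pool
#'
#' Rejects the pool (returns NULL with a message) when its mean TM-score,
#' computed before screening, is below \code{min_mean_tm}; otherwise
#' keeps the \code{ceiling(fraction * n)} highest-labeled models.
#' Screening is a training-time operation only.
#'
#' @param pool a labeled, unnormalized \code{TargetPool}.
#' @param config a \code{TrainingConfig}.
#' @return the screened \code{TargetPool}, or NULL when rejected.
#' @export
screenPool <- function(pool, config = trainingConfig()) {
  labels <- pool@labels
  if (!any(is.finite(labels))) stop("cannot screen an unlabeled pool")
  if (mean(labels, na.rm = TRUE) < config$min_mean_tm) {
    message("pool ", pool@targetId, " rejected: mean TM-score ",
            sprintf("%.3f", mean(labels, na.rm = TRUE)), " < ",
            config$min_mean_tm)
    return(NULL)
  }
  n_keep <- ceiling(config$screen_top_fraction * length(labels))
  keep <- names(sort(labels, decreasing = TRUE))[seq_len(n_keep)]
  f <- pool@features[pool@features$model_id %in% keep, , drop = FALSE]
  newTargetPool(pool@targetId, f, labels[keep], normalized = pool@normalized)
}

# Training-pool preparation. Order matters: features and labels are
# min-max normalized over the FULL pool first (the same scale ranking
# uses at test time), then the top fraction by label is retained, so a
# forest never sees features on a different scale than it will be asked
# to predict on. Rejection by mean TM-score uses the raw labels.
.prepareTrainingPools <- function(pools, config) {
  out <- list()
  for (p in pools) {
    labels <- p@labels
    if (!any(is.finite(labels))) stop("cannot train on an unlabeled pool")
    if (mean(labels, na.rm = TRUE) < config$min_mean_tm) {
      message("pool ", p@targetId, " rejected: mean TM-score ",
              sprintf("%.3f", mean(labels, na.rm = TRUE)), " < ",
              config$min_mean_tm)
      next
    }
    np <- if (p@normalized) p else normalizePool(p)
    n_keep <- ceiling(config$screen_top_fraction * length(labels))
    keep <- names(sort(labels, decreasing = TRUE))[seq_len(n_keep)]
    f <- np@features[np@features$model_id %in% keep, , drop = FALSE]
    lab <- if (config$label_mode == "normalized") np@labels[f$model_id]
           else labels[f$model_id]
    out[[p@targetId]] <- list(features = f, labels = lab,
                              target = p@targetId)
  }
  out
}

# stack prepared pools into one training matrix
.trainingRows <- function(prepared, config) {
  list(X = do.call(rbind, lapply(prepared, function(p)
         as.matrix(p$features[, featureNames()]))),
       y = unlist(lapply(prepared, function(p) unname(p$labels))),
       target = unlist(lapply(prepared, function(p)
         rep(p$target, nrow(p$features)))))
}

# Grid-search criterion on the training pools: mean per-target Pearson
# correlation between OOB ensemble predictions and the labels. Because
# per-tree RNG streams are fixed by offset, one forest of max(n_tree)
# trees per m_try yields every n_tree prefix of the grid for free.
.gridSearch <- function(prepared, config) {
  tr <- .trainingRows(prepared, config)
  n <- nrow(tr$X)
  best <- NULL
  for (m_try in config$m_try_grid) {
    forest <- fitForest(tr$X, tr$y, n_tree = max(config$n_tree_grid),
                        m_try = m_try, node_cutoff = config$node_cutoff,
                        seed = config$seed)
    pm <- predictPerTree(forest, tr$X)
    inbag <- matrix(TRUE, n, forest@nTree)
    for (t in seq_len(forest@nTree))
      inbag[forest@trees[[t]]$oob, t] <- FALSE
    pm[inbag] <- NA
    for (n_tree in config$n_tree_grid) {
      oob_pred <- rowMeans(pm[, seq_len(n_tree), drop = FALSE], na.rm = TRUE)
      crit <- mean(vapply(unique(tr$target), function(tid) {
        idx <- which(tr$target == tid & is.finite(oob_pred))
        if (length(idx) < 2 || stats::sd(tr$y[idx]) == 0 ||
            stats::sd(oob_pred[idx]) == 0) return(NA_real_)
        stats::cor(oob_pred[idx], tr$y[idx])
      }, numeric(1)), na.rm = TRUE)
      # maximize; ties to smaller n_tree then smaller m_try (iteration order)
      if (is.null(best) || (is.finite(crit) && crit > best$criterion)) {
        best <- list(n_tree = n_tree, m_try = m_try, criterion = crit)
      }
    }
  }
  best
}

#' Target-level cross-validation with grid search
#'
#' Partitions the targets (never individual models) into
#' \code{config$cv_folds} folds at random under the configuration seed.
#' For every fold, training pools are screened, the (n_tree, m_try) grid
#' is searched on the training folds (criterion: mean per-target Pearson
#' correlation between out-of-bag predictions and labels, ties to the
#' smaller n_tree), a forest is fitted with the selected parameters, and
#' the held-out pools are ranked without screening. Returns per-fold
#' selections and the aggregated metric report.
#'
#' @param pools named list of labeled, unnormalized \code{TargetPool}s.
#' @param config a \code{TrainingConfig}.
#' @return list with \code{folds} (target assignment), \code{per_fold}
#'   (chosen hyperparameters and criterion per fold),
#'   \code{predicted_scores} (per target), \code{report}
#'   (an \code{EvaluationReport} over all targets) and
#'   \code{chosen} (hyperparameters most often selected).
#' @export
crossValidate <- function(pools, config = trainingConfig()) {
  k <- config$cv_folds
  if (length(pools) < k)
    stop("parameter error: need at least as many pools as folds")
  if (is.null(names(pools)) || any(names(pools) == ""))
    names(pools) <- vapply(pools, targetId, character(1))
  tids <- names(pools)
  rng <- .lcgShuffle(length(tids), config$seed)
  fold_of <- stats::setNames(rep(seq_len(k), length.out = length(tids))[order(rng)],
                             tids)
  per_fold <- vector("list", k)
  predicted <- list()
  for (fold in seq_len(k)) {
    train_ids <- tids[fold_of[tids] != fold]
    test_ids <- tids[fold_of[tids] == fold]
    prepared <- .prepareTrainingPools(pools[train_ids], config)
    if (!length(prepared)) stop("all training pools rejected in fold ", fold)
    sel <- .gridSearch(prepared, config)
    forest <- .fitOnPools(prepared, sel$n_tree, sel$m_try, config)
    for (tid in test_ids) {
      ranked <- rankPool(forest, normalizePool(.stripLabels(pools[[tid]])))
      predicted[[tid]] <- stats::setNames(ranked$predicted_score,
                                          ranked$model_id)
    }
    per_fold[[fold]] <- data.frame(fold = fold, n_tree = sel$n_tree,
                                   m_try = sel$m_try,
                                   criterion = sel$criterion)
  }
  per_fold <- do.call(rbind, per_fold)
  chosen_tab <- stats::aggregate(list(times = rep(1, nrow(per_fold))),
                                 per_fold[, c("n_tree", "m_try")], sum)
  chosen <- chosen_tab[order(-chosen_tab$times, chosen_tab$n_tree,
                             chosen_tab$m_try)[1], c("n_tree", "m_try")]
  list(folds = fold_of, per_fold = per_fold,
       predicted_scores = predicted,
       report = evaluateSelections(pools, predicted, method = "ForestMQA"),
       chosen = as.list(chosen))
}

# deterministic shuffle keys without touching R's global RNG
.lcgShuffle <- function(n, seed) {
  s <- (as.numeric(seed) %% 2147483647) + 1
  out <- numeric(n)
  for (i in seq_len(n)) {
    s <- (s * 48271) %% 2147483647
    out[i] <- s
  }
  out
}

.stripLabels <- function(pool) {
  newTargetPool(pool@targetId, pool@features, NULL,
                normalized = pool@normalized)
}

.fitOnPools <- function(prepared, n_tree, m_try, config) {
  tr <- .trainingRows(prepared, config)
  fitForest(tr$X, tr$y, n_tree = n_tree, m_try = m_try,
            node_cutoff = config$node_cutoff, seed = config$seed,
            feature_hash = .featureHash(featureNames(),
                                        config$ss_normalize))
}

#' Fit the final quality-assessment forest
#'
#' Normalizes each training pool over its full decoy set (the same
#' scale \code{\link{rankPool}} uses later), retains the top fraction of
#' models by TM-score, rejects pools whose mean raw TM-score is below
#' the threshold, concatenates the surviving rows and fits one forest
#' with the published defaults n_tree = 3000, m_try = 1.
#'
#' @param pools named list of labeled, unnormalized \code{TargetPool}s.
#' @param n_tree,m_try hyperparameters (defaults 3000 and 1).
#' @param config a \code{TrainingConfig}.
#' @return a \code{RegressionForest}.
#' @export
fitFinal <- function(pools, n_tree = 3000L, m_try = 1L,
                     config = trainingConfig()) {
  prepared <- .prepareTrainingPools(pools, config)
  if (!length(prepared)) stop("empty training set after screening")
  .fitOnPools(prepared, n_tree, m_try, config)
}

#' Rank a pool of models
#'
#' Predicts the relative quality score of every model in a (label-free,
#' pool-normalized) pool and returns the models sorted by predicted
#' score, ties broken lexicographically by model_id; the first row is
#' the selected model. No screening is ever applied here.
#'
#' @param forest a trained \code{RegressionForest}.
#' @param pool a normalized \code{TargetPool}.
#' @return data.frame with columns model_id, predicted_score, rank.
#' @export
rankPool <- function(forest, pool) {
  single <- nrow(pool@features) == 1L
  if (!pool@normalized && !single)
    stop("pool features must be normalized; call normalizePool() first")
  X <- as.matrix(pool@features[, featureNames()])
  if (single) X <- pmin(pmax(X, 0), 1)
  if (any(X < -1e-9 | X > 1 + 1e-9))
    stop("pool features outside [0,1]; call normalizePool() first")
  pred <- predict(forest, X)
  ord <- order(-pred, pool@features$model_id)
  data.frame(model_id = pool@features$model_id[ord],
             predicted_score = pred[ord],
             rank = seq_along(ord), stringsAsFactors = FALSE)
}
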