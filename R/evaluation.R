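# Assessment metrics for comparing quality-assessment methods on
# labeled pools: correlation of selected vs best TM-score over targets,
# mean TM-score loss, per-target selection Z-scores and their bin
# distribution, mean per-target rank correlation, and pairwise
# gain/loss/equal counts between two methods.

#' Pearson correlation coefficient
#'
#' Standard product-moment correlation; used over targets between the
#' TM-score of the model a method selects and the pool-best TM-score.
#'
#' @param x,y equal-length numeric vectors, length >= 2.
#' @return r in [-1,1]; NA with a warning when either vector has zero
#'   variance.
#' @export
pearsonCC <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must have equal length")
  if (length(x) < 2) stop("need at least 2 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero-variance input; Pearson correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y)
}

#' Spearman rank correlation
#'
#' Computed from the rank-difference formula
#' \eqn{\rho = 1 - 6 \sum d_i^2 / (n (n^2 - 1))} when all ranks are
#' distinct; under ties, mean ranks are assigned and the equivalent
#' Pearson correlation of the ranks is returned.
#'
#' @param x,y equal-length numeric vectors, n >= 2.
#' @return rho in [-1,1]; NA with a warning when either vector is fully
#'   tied.
#' @export
spearmanRho <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must have equal length")
  n <- length(x)
  if (n < 2) stop("need at least 2 observations")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    warning("fully tied vector; Spearman correlation undefined")
    return(NA_real_)
  }
  ties <- anyDuplicated(rx) || anyDuplicated(ry)
  if (!ties) {
    d <- rx - ry
    return(1 - 6 * sum(d^2) / (n * (n^2 - 1)))
  }
  stats::cor(rx, ry)
}

#' TM-score loss of a selection
#'
#' \eqn{TM_{loss} = TM_{best} - TM_{selected}}; zero iff the selected
#' model attains the pool maximum (under ties, any maximal model counts
#' as best).
#'
#' @param pool a labeled \code{TargetPool}.
#' @param selected_model model_id of the selection.
#' @return nonnegative loss.
#' @export
tmLoss <- function(pool, selected_model) {
  labels <- pool@labels
  if (!selected_model %in% names(labels))
    stop("selected model '", selected_model, "' not in pool ", pool@targetId)
  if (!any(is.finite(labels))) stop("pool ", pool@targetId, " is unlabeled")
  max(labels, na.rm = TRUE) - labels[[selected_model]]
}

#' Selection Z-score
#'
#' \eqn{(TM_{selected} - \overline{TM}) / sd(TM)} over the pool's labels;
#' a uniform-random pick has expectation 0. The sample (n-1) standard
#' deviation is the default; the population variant is available.
#'
#' @param pool a labeled \code{TargetPool} with >= 2 distinct labels.
#' @param selected_model model_id of the selection.
#' @param sd_type "sample" (default) or "population".
#' @return z value; NA with a warning when the labels have zero spread.
#' @export
selectionZScore <- function(pool, selected_model,
                            sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  labels <- pool@labels
  if (!selected_model %in% names(labels))
    stop("selected model '", selected_model, "' not in pool ", pool@targetId)
  lab <- labels[is.finite(labels)]
  if (length(lab) < 2) stop("pool ", pool@targetId, " needs >= 2 labels")
  s <- stats::sd(lab)
  if (sd_type == "population") s <- s * sqrt((length(lab) - 1) / length(lab))
  if (s == 0) {
    warning("zero label spread in pool ", pool@targetId, "; Z undefined")
    return(NA_real_)
  }
  (labels[[selected_model]] - mean(lab)) / s
}

#' Pairwise gain/loss/equal comparison of two methods
#'
#' Counts, over pools, how often the model selected by method A has a
#' higher / lower / equal TM-score than the model selected by method B.
#'
#' @param selections_a,selections_b named character vectors
#'   (target_id -> model_id).
#' @param pools named list of labeled \code{TargetPool}s.
#' @return named numeric \code{c(gain, loss, equal)} with
#'   gain + loss + equal = number of compared pools.
#' @export
pairwiseCompare <- function(selections_a, selections_b, pools) {
  gain <- loss <- equal <- 0
  for (tid in names(pools)) {
    a <- if (tid %in% names(selections_a)) selections_a[[tid]] else NA
    b <- if (tid %in% names(selections_b)) selections_b[[tid]] else NA
    if (is.na(a) || is.na(b)) {
      warning("missing selection for pool ", tid, "; skipped")
      next
    }
    labels <- pools[[tid]]@labels
    d <- labels[[a]] - labels[[b]]
    if (d > 0) gain <- gain + 1
    else if (d < 0) loss <- loss + 1
    else equal <- equal + 1
  }
  c(gain = gain, loss = loss, equal = equal)
}

#' Mean per-target rank correlation
#'
#' Spearman correlation between the predicted scores and the true labels
#' within each pool, averaged over pools. Pools of size 1 are excluded
#' with a warning.
#'
#' @param pools named list of labeled \code{TargetPool}s.
#' @param predicted_scores named list (target_id -> named numeric of
#'   predicted scores per model_id).
#' @return mean rank correlation.
#' @export
ccRank <- function(pools, predicted_scores) {
  vals <- numeric(0)
  for (tid in names(pools)) {
    pool <- pools[[tid]]
    sc <- predicted_scores[[tid]]
    if (is.null(sc)) stop("no predicted scores for pool ", tid)
    ids <- pool@features$model_id
    if (length(ids) < 2) {
      warning("pool ", tid, " has a single model; excluded from CC_rank")
      next
    }
    vals <- c(vals, spearmanRho(sc[ids], pool@labels[ids]))
  }
  mean(vals)
}

#' Z-score bin distribution
#'
#' Histogram of selection Z-scores over the half-open bins Z<0, 0<=Z<1,
#' 1<=Z<2, 2<=Z<3 and Z>=3.
#'
#' @param z numeric vector of Z-scores (non-finite entries dropped).
#' @param fractions return fractions instead of counts.
#' @return named numeric of length 5.
#' @export
zBinDistribution <- function(z, fractions = FALSE) {
  z <- z[is.finite(z)]
  counts <- c("Z<0" = sum(z < 0),
              "0<=Z<1" = sum(z >= 0 & z < 1),
              "1<=Z<2" = sum(z >= 1 & z < 2),
              "2<=Z<3" = sum(z >= 2 & z < 3),
              "Z>=3" = sum(z >= 3))
  if (fractions && length(z)) counts / length(z) else counts
}

#' Evaluate one method's selections over labeled pools
#'
#' Builds the full metric report: the first-ranked model per pool is
#' taken from the predicted scores (ties broken lexicographically by
#' model_id), then CC_TM and Spearman between selected and pool-best
#' TM-scores over targets, mean TM-loss, mean per-target rank
#' correlation, per-target Z-scores with their bin distribution, and the
#' TM and Z sums over first-ranked models.
#'
#' @param pools named list of labeled \code{TargetPool}s (raw labels).
#' @param predicted_scores named list (target_id -> named numeric of
#'   predicted scores per model_id).
#' @param method method name recorded in the report.
#' @param sd_type Z-score standard-deviation variant.
#' @return an \code{\link{EvaluationReport-class}}.
#' @export
evaluateSelections <- function(pools, predicted_scores, method = "method",
                               sd_type = "sample") {
  sel <- vapply(names(pools), function(tid) {
    sc <- predicted_scores[[tid]]
    if (is.null(sc)) stop("no predicted scores for pool ", tid)
    top <- names(sc)[sc == max(sc)]
    sort(top)[1]
  }, character(1))
  tm_sel <- vapply(names(pools), function(tid)
    pools[[tid]]@labels[[sel[[tid]]]], numeric(1))
  tm_best <- vapply(pools, function(p) max(p@labels, na.rm = TRUE), numeric(1))
  z <- vapply(names(pools), function(tid)
    selectionZScore(pools[[tid]], sel[[tid]], sd_type = sd_type), numeric(1))
  new("EvaluationReport", method = method,
      ccTM = if (length(pools) >= 2) pearsonCC(tm_sel, tm_best) else NA_real_,
      spearman = if (length(pools) >= 2) spearmanRho(tm_sel, tm_best) else NA_real_,
      meanTMLoss = mean(tm_best - tm_sel),
      ccRank = ccRank(pools, predicted_scores),
      zScores = z, zBins = as.numeric(zBinDistribution(z)),
      tmSum = sum(tm_sel), zSum = sum(z[is.finite(z)]),
      nTargets = length(pools))
}
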