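# Metric suite: correlations, TM-loss, Z-scores, bins, pairwise counts.

labeledPool <- function(target_id, labels) {
  ids <- sprintf("%s_m%d", target_id, seq_along(labels))
  f <- data.frame(model_id = ids, stringsAsFactors = FALSE)
  for (cn in featureNames()) f[[cn]] <- seq_along(labels)
  newTargetPool(target_id, f, stats::setNames(labels, ids))
}

test_that("Pearson matches direct formula evaluation and guards", {
  x <- c(1, 2, 3)
  expect_equal(pearsonCC(x, x), 1)
  expect_equal(pearsonCC(x, -x), -1)
  expect_equal(pearsonCC(x, c(1, 2, 4)), 0.9819805, tolerance = 1e-6)
  expect_warning(r <- pearsonCC(c(1, 1), c(1, 2)), "zero-variance")
  expect_true(is.na(r))
})

test_that("Spearman follows the rank-difference formula", {
  expect_equal(spearmanRho(1:5, 1:5), 1)
  expect_equal(spearmanRho(1:3, 3:1), -1)
  # x=(1,2,3), y=(2,1,3): sum d^2 = 2 -> 1 - 12/24 = 0.5
  expect_equal(spearmanRho(c(1, 2, 3), c(2, 1, 3)), 0.5)
  expect_warning(r <- spearmanRho(c(2, 2, 2), 1:3), "tied")
  expect_true(is.na(r))
})

test_that("the d-squared formula equals Pearson-on-ranks without ties", {
  set.seed(51)
  for (i in 1:30) {
    n <- sample(4:25, 1)
    x <- sample(n); y <- sample(n)
    expect_equal(spearmanRho(x, y), cor(x, y, method = "spearman"),
                 tolerance = 1e-12)
    expect_equal(spearmanRho(x, y), cor(rank(x), rank(y)),
                 tolerance = 1e-12)
  }
  # under ties the mean-rank Pearson equivalent is used
  x <- c(1, 1, 2, 3); y <- c(4, 2, 2, 1)
  expect_equal(spearmanRho(x, y), cor(x, y, method = "spearman"),
               tolerance = 1e-12)
})

test_that("TM-loss is the gap to the pool best", {
  pool <- labeledPool("t", c(0.80, 0.74, 0.50))
  expect_equal(unname(tmLoss(pool, "t_m1")), 0)
  expect_equal(unname(tmLoss(pool, "t_m2")), 0.06)
  expect_error(tmLoss(pool, "zz"), "not in pool")
  # expectation of a uniform-random pick over labels {0.4, 0.5, 0.6}
  p2 <- labeledPool("u", c(0.4, 0.5, 0.6))
  losses <- vapply(c("u_m1", "u_m2", "u_m3"), function(id)
    unname(tmLoss(p2, id)), numeric(1))
  expect_equal(mean(losses), 0.1)
})

test_that("selection Z-scores use sample sd by default, population on request", {
  pool <- labeledPool("t", c(0.4, 0.5, 0.6))
  expect_equal(unname(selectionZScore(pool, "t_m3")), 1)
  expect_equal(unname(selectionZScore(pool, "t_m3", sd_type = "population")),
               sqrt(3 / 2), tolerance = 1e-12)
  expect_equal(unname(selectionZScore(pool, "t_m2")), 0)
  expect_warning(z <- selectionZScore(labeledPool("c", c(0.5, 0.5)), "c_m1"),
                 "zero")
  expect_true(is.na(z))
})

test_that("a random pick has mean Z near zero over many pools", {
  set.seed(52)
  zs <- vapply(1:300, function(i) {
    labels <- runif(8, 0.2, 0.9)
    pool <- labeledPool(paste0("r", i), labels)
    unname(selectionZScore(pool, sample(names(poolLabels(pool)), 1)))
  }, numeric(1))
  expect_lt(abs(mean(zs)), 2 * sd(zs) / sqrt(length(zs)) + 0.02)
})

test_that("pairwise comparison counts gains, losses and ties", {
  pools <- list(a = labeledPool("a", c(0.9, 0.8)),
                b = labeledPool("b", c(0.7, 0.6)),
                c = labeledPool("c", c(0.5, 0.5)))
  sa <- c(a = "a_m1", b = "b_m2", c = "c_m1")
  sb <- c(a = "a_m2", b = "b_m1", c = "c_m2")
  expect_equal(pairwiseCompare(sa, sb, pools),
               c(gain = 1, loss = 1, equal = 1))
  expect_equal(pairwiseCompare(sa, sa, pools),
               c(gain = 0, loss = 0, equal = 3))
  expect_warning(out <- pairwiseCompare(sa[1:2], sb, pools), "missing")
  expect_equal(sum(out), 2)
})

test_that("CC_rank averages per-pool rank correlations", {
  p1 <- labeledPool("p1", c(0.9, 0.7, 0.5, 0.3))
  p2 <- labeledPool("p2", c(0.8, 0.6, 0.4, 0.2))
  ids1 <- names(poolLabels(p1)); ids2 <- names(poolLabels(p2))
  perfect <- list(p1 = stats::setNames(4:1 / 4, ids1),
                  p2 = stats::setNames(4:1 / 4, ids2))
  expect_equal(ccRank(list(p1 = p1, p2 = p2), perfect), 1)
  mixed <- list(p1 = stats::setNames(4:1 / 4, ids1),
                p2 = stats::setNames(1:4 / 4, ids2))
  expect_equal(ccRank(list(p1 = p1, p2 = p2), mixed), 0)
})

test_that("random scores give CC_rank near zero over many pools", {
  set.seed(53)
  pools <- list(); scores <- list()
  for (i in 1:100) {
    tid <- paste0("n", i)
    pools[[tid]] <- labeledPool(tid, runif(12, 0.2, 0.9))
    scores[[tid]] <- stats::setNames(runif(12),
                                     names(poolLabels(pools[[tid]])))
  }
  expect_lt(abs(ccRank(pools, scores)), 0.07)
})

test_that("Z bins use half-open boundaries and sum to the target count", {
  z <- c(-0.1, 0.5, 1.5, 2.5, 3.5)
  expect_equal(unname(zBinDistribution(z)), rep(1, 5))
  expect_equal(unname(zBinDistribution(1.0)), c(0, 0, 1, 0, 0))
  expect_equal(unname(zBinDistribution(numeric(0))), rep(0, 5))
  expect_equal(sum(zBinDistribution(rnorm(37))), 37)
  expect_equal(sum(zBinDistribution(c(-1, 0, 4), fractions = TRUE)), 1)
})

test_that("metrics are invariant under model_id relabeling", {
  labels <- c(0.85, 0.55, 0.35, 0.65)
  p <- labeledPool("t", labels)
  ids <- names(poolLabels(p))
  sc <- stats::setNames(c(0.2, 0.9, 0.1, 0.5), ids)
  f2 <- poolFeatures(p)
  f2$model_id <- paste0("renamed_", rev(seq_along(ids)))
  p2 <- newTargetPool("t", f2, stats::setNames(labels,
                                               f2$model_id))
  sc2 <- stats::setNames(unname(sc), f2$model_id)
  r1 <- evaluateSelections(list(t = p), list(t = sc))
  r2 <- evaluateSelections(list(t = p2), list(t = sc2))
  expect_equal(r1@meanTMLoss, r2@meanTMLoss)
  expect_equal(r1@zScores, r2@zScores, ignore_attr = TRUE)
})

test_that("the aggregate report ties the pieces together", {
  pools <- list(); scores <- list()
  set.seed(54)
  for (i in 1:6) {
    tid <- sprintf("T%02d", i)
    labels <- sort(runif(8, 0.3, 0.9))
    pools[[tid]] <- labeledPool(tid, labels)
    ids <- names(poolLabels(pools[[tid]]))
    scores[[tid]] <- stats::setNames(labels + rnorm(8, sd = 0.02), ids)
  }
  rep_ <- evaluateSelections(pools, scores, method = "near-perfect")
  expect_s4_class(rep_, "EvaluationReport")
  expect_gte(rep_@ccTM, 0.9)
  expect_gte(rep_@ccRank, 0.9)
  expect_lt(rep_@meanTMLoss, 0.05)
  expect_equal(sum(rep_@zBins), 6)
  expect_equal(rep_@nTargets, 6L)
  # mean loss is zero iff every selection is a pool maximum
  perfect <- lapply(pools, function(p)
    stats::setNames(poolLabels(p), names(poolLabels(p))))
  expect_equal(evaluateSelections(pools, perfect)@meanTMLoss, 0)
})
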