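#' @useDynLib ForestMQA, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
NULL

#' Canonical feature order of the quality-assessment feature vector
#'
#' Nine features per model, in fixed order: three statistical-potential
#' energies (dDFIRE, RWplus, GOAP slots), three secondary-structure match
#' fractions (helix, sheet, coil), the confidence-weighted secondary-structure
#' consistency score, and the two solvent-accessibility consistency terms
#' (Pearson correlation and cosine of observed vs. predicted per-residue ASA).
#'
#' @return Character vector of the nine feature column names.
#' @export
featureNames <- function() {
  c("F1_dDFIRE", "F2_RWplus", "F3_GOAP",
    "F4_helix_match", "F5_sheet_match", "F6_coil_match",
    "F7_ss_consistency", "F8_asa_corr", "F9_asa_cos")
}

#' ProteinModel: one parsed structural model
#'
#' Holds the heavy-atom coordinates of a single decoy (or reference
#' structure), residue-indexed. Residues are renumbered 1..N internally in
#' file order; author numbering (chain, resno, insertion code) is kept as
#' metadata. Every retained residue has a CA atom.
#'
#' @slot modelId character identifier of the model.
#' @slot targetId character identifier of the target the model belongs to.
#' @slot atoms data.frame with columns \code{residue} (internal 1-based
#'   index), \code{name}, \code{resname}, \code{chain}, \code{resno},
#'   \code{insert}, \code{x}, \code{y}, \code{z}, \code{element}.
#' @export
setClass("ProteinModel",
  representation(modelId = "character", targetId = "character",
                 atoms = "data.frame"),
  validity = function(object) {
    a <- object@atoms
    need <- c("residue", "name", "resname", "chain", "resno", "insert",
              "x", "y", "z", "element")
    if (!all(need %in% names(a)))
      return(sprintf("atoms must have columns: %s", paste(need, collapse = ", ")))
    if (nrow(a) == 0L) return("model has no atoms")
    if (!all(is.finite(a$x) & is.finite(a$y) & is.finite(a$z)))
      return("non-finite coordinates")
    has_ca <- tapply(a$name == "CA", a$residue, any)
    if (!all(has_ca)) return("every residue must retain a CA atom")
    TRUE
  })

#' TargetPool: a target's decoy set with features and labels
#'
#' @slot targetId character.
#' @slot features data.frame with a \code{model_id} column followed by the
#'   nine feature columns (see \code{\link{featureNames}}); raw or
#'   pool-normalized depending on \code{normalized}.
#' @slot labels named numeric vector of TM-scores against the reference
#'   (NA when no reference exists); names match \code{model_id}.
#' @slot normalized logical; TRUE after per-pool min-max normalization.
#' @slot hasReference logical.
#' @export
setClass("TargetPool",
  representation(targetId = "character", features = "data.frame",
                 labels = "numeric", normalized = "logical",
                 hasReference = "logical"),
  prototype(normalized = FALSE, hasReference = FALSE),
  validity = function(object) {
    f <- object@features
    if (!"model_id" %in% names(f)) return("features must have a model_id column")
    miss <- setdiff(featureNames(), names(f))
    if (length(miss)) return(sprintf("missing feature columns: %s",
                                     paste(miss, collapse = ", ")))
    if (anyDuplicated(f$model_id)) return("duplicate model_id in pool")
    if (length(object@labels) &&
        !setequal(names(object@labels), f$model_id))
      return("label names must match model_id")
    TRUE
  })

#' Superposition: result of a least-squares rigid-body fit
#'
#' @slot rotation 3x3 orthonormal matrix with determinant +1.
#' @slot translation length-3 numeric, Angstrom.
#' @slot rmsd numeric, RMSD over the fitted subset, Angstrom.
#' @slot alignedPairs integer indices of the residue pairs used in the fit.
#' @slot degenerate logical; TRUE when the point set was (near-)collinear.
#' @export
setClass("Superposition",
  representation(rotation = "matrix", translation = "numeric",
                 rmsd = "numeric", alignedPairs = "integer",
                 degenerate = "logical"),
  prototype(degenerate = FALSE),
  validity = function(object) {
    R <- object@rotation
    if (!all(dim(R) == c(3, 3))) return("rotation must be 3x3")
    if (abs(det(R) - 1) > 1e-9) return("rotation determinant must be +1")
    if (max(abs(crossprod(R) - diag(3))) > 1e-6)
      return("rotation must be orthonormal")
    if (object@rmsd < 0) return("rmsd must be nonnegative")
    TRUE
  })

#' RegressionForest: trained ensemble of regression trees
#'
#' @slot trees list of flattened tree structures (feature, threshold, left,
#'   right, value, count, bootstrap, oob) as grown by the C++ core.
#' @slot nTree integer number of trees.
#' @slot mTry integer features considered per split.
#' @slot nodeCutoff integer; a node with fewer rows is never split.
#' @slot seed numeric root seed of the deterministic per-tree streams.
#' @slot featureNames character, column order the forest was trained on.
#' @slot importance named numeric raw permutation importance per feature.
#' @slot oobError numeric, mean squared error of out-of-bag predictions.
#' @slot oobPredictions numeric OOB ensemble prediction per training row
#'   (NA where a row was in-bag for every tree).
#' @slot nTrain integer number of training rows.
#' @slot featureHash character; hash of feature order and normalization
#'   variant, checked at prediction time.
#' @export
setClass("RegressionForest",
  representation(trees = "list", nTree = "integer", mTry = "integer",
                 nodeCutoff = "integer", seed = "numeric",
                 featureNames = "character", importance = "numeric",
                 oobError = "numeric", oobPredictions = "numeric",
                 nTrain = "integer", featureHash = "character"),
  validity = function(object) {
    if (object@nTree < 1L) return("nTree must be >= 1")
    p <- length(object@featureNames)
    if (object@mTry < 1L || object@mTry > p)
      return(sprintf("mTry must be in [1, %d]", p))
    if (length(object@trees) != object@nTree)
      return("length(trees) must equal nTree")
    if (length(object@importance) &&
        length(object@importance) != p)
      return("importance length must equal number of features")
    TRUE
  })

#' EvaluationReport: metric suite for one quality-assessment method
#'
#' @slot method character method name.
#' @slot ccTM numeric Pearson correlation over targets between the TM-score
#'   of the selected model and the pool-best TM-score.
#' @slot spearman numeric Spearman rank correlation of the same quantities.
#' @slot meanTMLoss numeric mean of (TM_best - TM_selected) over targets.
#' @slot ccRank numeric mean per-target Spearman correlation of predicted
#'   vs. true rankings.
#' @slot zScores named numeric per-target Z-score of the selected model.
#' @slot zBins numeric counts in the bins Z<0, 0<=Z<1, 1<=Z<2, 2<=Z<3, Z>=3.
#' @slot tmSum numeric sum of TM-scores of the first-ranked models.
#' @slot zSum numeric sum of the per-target Z-scores.
#' @slot nTargets integer.
#' @export
setClass("EvaluationReport",
  representation(method = "character", ccTM = "numeric", spearman = "numeric",
                 meanTMLoss = "numeric", ccRank = "numeric",
                 zScores = "numeric", zBins = "numeric", tmSum = "numeric",
                 zSum = "numeric", nTargets = "integer"),
  validity = function(object) {
    if (length(object@zBins) != 5L) return("zBins must have 5 bins")
    if (length(object@zScores) &&
        sum(object@zBins) != sum(is.finite(object@zScores)))
      return("zBins must count the finite z-scores")
    if (is.finite(object@meanTMLoss) && object@meanTMLoss < -1e-12)
      return("meanTMLoss must be nonnegative")
    TRUE
  })

setMethod("show", "ProteinModel", function(object) {
  cat(sprintf("ProteinModel '%s' (target '%s'): %d residues, %d atoms\n",
              object@modelId, object@targetId,
              nResidues(object), nrow(object@atoms)))
})

setMethod("show", "TargetPool", function(object) {
  cat(sprintf("TargetPool '%s': %d models, %s, labels %s\n",
              object@targetId, nrow(object@features),
              if (object@normalized) "normalized" else "raw features",
              if (length(object@labels) && any(is.finite(object@labels)))
                "present" else "absent"))
})

setMethod("show", "RegressionForest", function(object) {
  cat(sprintf(paste0("RegressionForest: %d trees, mTry %d, node cutoff %d, ",
                     "%d training rows\n  OOB MSE %.5f\n"),
              object@nTree, object@mTry, object@nodeCutoff, object@nTrain,
              object@oobError))
})

setMethod("show", "EvaluationReport", function(object) {
  cat(sprintf("EvaluationReport [%s] over %d targets\n", object@method,
              object@nTargets))
  cat(sprintf("  CC_TM %.4f | Spearman %.4f | mean TM_loss %.4f | CC_rank %.4f\n",
              object@ccTM, object@spearman, object@meanTMLoss, object@ccRank))
  cat(sprintf("  TM_sum %.3f | Z_sum %.3f\n", object@tmSum, object@zSum))
})

# ---- accessors ----

#' @describeIn ProteinModel-class Number of residues.
#' @param model,object a \code{ProteinModel}.
#' @export
nResidues <- function(model) {
  stopifnot(is(model, "ProteinModel"))
  max(model@atoms$residue)
}

#' Model identifier accessor
#' @param x a ProteinModel or RegressionForest-like object with an id.
#' @export
modelId <- function(x) x@modelId

#' Target identifier accessor
#' @param x a ProteinModel or TargetPool.
#' @export
targetId <- function(x) x@targetId

#' Pool feature table accessor
#' @param pool a \code{TargetPool}.
#' @return data.frame with model_id and the nine feature columns.
#' @export
poolFeatures <- function(pool) pool@features

#' Pool label accessor
#' @param pool a \code{TargetPool}.
#' @return named numeric vector of TM-score labels (may contain NA).
#' @export
poolLabels <- function(pool) pool@labels

#' Is the pool normalized?
#' @param pool a \code{TargetPool}.
#' @export
isNormalized <- function(pool) pool@normalized

#' Forest importance accessor
#' @param forest a \code{RegressionForest}.
#' @return named numeric vector of raw permutation importances.
#' @export
forestImportance <- function(forest) forest@importance

#' Forest out-of-bag error accessor
#' @param forest a \code{RegressionForest}.
#' @export
oobError <- function(forest) forest@oobError

#' Per-target Z-scores of an evaluation report
#' @param report an \code{EvaluationReport}.
#' @export
zScores <- function(report) report@zScores
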