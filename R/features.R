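# Assembly of the 9-dimensional feature vector per model and the
# per-target [0,1] min-max normalization of features and TM-score labels.

#' Secondary-structure match fractions
#'
#' Fraction of positions where observed and predicted secondary structure
#' agree, split by state: helix = #\{i: obs_i = pred_i = H\} / N_res, and
#' likewise for sheet (E) and coil (C).
#'
#' @param observed,predicted equal-length strings over \{H, E, C\}.
#' @return named numeric (helix, sheet, coil), each in [0,1], sum <= 1.
#' @export
ssMatchFractions <- function(observed, predicted) {
  o <- strsplit(observed, "")[[1]]; p <- strsplit(predicted, "")[[1]]
  if (length(o) != length(p))
    stop("alignment error: secondary-structure strings differ in length")
  if (!length(o)) stop("empty secondary-structure string")
  n <- length(o)
  c(helix = sum(o == "H" & p == "H") / n,
    sheet = sum(o == "E" & p == "E") / n,
    coil  = sum(o == "C" & p == "C") / n)
}

#' Confidence-weighted secondary-structure consistency score
#'
#' \eqn{(1/N_{res}) \sum_i \delta(s_i^{obs}, s_i^{pred}) c_i} with
#' \eqn{\delta} the Kronecker delta and \eqn{c_i \in [0,1]} the predictor
#' confidence. With all confidences 1 this equals the sum of the three
#' match fractions. An alternative normalization by \eqn{\sum_i c_i} is
#' available via \code{normalize = "confidence"}.
#'
#' @param observed,predicted equal-length strings over \{H, E, C\}.
#' @param conf per-residue confidences in [0,1].
#' @param normalize "length" (default) or "confidence".
#' @return score in [0,1].
#' @export
ssConsistencyScore <- function(observed, predicted, conf,
                               normalize = c("length", "confidence")) {
  normalize <- match.arg(normalize)
  o <- strsplit(observed, "")[[1]]; p <- strsplit(predicted, "")[[1]]
  if (length(o) != length(p) || length(o) != length(conf))
    stop("alignment error: states and confidence must have equal length")
  if (any(conf < 0 | conf > 1)) stop("confidences must lie in [0,1]")
  num <- sum((o == p) * conf)
  den <- if (normalize == "length") length(o) else max(sum(conf), .Machine$double.eps)
  num / den
}

#' Solvent-accessibility consistency features
#'
#' Pearson correlation and cosine similarity between the per-residue ASA
#' observed in the 3D model and the ASA predicted from sequence.
#'
#' @param a_model,a_pred equal-length nonnegative numeric vectors
#'   (Angstrom^2), length >= 2.
#' @return named numeric \code{c(pearson, cosine)}; a zero-variance
#'   vector yields pearson 0 with a warning, a zero-norm vector cosine 0
#'   with a warning.
#' @export
asaConsistency <- function(a_model, a_pred) {
  if (length(a_model) != length(a_pred))
    stop("alignment error: ASA tracks differ in length")
  if (length(a_model) < 2) stop("ASA tracks must have length >= 2")
  if (stats::sd(a_model) == 0 || stats::sd(a_pred) == 0) {
    warning("zero-variance ASA vector; correlation set to 0")
    r <- 0
  } else {
    r <- stats::cor(a_model, a_pred)
  }
  na <- sqrt(sum(a_model^2)); np <- sqrt(sum(a_pred^2))
  if (na == 0 || np == 0) {
    warning("zero-norm ASA vector; cosine set to 0")
    cosv <- 0
  } else {
    cosv <- sum(a_model * a_pred) / (na * np)
  }
  c(pearson = r, cosine = cosv)
}

#' Assemble the 9-feature vector for one model
#'
#' Fixed order: three potential energies (dDFIRE, RWplus, GOAP slots),
#' helix/sheet/coil match fractions, the confidence-weighted consistency
#' score, and the two ASA consistency terms. See \code{\link{featureNames}}.
#'
#' @param model a \code{ProteinModel} (used for its id and length checks).
#' @param observed_ss,predicted_ss H/E/C strings of model length.
#' @param conf per-residue prediction confidences in [0,1].
#' @param asa_model,asa_pred per-residue ASA tracks, Angstrom^2.
#' @param energies list of three \code{EnergyTable}s in feature-slot order.
#' @param ss_normalize normalization variant for the consistency score.
#' @return named numeric vector of length 9.
#' @export
buildFeatureVector <- function(model, observed_ss, predicted_ss, conf,
                               asa_model, asa_pred, energies,
                               ss_normalize = "length") {
  n <- nResidues(model)
  if (nchar(observed_ss) != n || nchar(predicted_ss) != n ||
      length(conf) != n || length(asa_model) != n || length(asa_pred) != n)
    stop("alignment error: tracks must match the model length")
  if (length(energies) != 3)
    stop("exactly three energy tables are required")
  e <- vapply(energies, energyOf, numeric(1), model_id = modelId(model))
  m <- ssMatchFractions(observed_ss, predicted_ss)
  s7 <- ssConsistencyScore(observed_ss, predicted_ss, conf,
                           normalize = ss_normalize)
  a <- asaConsistency(asa_model, asa_pred)
  stats::setNames(c(e, m, s7, a), featureNames())
}

#' Construct a TargetPool from a feature table
#'
#' @param target_id target identifier.
#' @param features data.frame with \code{model_id} and the nine feature
#'   columns.
#' @param labels named numeric TM-score labels (optional; NA allowed).
#' @param normalized whether the features are already pool-normalized.
#' @return a \code{\link{TargetPool-class}}.
#' @export
newTargetPool <- function(target_id, features, labels = NULL,
                          normalized = FALSE) {
  if (is.null(labels))
    labels <- stats::setNames(rep(NA_real_, nrow(features)), features$model_id)
  labels <- labels[features$model_id]
  new("TargetPool", targetId = target_id,
      features = features[, c("model_id", featureNames())],
      labels = labels, normalized = normalized,
      hasReference = any(is.finite(labels)))
}

#' Per-pool min-max normalization of features and labels
#'
#' Maps every feature column, and the TM-score label when present, to
#' [0,1] within the target's pool via \eqn{(x - \min x) / (\max x - \min
#' x)}: the pool minimum maps to 0 and the maximum to 1. A constant
#' column is set to all zeros with a warning. Normalization is always
#' per-target, never across targets, so the resulting scores are relative
#' quality within a pool.
#'
#' @param pool a \code{TargetPool} with at least 2 models.
#' @return the normalized \code{TargetPool}.
#' @export
normalizePool <- function(pool) {
  f <- pool@features
  if (nrow(f) < 2) stop("normalization needs a pool of >= 2 models")
  minmax <- function(x, what) {
    lo <- min(x); hi <- max(x)
    if (hi == lo) {
      warning(sprintf("constant column '%s' in pool %s; set to 0",
                      what, pool@targetId))
      return(rep(0, length(x)))
    }
    (x - lo) / (hi - lo)
  }
  for (cn in featureNames()) f[[cn]] <- minmax(f[[cn]], cn)
  labels <- pool@labels
  if (any(is.finite(labels))) labels <- minmax(labels, "label")
  new("TargetPool", targetId = pool@targetId, features = f,
      labels = labels, normalized = TRUE,
      hasReference = pool@hasReference)
}

#' Extract the full feature table for a decoy pool
#'
#' Runs the observed-structure stand-ins (secondary structure via
#' \code{\link{assignSecondaryStructure}}, ASA via
#' \code{\link{computeASA}}) on every decoy, combines them with the
#' sequence-based predictions and the three energy tables, and computes
#' TM-score labels against the reference when one is given. Supplied
#' externally computed observed tracks take precedence over the
#' stand-ins.
#'
#' @param models list of \code{ProteinModel} decoys of one target.
#' @param target_id target identifier.
#' @param predicted_ss,conf sequence-based secondary-structure prediction
#'   and confidences.
#' @param asa_pred sequence-based ASA prediction, Angstrom^2.
#' @param energies list of three \code{EnergyTable}s.
#' @param reference optional reference \code{ProteinModel} for labels.
#' @param observed optional named list per model_id with elements
#'   \code{ss} and \code{asa} (e.g. parsed from DSSP files).
#' @param ss_normalize consistency-score normalization variant.
#' @return a raw (unnormalized) \code{TargetPool}.
#' @export
extractPoolFeatures <- function(models, target_id, predicted_ss, conf,
                                asa_pred, energies, reference = NULL,
                                observed = NULL, ss_normalize = "length") {
  rows <- lapply(models, function(m) {
    obs <- observed[[modelId(m)]]
    ss <- if (!is.null(obs$ss)) obs$ss else assignSecondaryStructure(m)
    asa <- if (!is.null(obs$asa)) obs$asa else computeASA(m)
    fv <- buildFeatureVector(m, ss, predicted_ss, conf, asa, asa_pred,
                             energies, ss_normalize = ss_normalize)
    data.frame(model_id = modelId(m), t(fv), check.names = FALSE,
               stringsAsFactors = FALSE)
  })
  features <- do.call(rbind, rows)
  labels <- if (is.null(reference)) NULL else
    stats::setNames(vapply(models, tmScore, numeric(1),
                           reference = reference),
                    vapply(models, modelId, character(1)))
  newTargetPool(target_id, features, labels)
}

#' Write a feature table to CSV
#'
#' Serializes one or more pools as a flat CSV with columns target_id,
#' model_id, F1..F9 and label. Lines starting with '#' carry provenance
#' and are skipped on reading.
#'
#' @param pools list of \code{TargetPool}s (or a single pool).
#' @param path output CSV path.
#' @param header optional character vector of '#' provenance lines.
#' @return \code{path}, invisibly.
#' @export
writeFeatureTable <- function(pools, path, header = NULL) {
  if (is(pools, "TargetPool")) pools <- list(pools)
  tabs <- lapply(pools, function(p) {
    cbind(data.frame(target_id = p@targetId,
                     stringsAsFactors = FALSE),
          p@features,
          data.frame(label = unname(p@labels[p@features$model_id])))
  })
  out <- do.call(rbind, tabs)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a feature table written by \code{\link{writeFeatureTable}}
#'
#' @param path CSV path.
#' @param normalized mark the pools as already normalized.
#' @return named list of \code{TargetPool}s, one per target_id.
#' @export
readFeatureTable <- function(path, normalized = FALSE) {
  if (!file.exists(path)) stop("feature table not found: ", path)
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("target_id", "model_id", featureNames())
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("format error: missing columns ", paste(miss, collapse = ", "))
  pools <- lapply(split(tab, tab$target_id), function(d) {
    labels <- if ("label" %in% names(d))
      stats::setNames(d$label, d$model_id) else NULL
    newTargetPool(d$target_id[1], d, labels, normalized = normalized)
  })
  pools[order(names(pools))]
}
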