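# Statistical-potential features. External programs (dDFIRE, GOAP,
# RWplus, ...) are ingested as 2-column score tables; a built-in
# residue-contact pseudo-potential is provided so the whole pipeline can
# run self-contained. Energies are only ever used through per-pool
# min-max normalization downstream, so units and absolute scale of the
# external programs never matter. Convention: lower = better.

#' EnergyTable: per-model energies from one scoring method
#'
#' @slot methodName character, e.g. "dDFIRE".
#' @slot scores named numeric vector, model_id -> energy (lower = better).
#' @export
setClass("EnergyTable",
  representation(methodName = "character", scores = "numeric"),
  validity = function(object) {
    if (!length(object@scores)) return("empty energy table")
    if (is.null(names(object@scores))) return("scores must be named by model_id")
    if (anyDuplicated(names(object@scores))) return("duplicate model_id")
    if (!all(is.finite(object@scores))) return("non-finite energy values")
    TRUE
  })

setMethod("show", "EnergyTable", function(object) {
  cat(sprintf("EnergyTable '%s': %d models, range [%.4g, %.4g]\n",
              object@methodName, length(object@scores),
              min(object@scores), max(object@scores)))
})

#' Read an external energy score table
#'
#' Parses a 2-column TSV/CSV of (model_id, energy), as written by
#' external statistical-potential programs. Lines starting with '#' are
#' skipped. Duplicate model ids or non-numeric energies are errors.
#'
#' @param path score table file.
#' @param method_name label for the feature slot (e.g. "dDFIRE").
#' @param flip_sign negate energies, for tables where higher = better.
#' @return an \code{\link{EnergyTable-class}}.
#' @export
readEnergyTable <- function(path, method_name, flip_sign = FALSE) {
  if (!file.exists(path)) stop("energy table not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  toks <- strsplit(trimws(lines[keep]), "[\t,\\s]+", perl = TRUE)
  if (!length(toks)) stop("format error: empty energy table ", path)
  ids <- vapply(toks, `[`, "", 1)
  vals <- suppressWarnings(as.numeric(vapply(toks, `[`, "", 2)))
  bad <- which(!is.finite(vals))
  if (length(bad))
    stop(sprintf("format error: non-numeric energy at line %d of %s",
                 lineno[bad[1]], path))
  if (anyDuplicated(ids))
    stop("format error: duplicate model_id '", ids[duplicated(ids)][1],
         "' in ", path)
  names(vals) <- ids
  if (flip_sign) vals <- -vals
  new("EnergyTable", methodName = method_name, scores = vals)
}

#' Look up a model's energy
#' @param table an \code{EnergyTable}.
#' @param model_id model identifier.
#' @return energy scalar; errors naming the table when absent.
#' @export
energyOf <- function(table, model_id) {
  if (!model_id %in% names(table@scores))
    stop(sprintf("%s: model %s absent", table@methodName, model_id))
  unname(table@scores[[model_id]])
}

# Kyte-Doolittle hydropathy, shifted to [0, 1] (1 = most hydrophobic);
# the pairwise product rewards hydrophobic burial.
.KD <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
         E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
         M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
         Y = -1.3, V = 4.2)

#' Built-in residue-contact pseudo-potential
#'
#' A deterministic CA-distance-binned contact energy for self-contained
#' testing of the pipeline: \eqn{E = \sum_{i<j, |i-j| \ge 3} w(aa_i,
#' aa_j, bin(d_{ij}))}. The shipped weights reward hydrophobic contacts
#' (distance bins 4-6.5, 6.5-8 and 8-10 Angstrom, weighted by the product
#' of shifted Kyte-Doolittle hydropathies) and penalize CA clashes below
#' 4 Angstrom. Lower = better; compact native-like conformations score
#' below expanded copies of themselves. Not a substitute for real
#' statistical potentials in production use.
#'
#' @param model a \code{ProteinModel} with CA atoms.
#' @return finite energy scalar (0 for chains with no pair |i-j| >= 3).
#' @export
contactPotential <- function(model) {
  ca <- caCoords(model)
  n <- nrow(ca)
  if (n < 4) return(0)
  h <- (.KD[strsplit(sequenceOf(model), "")[[1]]] + 4.5) / 9
  h[is.na(h)] <- 0.5
  d <- .pairdist(ca, ca)
  sep <- abs(outer(seq_len(n), seq_len(n), "-")) >= 3
  upper <- upper.tri(d)
  hh <- outer(h, h)
  w <- matrix(0, n, n)
  w[d < 4] <- 2.0
  band <- function(lo, hi, coef) {
    m <- d >= lo & d < hi
    w[m] <<- w[m] - coef * hh[m]
  }
  band(4, 6.5, 1.0)
  band(6.5, 8, 0.6)
  band(8, 10, 0.2)
  sum(w[sep & upper])
}
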