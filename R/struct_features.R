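# Observed structural features computed from a 3D model: a 3-state
# secondary-structure assignment via the Kabsch-Sander hydrogen-bond
# criterion and per-residue absolute solvent accessibility via the
# Shrake-Rupley rolling-probe method. Both are documented stand-ins for
# DSSP so the pipeline is self-contained; externally produced DSSP /
# PSIPRED-style / accessibility-prediction files can be parsed instead
# and take precedence when supplied.

.VDW <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)

# Maximum ASA per residue (Tien et al. theoretical values, Angstrom^2),
# used to convert relative accessibility predictions to absolute.
.MAX_ASA <- c(A = 129, R = 274, N = 195, D = 193, C = 167, Q = 225,
              E = 223, G = 104, H = 224, I = 197, L = 201, K = 236,
              M = 224, F = 240, P = 159, S = 155, T = 172, W = 285,
              Y = 263, V = 174)

#' Maximum solvent accessibility table
#'
#' Per-residue theoretical maximum absolute solvent accessibility
#' (Angstrom^2) used to convert relative accessibility to absolute.
#' @return named numeric vector over the 20 one-letter codes.
#' @export
maxASATable <- function() .MAX_ASA

# Express coordinates in a molecule-fixed frame (centered, principal
# axes, signs fixed by the third moment) so that the deterministic
# sphere-point set yields surface areas invariant under rigid rotation
# and translation of the input model.
.canonicalFrame <- function(xyz) {
  xyz <- sweep(xyz, 2, colMeans(xyz))
  if (nrow(xyz) < 3) return(xyz)
  cv <- crossprod(xyz) / nrow(xyz)
  if (max(abs(cv)) < 1e-12) return(xyz)
  V <- eigen(cv, symmetric = TRUE)$vectors
  for (k in 1:3) {
    pk <- as.numeric(xyz %*% V[, k])
    s3 <- sum(pk^3)
    if (abs(s3) > 1e-6) {
      if (s3 < 0) V[, k] <- -V[, k]
    } else if (V[which.max(abs(V[, k])), k] < 0) {
      V[, k] <- -V[, k]
    }
  }
  if (det(V) < 0) V[, 3] <- -V[, 3]
  xyz %*% V
}

.pairdist <- function(A, B) {
  # Euclidean distances between rows of A and rows of B
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  sqrt(pmax(d2, 0))
}

#' Assign 3-state secondary structure from coordinates
#'
#' Stand-in for DSSP implementing the Kabsch-Sander electrostatic
#' hydrogen-bond criterion: the amide H is reconstructed from the previous
#' residue's carbonyl, the H-bond energy
#' \eqn{E = 0.084 \cdot 332 (1/r_{ON} + 1/r_{CH} - 1/r_{OH} - 1/r_{CN})}
#' (kcal/mol) is evaluated for every donor/acceptor pair, and a bond is
#' called when E < -0.5 kcal/mol. Helices (3-, 4- and 5-turns, i.e. DSSP
#' G/H/I) reduce to 'H', isolated parallel/antiparallel bridges (DSSP E/B)
#' to 'E', everything else to 'C'.
#'
#' @param model a \code{ProteinModel} with backbone N, CA, C, O atoms.
#' @return character string over \{H, E, C\} of length \code{nResidues(model)}.
#' @export
assignSecondaryStructure <- function(model) {
  n <- nResidues(model)
  N <- .atomCoords(model, "N")
  C <- .atomCoords(model, "C")
  O <- .atomCoords(model, "O")
  complete <- rowSums(is.na(cbind(N, C, O))) == 0
  if (sum(complete) < 5L) {
    warning("fewer than 5 residues with complete backbone; returning all-coil")
    return(strrep("C", n))
  }
  res3 <- model@atoms$resname[!duplicated(model@atoms$residue)]

  # reconstructed amide H: 1.0 A from N, opposite the previous carbonyl O->C
  H <- matrix(NA_real_, n, 3)
  for (i in 2:n) {
    v <- C[i - 1, ] - O[i - 1, ]
    nv <- sqrt(sum(v^2))
    if (is.finite(nv) && nv > 0) H[i, ] <- N[i, ] + v / nv
  }

  # donor d (its N-H) to acceptor a (its C=O); prolines cannot donate
  can_donate <- !is.na(H[, 1]) & res3 != "PRO" & complete
  can_accept <- complete
  rON <- .pairdist(O, N); rCH <- .pairdist(C, H)
  rOH <- .pairdist(O, H); rCN <- .pairdist(C, N)
  E <- 0.084 * 332 * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
  E[!is.finite(E)] <- 0
  hb <- E < -0.5                    # hb[a, d]: CO of a accepts NH of d
  hb[!can_accept, ] <- FALSE
  hb[, !can_donate] <- FALSE
  near <- abs(outer(seq_len(n), seq_len(n), "-")) < 2
  hb[near] <- FALSE

  ss <- rep("C", n)

  # bridges (strand): i < j, j >= i + 3
  isE <- rep(FALSE, n)
  hbp <- function(a, d) a >= 1 && a <= n && d >= 1 && d <= n && hb[a, d]
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j < i + 3) next
      par <- (hbp(i - 1, j) && hbp(j, i + 1)) ||
             (hbp(j - 1, i) && hbp(i, j + 1))
      anti <- (hbp(i, j) && hbp(j, i)) ||
              (hbp(i - 1, j + 1) && hbp(j - 1, i + 1))
      if (par || anti) isE[c(i, j)] <- TRUE
    }
  }

  # n-turns -> helix: turns at i-1 and i extend residues i .. i+k-1
  for (k in c(4, 3, 5)) {
    turn <- rep(FALSE, n)
    for (i in seq_len(n - k)) turn[i] <- hb[i, i + k]
    for (i in 2:max(2, n - k)) {
      if (turn[i - 1] && turn[i]) ss[i:(i + k - 1)] <- "H"
    }
  }
  ss[isE & ss != "H"] <- "E"
  paste(ss, collapse = "")
}

#' Per-residue absolute solvent accessibility (Shrake-Rupley)
#'
#' Rolling-probe accessible surface area with a deterministic
#' golden-section spiral point set, summed over the heavy atoms of each
#' residue. Van der Waals radii: C 1.70, N 1.55, O 1.52, S 1.80 (others
#' 1.70); probe radius 1.4 Angstrom.
#'
#' @param model a \code{ProteinModel}.
#' @param probe probe radius in Angstrom (default 1.4).
#' @param n_points sphere points per atom (default 960).
#' @return numeric vector of per-residue ASA in Angstrom^2.
#' @export
computeASA <- function(model, probe = 1.4, n_points = 960L) {
  a <- model@atoms
  heavy <- toupper(substr(a$element, 1, 1)) != "H"
  a <- a[heavy, , drop = FALSE]
  radii <- .VDW[toupper(substr(a$element, 1, 1))]
  radii[is.na(radii)] <- 1.70
  per_atom <- .sasa_atoms(.canonicalFrame(as.matrix(a[, c("x", "y", "z")])),
                          unname(radii), probe, as.integer(n_points))
  as.numeric(tapply(per_atom, factor(a$residue, levels = seq_len(nResidues(model))),
                    sum, default = 0))
}

.reduce8to3 <- function(states) {
  out <- rep("C", length(states))
  out[states %in% c("H", "G", "I")] <- "H"
  out[states %in% c("E", "B")] <- "E"
  out
}

#' Parse classic DSSP text output
#'
#' Extracts the per-residue secondary-structure column (reduced to 3
#' states: H/G/I to H, E/B to E, rest to C) and the ACC column of
#' absolute solvent accessibility. Chain-break rows are skipped.
#'
#' @param path DSSP output file.
#' @param model optional \code{ProteinModel}; when given, the DSSP
#'   sequence is checked against the model sequence and mismatching
#'   positions raise an alignment error.
#' @return list with \code{states} (character string over H/E/C),
#'   \code{asa} (numeric vector, Angstrom^2) and \code{sequence}.
#' @export
parseDSSPFile <- function(path, model = NULL) {
  if (!file.exists(path)) stop("DSSP file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^  #  RESIDUE", lines)
  if (!length(hdr)) stop("format error: DSSP residue header not found in ", path)
  body <- lines[(hdr[1] + 1):length(lines)]
  body <- body[nchar(body) >= 38]
  aa <- substr(body, 14, 14)
  keep <- aa != "!"
  body <- body[keep]; aa <- aa[keep]
  if (!length(body)) stop("format error: DSSP file has no residue rows")
  states <- .reduce8to3(substr(body, 17, 17))
  asa <- suppressWarnings(as.numeric(substr(body, 35, 38)))
  if (anyNA(asa)) stop("format error: unreadable ACC column in ", path)
  seq <- paste(aa, collapse = "")
  if (!is.null(model)) {
    mseq <- sequenceOf(model)
    if (nchar(mseq) != nchar(seq))
      stop("alignment error: DSSP has ", nchar(seq), " residues, model has ",
           nchar(mseq))
    mm <- which(strsplit(seq, "")[[1]] != strsplit(mseq, "")[[1]])
    if (length(mm))
      stop("alignment error: sequence mismatch at positions ",
           paste(mm, collapse = ", "))
  }
  list(states = paste(states, collapse = ""), asa = asa, sequence = seq)
}

#' Parse a secondary-structure prediction file
#'
#' Accepts the PSIPRED vertical (.ss2) format (index, residue, state,
#' three class probabilities; confidence = the maximum class probability)
#' or a generic 3-column table (residue, state, confidence) where integer
#' confidences 0-9 are divided by 9.
#'
#' @param path prediction file.
#' @return list with \code{states} (string over H/E/C) and
#'   \code{confidence} (numeric in [0,1]).
#' @export
parseSSPrediction <- function(path) {
  if (!file.exists(path)) stop("prediction file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  toks <- strsplit(trimws(lines), "[\\s,]+", perl = TRUE)
  ncols <- lengths(toks)
  if (!length(toks)) stop("format error: empty prediction file ", path)
  if (all(ncols >= 6)) {             # PSIPRED vertical format
    state <- vapply(toks, `[`, "", 3)
    probs <- t(vapply(toks, function(t) as.numeric(t[4:6]), numeric(3)))
    conf <- apply(probs, 1, max)
  } else if (all(ncols == 3)) {      # generic (residue, state, confidence)
    state <- vapply(toks, `[`, "", 2)
    conf <- as.numeric(vapply(toks, `[`, "", 3))
    raw <- vapply(toks, `[`, "", 3)
    if (all(grepl("^[0-9]$", raw))) conf <- conf / 9
  } else {
    stop("format error: unrecognized prediction layout in ", path)
  }
  if (anyNA(conf)) stop("format error: non-numeric confidence in ", path)
  bad <- !state %in% c("H", "E", "C")
  if (any(bad))
    stop("format error: unknown secondary-structure state '",
         state[which(bad)[1]], "' in ", path)
  list(states = paste(state, collapse = ""),
       confidence = pmin(pmax(conf, 0), 1))
}

#' Parse a solvent-accessibility prediction file
#'
#' Accepts a 2-column table (residue index, absolute ASA in Angstrom^2)
#' or, with \code{relative = TRUE}, a 3-column table (index, one-letter
#' residue, relative ASA in [0,1]) converted to absolute via the shipped
#' maximum-ASA table. Negative values are clamped to 0 with a warning.
#'
#' @param path prediction file.
#' @param relative interpret values as relative accessibility.
#' @return numeric vector of absolute ASA, Angstrom^2.
#' @export
parseASAPrediction <- function(path, relative = FALSE) {
  if (!file.exists(path)) stop("prediction file not found: ", path)
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (relative) {
    if (ncol(tab) < 3)
      stop("format error: relative ASA table needs (index, residue, value)")
    mx <- .MAX_ASA[toupper(tab[[2]])]
    if (anyNA(mx))
      stop("format error: unknown residue letter in ", path)
    vals <- as.numeric(tab[[3]]) * unname(mx)
  } else {
    vals <- as.numeric(tab[[ncol(tab)]])
  }
  if (anyNA(vals)) stop("format error: non-numeric ASA value in ", path)
  if (any(vals < 0)) {
    warning("negative predicted ASA clamped to 0")
    vals <- pmax(vals, 0)
  }
  vals
}
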