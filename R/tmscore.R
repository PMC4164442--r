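# TM-score between a decoy and a reference structure. The score is the
# training label, the screening statistic and the basis of every
# evaluation metric, so it is computed deterministically: Kabsch
# least-squares superposition plus the standard iterative seed-fragment
# extension search over superpositions.

.cbrt <- function(x) sign(x) * abs(x)^(1 / 3)

#' TM-score distance scale d0
#'
#' \eqn{d_0(L) = 1.24 (L - 15)^{1/3} - 1.8}, floored at 0.5 Angstrom for
#' short chains; L is the reference length.
#'
#' @param L reference chain length (residues).
#' @return d0 in Angstrom.
#' @export
tmD0 <- function(L) pmax(0.5, 1.24 * .cbrt(L - 15) - 1.8)

#' Kabsch least-squares rigid-body superposition
#'
#' Finds the rotation (determinant +1; reflections prevented) and
#' translation minimizing the RMSD of \code{coords_b} onto
#' \code{coords_a}.
#'
#' @param coords_a,coords_b n x 3 coordinate matrices (Angstrom), n >= 3.
#' @return a \code{\link{Superposition-class}}: \code{rotation} R and
#'   \code{translation} t such that \code{coords_b \%*\% t(R) + t}
#'   superposes onto \code{coords_a}; near-collinear point sets are
#'   flagged \code{degenerate} but still fitted.
#' @export
kabschSuperpose <- function(coords_a, coords_b) {
  fit <- .kabschFit(as.matrix(coords_a), as.matrix(coords_b))
  if (fit$degenerate)
    warning("near-collinear point set; fit may be ill-determined")
  new("Superposition", rotation = fit$rotation,
      translation = fit$translation, rmsd = fit$rmsd,
      alignedPairs = seq_len(nrow(coords_a)), degenerate = fit$degenerate)
}

# plain-list core used in the TM-score search hot loop
.kabschFit <- function(coords_a, coords_b) {
  if (nrow(coords_a) != nrow(coords_b))
    stop("coordinate sets must have equal length")
  n <- nrow(coords_a)
  if (n < 3) stop("at least 3 points are required for superposition")
  ca <- colMeans(coords_a); cb <- colMeans(coords_b)
  P <- sweep(coords_b, 2, cb); Q <- sweep(coords_a, 2, ca)
  H <- crossprod(P, Q)
  sv <- svd(H)
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted <- P %*% t(R)
  list(rotation = R, translation = as.numeric(ca - R %*% cb),
       rmsd = sqrt(mean(rowSums((fitted - Q)^2))),
       degenerate = sv$d[2] < 1e-8 * max(sv$d[1], 1))
}

.applySuperposition <- function(sup, coords) {
  sweep(coords %*% t(sup$rotation), 2, sup$translation, "+")
}

#' TM-score of a decoy against a reference
#'
#' Length-normalized structural similarity in (0, 1] over CA atoms:
#' \eqn{TM = \max \frac{1}{L} \sum_i 1 / (1 + (d_i/d_0)^2)} with L the
#' reference length and d0 from \code{\link{tmD0}}. The maximum over
#' superpositions is searched by iterative seed-fragment extension: seed
#' windows of length L, L/2 and L/4 are superposed, residue pairs closer
#' than a d0-based cutoff are selected, and the fit/select cycle is
#' iterated to convergence; the best score over all seeds is returned.
#' Residue correspondence is by position after a sequence-identity check;
#' residues missing a CA in either model are skipped.
#'
#' @param decoy,reference \code{ProteinModel} objects over the same
#'   sequence positions.
#' @return TM-score in (0, 1].
#' @export
tmScore <- function(decoy, reference) {
  xd <- caCoords(decoy); xr <- caCoords(reference)
  L <- nrow(xr)
  n <- min(nrow(xd), L)
  ok <- which(stats::complete.cases(xd[seq_len(n), , drop = FALSE]) &
              stats::complete.cases(xr[seq_len(n), , drop = FALSE]))
  if (length(ok) < 3) stop("fewer than 3 common residues with CA atoms")
  sd_ <- substr(sequenceOf(decoy), 1, n); sr <- substr(sequenceOf(reference), 1, n)
  if (sd_ != sr)
    warning("decoy and reference sequences differ; scoring by position")
  A <- xd[ok, , drop = FALSE]; B <- xr[ok, , drop = FALSE]
  na <- length(ok)
  d0 <- tmD0(L)

  score_of <- function(sup) {
    d <- sqrt(rowSums((.applySuperposition(sup, A) - B)^2))
    list(score = sum(1 / (1 + (d / d0)^2)) / L, d = d)
  }

  best <- 0
  seed_len <- unique(pmax(4L, floor(na / c(1L, 2L, 4L))))
  seed_len <- seed_len[seed_len <= na]
  for (l in seed_len) {
    step <- max(1L, l %/% 2L)
    starts <- unique(c(seq(1L, na - l + 1L, by = step), na - l + 1L))
    for (s in starts) {
      idx <- s:(s + l - 1L)
      sup <- .kabschFit(B[idx, , drop = FALSE], A[idx, , drop = FALSE])
      prev <- integer(0)
      for (it in seq_len(20L)) {
        sc <- score_of(sup)
        if (sc$score > best) best <- sc$score
        cut <- d0
        sel <- which(sc$d < cut)
        while (length(sel) < 3L) {
          cut <- cut + 0.5
          sel <- which(sc$d < cut)
        }
        if (identical(sel, prev)) break
        prev <- sel
        sup <- .kabschFit(B[sel, , drop = FALSE],
                          A[sel, , drop = FALSE])
      }
      sc <- score_of(sup)
      if (sc$score > best) best <- sc$score
    }
  }
  best
}
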