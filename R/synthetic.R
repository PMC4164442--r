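# Synthetic study material: reference backbones built from ideal
# internal coordinates, decoy pools with a controlled quality gradient,
# simulated sequence-based predictions with tunable agreement, and
# simulated energies with tunable correlation to quality. Everything is
# deterministic per seed, so the full pipeline is testable with no
# external binaries or downloads.

.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Decoy generator parameters
#'
#' Study conditions for the synthetic pools. Defaults: 30-residue
#' helix-loop-helix targets, 10 decoys per pool with per-residue rigid
#' jitter scales spread over 0 to 3 Angstrom (a quality gradient from
#' native to heavily distorted), secondary-structure predictions correct
#' at 85% of positions, accessibility predictions with 15 Angstrom^2
#' noise, and simulated energies correlating with (1 - TM) at 0.8.
#'
#' @param n_residues chain length (>= 8).
#' @param topology "helix", "helix-loop-helix" or "strand-pair".
#' @param n_decoys decoys per pool (>= 2).
#' @param noise_sigmas per-decoy jitter scale, Angstrom (length n_decoys;
#'   must not be all equal).
#' @param ss_pred_accuracy probability a predicted state is correct.
#' @param asa_pred_noise_sd Gaussian noise of the ASA prediction, A^2.
#' @param energy_quality_corr target correlation between each simulated
#'   energy and (1 - TM), in [-1, 1].
#' @param seed integer seed.
#' @return a list of class \code{DecoyGeneratorParams}.
#' @export
decoyGeneratorParams <- function(n_residues = 30L,
                                 topology = c("helix-loop-helix", "helix",
                                              "strand-pair"),
                                 n_decoys = 10L,
                                 noise_sigmas = seq(0, 3, length.out = n_decoys),
                                 ss_pred_accuracy = 0.85,
                                 asa_pred_noise_sd = 15,
                                 energy_quality_corr = 0.8,
                                 seed = 1L) {
  topology <- match.arg(topology)
  if (n_residues < 8) stop("parameter error: n_residues must be >= 8")
  if (n_decoys < 2) stop("parameter error: n_decoys must be >= 2")
  if (length(noise_sigmas) != n_decoys)
    stop("parameter error: noise_sigmas must have length n_decoys")
  if (ss_pred_accuracy < 0 || ss_pred_accuracy > 1 ||
      abs(energy_quality_corr) > 1)
    stop("parameter error: probabilities/correlations out of range")
  structure(list(n_residues = as.integer(n_residues), topology = topology,
                 n_decoys = as.integer(n_decoys),
                 noise_sigmas = as.numeric(noise_sigmas),
                 ss_pred_accuracy = ss_pred_accuracy,
                 asa_pred_noise_sd = asa_pred_noise_sd,
                 energy_quality_corr = energy_quality_corr,
                 seed = as.integer(seed)),
            class = "DecoyGeneratorParams")
}

# NeRF atom placement: position D at distance r from C, angle(B,C,D) =
# theta, dihedral(A,B,C,D) = chi (degrees)
.placeAtom <- function(A, B, C, r, theta, chi) {
  th <- theta * pi / 180; ch <- chi * pi / 180
  d2 <- c(-r * cos(th), r * cos(ch) * sin(th), r * sin(ch) * sin(th))
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A; ab <- ab / sqrt(sum(ab^2))
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  C + cbind(bc, m, n) %*% d2
}

# per-residue (phi, psi) for the supported topologies
.topologyTorsions <- function(n, topology) {
  helix <- c(-57, -47); strand <- c(-120, 120); loop <- c(-75, 145)
  phi_psi <- matrix(rep(helix, n), ncol = 2, byrow = TRUE)
  if (topology == "helix-loop-helix") {
    l1 <- max(3L, floor(0.4 * n)); ll <- max(2L, floor(0.2 * n))
    for (i in (l1 + 1):(l1 + ll)) phi_psi[i, ] <- loop
  } else if (topology == "strand-pair") {
    half <- floor((n - 2) / 2)
    phi_psi[seq_len(half), ] <- matrix(rep(strand, half), ncol = 2, byrow = TRUE)
    phi_psi[half + 1, ] <- c(-60, -30)
    phi_psi[half + 2, ] <- c(-90, 0)
    rest <- (half + 3):n
    phi_psi[rest, ] <- matrix(rep(strand, length(rest)), ncol = 2, byrow = TRUE)
  }
  phi_psi
}

# a fixed mixed sequence so hydropathy-based terms are non-trivial
.syntheticSequence <- function(n) {
  pat <- c("ALA", "VAL", "LEU", "GLU", "LYS", "ILE", "ASP", "PHE", "SER",
           "ARG")
  pat[(seq_len(n) - 1) %% length(pat) + 1]
}

#' Build a reference backbone from ideal internal coordinates
#'
#' Places N, CA, C and O atoms residue by residue (NeRF) using standard
#' bond lengths (N-CA 1.458, CA-C 1.525, C-N 1.329, C=O 1.231 Angstrom)
#' and angles, with torsions set by the topology: helix phi -57 / psi
#' -47, strand phi -120 / psi 120, plus a loop or turn segment for the
#' multi-segment topologies. Deterministic per parameter set.
#'
#' @param params a \code{\link{decoyGeneratorParams}} list.
#' @param target_id identifier for the built target.
#' @return a \code{ProteinModel} of the reference structure.
#' @export
makeReference <- function(params = decoyGeneratorParams(),
                          target_id = "synthetic") {
  n <- params$n_residues
  tor <- .topologyTorsions(n, params$topology)
  N <- CA <- C <- O <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(1.458, 0, 0)
  C[1, ] <- CA[1, ] + 1.525 * c(cos(pi * (180 - 111.2) / 180),
                                sin(pi * (180 - 111.2) / 180), 0)
  for (i in 2:n) {
    N[i, ] <- .placeAtom(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                         1.329, 116.2, tor[i - 1, 2])
    CA[i, ] <- .placeAtom(CA[i - 1, ], C[i - 1, ], N[i, ],
                          1.458, 121.7, 180)
    C[i, ] <- .placeAtom(C[i - 1, ], N[i, ], CA[i, ],
                         1.525, 111.2, tor[i, 1])
  }
  for (i in seq_len(n)) {
    psi <- tor[i, 2]
    O[i, ] <- .placeAtom(N[i, ], CA[i, ], C[i, ], 1.231, 120.5, psi + 180)
  }
  seqs <- .syntheticSequence(n)
  atoms <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(residue = i,
               name = c("N", "CA", "C", "O"),
               resname = seqs[i], chain = "A", resno = i, insert = "",
               x = c(N[i, 1], CA[i, 1], C[i, 1], O[i, 1]),
               y = c(N[i, 2], CA[i, 2], C[i, 2], O[i, 2]),
               z = c(N[i, 3], CA[i, 3], C[i, 3], O[i, 3]),
               element = c("N", "C", "C", "O"),
               stringsAsFactors = FALSE)
  }))
  new("ProteinModel", modelId = paste0(target_id, "_ref"),
      targetId = target_id, atoms = atoms)
}

.jitterModel <- function(reference, sigma, model_id) {
  a <- reference@atoms
  n <- max(a$residue)
  shift <- matrix(stats::rnorm(3 * n, sd = sigma), n, 3)
  a$x <- a$x + shift[a$residue, 1]
  a$y <- a$y + shift[a$residue, 2]
  a$z <- a$z + shift[a$residue, 3]
  new("ProteinModel", modelId = model_id, targetId = reference@targetId,
      atoms = a)
}

#' Generate a synthetic decoy pool
#'
#' Decoy i is the reference plus iid Gaussian rigid per-residue jitter of
#' scale \code{noise_sigmas[i]} (the same displacement applied to all
#' backbone atoms of a residue, so secondary structure degrades smoothly
#' with noise). Labels are TM-scores against the reference. Simulated
#' predictor outputs emulate sequence-based tools: secondary-structure
#' predictions agree with the reference assignment at rate
#' \code{ss_pred_accuracy} with higher confidence on correct positions;
#' ASA predictions are the reference ASA plus Gaussian noise; the three
#' simulated energies are affine in (1 - TM) plus Gaussian noise tuned
#' to the requested correlation level.
#'
#' @param params a \code{\link{decoyGeneratorParams}} list.
#' @param target_id target identifier.
#' @param extract_features also run the observed-structure stand-ins and
#'   return a ready \code{TargetPool} (default TRUE).
#' @return list with \code{reference}, \code{models}, \code{labels},
#'   \code{predicted_ss}, \code{conf}, \code{asa_pred}, \code{energies}
#'   and (when extracted) \code{pool}.
#' @export
makeDecoyPool <- function(params = decoyGeneratorParams(),
                          target_id = "synthetic",
                          extract_features = TRUE) {
  if (length(unique(params$noise_sigmas)) < 2)
    stop("parameter error: degenerate noise_sigmas (all equal)")
  .withSeed(params$seed, {
    reference <- makeReference(params, target_id)
    ids <- sprintf("%s_m%02d", target_id, seq_len(params$n_decoys))
    models <- lapply(seq_len(params$n_decoys), function(i)
      .jitterModel(reference, params$noise_sigmas[i], ids[i]))
    labels <- stats::setNames(
      vapply(models, tmScore, numeric(1), reference = reference), ids)

    # sequence-based secondary-structure prediction of tunable accuracy
    ss_ref <- strsplit(assignSecondaryStructure(reference), "")[[1]]
    n <- params$n_residues
    correct <- stats::runif(n) < params$ss_pred_accuracy
    pred <- ss_ref
    for (i in which(!correct))
      pred[i] <- sample(setdiff(c("H", "E", "C"), ss_ref[i]), 1)
    conf <- ifelse(correct, stats::runif(n, 0.65, 0.95),
                   stats::runif(n, 0.35, 0.65))

    asa_ref <- computeASA(reference)
    asa_pred <- pmax(0, asa_ref + stats::rnorm(n, sd = params$asa_pred_noise_sd))

    # simulated energies: correlated with (1 - TM) at the requested level
    rho <- params$energy_quality_corr
    q <- 1 - labels
    qs <- if (stats::sd(q) > 0) (q - mean(q)) / stats::sd(q) else q * 0
    energies <- lapply(c("dDFIRE", "RWplus", "GOAP"), function(nm) {
      e <- rho * qs + sqrt(max(0, 1 - rho^2)) * stats::rnorm(length(q))
      new("EnergyTable", methodName = nm,
          scores = stats::setNames(100 * e - 1000, ids))
    })

    out <- list(reference = reference, models = models, labels = labels,
                predicted_ss = paste(pred, collapse = ""), conf = conf,
                asa_pred = asa_pred, energies = energies)
    if (extract_features) {
      out$pool <- extractPoolFeatures(models, target_id,
                                      out$predicted_ss, conf, asa_pred,
                                      energies, reference = reference)
    }
    out
  })
}

#' Generate a set of synthetic target pools
#'
#' Convenience wrapper producing \code{n_pools} independent pools with
#' per-pool seeds derived from the root seed by fixed offsets.
#'
#' @param n_pools number of targets.
#' @param params base \code{\link{decoyGeneratorParams}}.
#' @param prefix target_id prefix.
#' @return named list of the \code{\link{makeDecoyPool}} results.
#' @export
makePoolSet <- function(n_pools, params = decoyGeneratorParams(),
                        prefix = "T") {
  out <- lapply(seq_len(n_pools), function(i) {
    p <- params
    p$seed <- params$seed + 1009L * i
    makeDecoyPool(p, target_id = sprintf("%s%03d", prefix, i))
  })
  names(out) <- vapply(out, function(x) x$reference@targetId, character(1))
  out
}

#' Write a simulated pool to disk
#'
#' Emits what the external-tool workflow would supply: one PDB per decoy
#' plus the reference, a secondary-structure prediction table, an ASA
#' prediction table, one energy table per method, and a labels CSV.
#'
#' @param sim a \code{\link{makeDecoyPool}} result.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeSimulatedPool <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writePDB(sim$reference, file.path(dir, "reference.pdb"))
  for (m in sim$models)
    writePDB(m, file.path(dir, paste0(modelId(m), ".pdb")))
  st <- strsplit(sim$predicted_ss, "")[[1]]
  utils::write.table(data.frame(seq_along(st), st, sprintf("%.3f", sim$conf)),
                     file.path(dir, "ss_prediction.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  utils::write.table(data.frame(seq_along(sim$asa_pred),
                                sprintf("%.2f", sim$asa_pred)),
                     file.path(dir, "asa_prediction.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  for (e in sim$energies)
    utils::write.table(data.frame(names(e@scores), e@scores),
                       file.path(dir, paste0("energy_", e@methodName, ".tsv")),
                       sep = "\t", row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  utils::write.csv(data.frame(model_id = names(sim$labels),
                              tm_score = unname(sim$labels)),
                   file.path(dir, "labels.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(dir)
}
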