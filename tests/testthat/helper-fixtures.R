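# Shared fixtures and independent oracles, all built in code.

# minimal fixed-width PDB text; atoms = data.frame(name, resname, resno,
# x, y, z) plus optional chain / element / altloc columns
pdbText <- function(atoms, chain = "A") {
  lines <- vapply(seq_len(nrow(atoms)), function(i) {
    a <- atoms[i, ]
    alt <- if ("alt" %in% names(atoms)) a$alt else ""
    elem <- if ("element" %in% names(atoms)) a$element else
      substr(gsub("[0-9]", "", a$name), 1, 1)
    rec <- if ("record" %in% names(atoms)) a$record else "ATOM"
    sprintf("%-6s%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            rec, i, paste0(" ", a$name), alt, a$resname, chain,
            a$resno, a$x, a$y, a$z, 1.0, 0.0, elem)
  }, character(1))
  paste(c(lines, "END"), collapse = "\n")
}

# hand-written 3-residue ALA-GLY-ALA backbone along x
triPeptideAtoms <- function() {
  rows <- list()
  resn <- c("ALA", "GLY", "ALA")
  for (i in 1:3) {
    x0 <- (i - 1) * 3.8
    rows[[i]] <- data.frame(
      name = c("N", "CA", "C", "O"),
      resname = resn[i], resno = i,
      x = x0 + c(0, 1.0, 2.0, 2.4),
      y = c(0.5, 1.2, 0.4, -0.6), z = 0,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

writeTempPDB <- function(text) {
  path <- tempfile(fileext = ".pdb")
  writeLines(text, path)
  path
}

# Monte-Carlo SASA oracle: same radii/probe physics as the package, but
# random sampling instead of a deterministic spiral point set
mcSASA <- function(coords, radii, probe = 1.4, n_points = 4000, seed = 99) {
  set.seed(seed)
  n <- nrow(coords)
  out <- numeric(n)
  for (i in seq_len(n)) {
    R <- radii[i] + probe
    z <- runif(n_points, -1, 1)
    phi <- runif(n_points, 0, 2 * pi)
    r <- sqrt(1 - z^2)
    pts <- cbind(coords[i, 1] + R * r * cos(phi),
                 coords[i, 2] + R * r * sin(phi),
                 coords[i, 3] + R * z)
    free <- rep(TRUE, n_points)
    for (j in seq_len(n)[-i]) {
      Rj <- radii[j] + probe
      d2 <- (pts[, 1] - coords[j, 1])^2 + (pts[, 2] - coords[j, 2])^2 +
        (pts[, 3] - coords[j, 3])^2
      free <- free & d2 >= Rj^2
    }
    out[i] <- 4 * pi * R^2 * mean(free)
  }
  out
}

# TM-score oracle: direct numerical maximization of the TM objective
# over rigid-body parameters (multi-start Nelder-Mead), independent of
# the fragment-extension search path
tmOracle <- function(decoy, reference) {
  A <- caCoords(decoy); B <- caCoords(reference)
  L <- nrow(B)
  d0 <- tmD0(L)
  obj <- function(par) {
    cx <- cos(par[1]); sx <- sin(par[1])
    cy <- cos(par[2]); sy <- sin(par[2])
    cz <- cos(par[3]); sz <- sin(par[3])
    Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
    Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
    Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
    R <- Rz %*% Ry %*% Rx
    At <- sweep(A %*% t(R), 2, par[4:6], "+")
    d <- sqrt(rowSums((At - B)^2))
    -sum(1 / (1 + (d / d0)^2)) / L
  }
  starts <- as.matrix(expand.grid(a = c(0, pi / 2, pi, 3 * pi / 2),
                                  b = c(0, pi / 2, pi),
                                  c = c(0, pi / 2, pi, 3 * pi / 2)))
  # also start from the global least-squares rotation (closed-form
  # algebra, not the fragment-extension heuristic under test)
  ls_fit <- kabschSuperpose(B, A)
  R <- ls_fit@rotation
  eul <- c(atan2(R[3, 2], R[3, 3]),
           atan2(-R[3, 1], sqrt(R[3, 2]^2 + R[3, 3]^2)),
           atan2(R[2, 1], R[1, 1]))
  starts <- rbind(starts, eul)
  shift0 <- colMeans(B) - colMeans(A)
  best <- -Inf
  for (k in seq_len(nrow(starts))) {
    fit <- optim(c(as.numeric(starts[k, ]), shift0), obj,
                 control = list(maxit = 4000, reltol = 1e-12))
    fit <- optim(fit$par, obj, control = list(maxit = 4000, reltol = 1e-12))
    best <- max(best, -fit$value)
  }
  best
}

# exhaustive CART regression oracle: best split over all features and
# all midpoints, recursive, same stopping rule as the forest trees
cartOracle <- function(X, y, node_cutoff = 5) {
  grow <- function(rows) {
    n <- length(rows)
    node <- list(value = mean(y[rows]), count = n, feature = NA,
                 threshold = NA, left = NULL, right = NULL)
    if (n < node_cutoff || var(y[rows]) < 1e-24) return(node)
    best <- NULL
    for (f in seq_len(ncol(X))) {
      v <- X[rows, f]
      sv <- sort(unique(v))
      if (length(sv) < 2) next
      for (thr in (sv[-1] + sv[-length(sv)]) / 2) {
        l <- rows[v <= thr]; r <- rows[v > thr]
        gain <- sum(y[l])^2 / length(l) + sum(y[r])^2 / length(r)
        if (is.null(best) || gain > best$gain)
          best <- list(f = f, thr = thr, gain = gain)
      }
    }
    if (is.null(best)) return(node)
    node$feature <- best$f
    node$threshold <- best$thr
    v <- X[rows, best$f]
    node$left <- grow(rows[v <= best$thr])
    node$right <- grow(rows[v > best$thr])
    node
  }
  grow(seq_along(y))
}

# flatten the package's tree (node arrays) into (feature, threshold)
# pairs in depth-first order, for comparison with the oracle
treeSplits <- function(tree) {
  out <- list()
  walk <- function(node) {
    if (tree$feature[node + 1] < 0) return()
    out[[length(out) + 1]] <<- c(feature = tree$feature[node + 1] + 1,
                                 threshold = tree$threshold[node + 1])
    walk(tree$left[node + 1])
    walk(tree$right[node + 1])
  }
  walk(0)
  do.call(rbind, out)
}

oracleSplits <- function(node) {
  out <- list()
  walk <- function(nd) {
    if (is.null(nd) || is.na(nd$feature)) return()
    out[[length(out) + 1]] <<- c(feature = nd$feature,
                                 threshold = nd$threshold)
    walk(nd$left)
    walk(nd$right)
  }
  walk(node)
  do.call(rbind, out)
}

# quick small pool set for pipeline tests: cheap settings, still
# exercising the full extraction path
smallPoolParams <- function(seed = 1, n_decoys = 6) {
  decoyGeneratorParams(n_residues = 16, topology = "helix",
                       n_decoys = n_decoys,
                       noise_sigmas = seq(0, 3, length.out = n_decoys),
                       seed = seed)
}

# feature-table-only pools (no structure work): labels drive features
# through a known monotone map plus noise, for protocol tests
syntheticFeaturePool <- function(target_id, n = 10, seed = 1,
                                 label_fun = NULL) {
  set.seed(seed)
  labels <- round(runif(n, 0.2, 0.95), 3)
  f <- data.frame(model_id = sprintf("%s_m%02d", target_id, seq_len(n)),
                  stringsAsFactors = FALSE)
  for (j in seq_along(featureNames())) {
    cn <- featureNames()[j]
    f[[cn]] <- if (j == 1) -labels else runif(n)
  }
  if (!is.null(label_fun)) labels <- label_fun(f)
  newTargetPool(target_id, f, setNames(labels, f$model_id))
}
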