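# Observed secondary structure (Kabsch-Sander stand-in), Shrake-Rupley
# accessibility, and the external-prediction parsers.

rigidMove <- function(model, angle = 0.7) {
  R <- matrix(c(cos(angle), -sin(angle), 0,
                sin(angle), cos(angle), 0, 0, 0, 1), 3, byrow = TRUE)
  a <- model@atoms
  xyz <- as.matrix(a[, c("x", "y", "z")]) %*% t(R)
  a$x <- xyz[, 1] + 11.3; a$y <- xyz[, 2] - 4.2; a$z <- xyz[, 3] + 7.7
  new("ProteinModel", modelId = model@modelId, targetId = model@targetId,
      atoms = a)
}

singleResidueModel <- function(name = "CA", xyz = c(0, 0, 0), element = "C",
                               resno = 1, resname = "ALA") {
  atoms <- data.frame(residue = 1L, name = name, resname = resname,
                      chain = "A", resno = resno, insert = "",
                      x = xyz[1], y = xyz[2], z = xyz[3], element = element,
                      stringsAsFactors = FALSE)
  new("ProteinModel", modelId = "single", targetId = "t", atoms = atoms)
}

test_that("an ideal poly-helix is assigned helix over its core", {
  ref <- makeReference(decoyGeneratorParams(n_residues = 12,
                                            topology = "helix"))
  ss <- strsplit(assignSecondaryStructure(ref), "")[[1]]
  expect_length(ss, 12)
  expect_gte(sum(ss == "H"), 8)
  expect_true(all(ss[3:10] == "H"))
})

test_that("an extended chain with no H-bond partners is all coil", {
  n <- 10
  atoms <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(residue = i, name = c("N", "CA", "C", "O"),
               resname = "ALA", chain = "A", resno = i, insert = "",
               x = i * 3.8 + c(0, 1, 2, 2.2), y = c(0, 0.8, 0, -1),
               z = 0, element = c("N", "C", "C", "O"),
               stringsAsFactors = FALSE)
  }))
  m <- new("ProteinModel", modelId = "ext", targetId = "t", atoms = atoms)
  expect_equal(assignSecondaryStructure(m), strrep("C", n))
})

test_that("degenerate short models return all-coil with a warning", {
  at <- triPeptideAtoms()[1:8, ] # two residues
  m <- readPDB(writeTempPDB(pdbText(at)))
  expect_warning(ss <- assignSecondaryStructure(m), "backbone")
  expect_equal(ss, "CC")
})

test_that("secondary structure is invariant under rigid motion", {
  ref <- makeReference(decoyGeneratorParams(n_residues = 14,
                                            topology = "helix-loop-helix"))
  expect_identical(assignSecondaryStructure(ref),
                   assignSecondaryStructure(rigidMove(ref)))
})

test_that("a free carbon atom has the closed-form sphere area", {
  m <- singleResidueModel()
  expect_equal(computeASA(m), 4 * pi * (1.7 + 1.4)^2, tolerance = 1e-6)
})

test_that("an enclosed atom has zero accessible area", {
  # central CA surrounded by a dense shell of neighbours at 2 Angstrom
  k <- 80
  golden <- pi * (3 - sqrt(5))
  z <- 1 - 2 * (seq_len(k) - 0.5) / k
  r <- sqrt(1 - z^2)
  th <- golden * seq_len(k)
  shell <- 2 * cbind(r * cos(th), r * sin(th), z)
  atoms <- rbind(
    data.frame(residue = 1L, name = "CA", resname = "ALA", chain = "A",
               resno = 1L, insert = "", x = 0, y = 0, z = 0, element = "C",
               stringsAsFactors = FALSE),
    do.call(rbind, lapply(seq_len(k), function(i)
      data.frame(residue = i + 1L, name = "CA", resname = "ALA",
                 chain = "A", resno = i + 1L, insert = "",
                 x = shell[i, 1], y = shell[i, 2], z = shell[i, 3],
                 element = "C", stringsAsFactors = FALSE))))
  m <- new("ProteinModel", modelId = "shell", targetId = "t", atoms = atoms)
  expect_equal(computeASA(m)[1], 0)
})

test_that("identical residues far apart get identical per-residue ASA", {
  atoms <- do.call(rbind, lapply(c(0, 500), function(x0) {
    i <- if (x0 == 0) 1L else 2L
    data.frame(residue = i, name = c("N", "CA", "C", "O"),
               resname = "GLY", chain = "A", resno = i, insert = "",
               x = x0 + c(0, 1.46, 2.0, 2.4), y = c(0, 0.5, 1.9, 2.9),
               z = 0, element = c("N", "C", "C", "O"),
               stringsAsFactors = FALSE)
  }))
  m <- new("ProteinModel", modelId = "two", targetId = "t", atoms = atoms)
  asa <- computeASA(m)
  expect_equal(asa[1], asa[2], tolerance = 1e-9)
})

test_that("ASA is invariant under rigid motion of the model", {
  ref <- makeReference(decoyGeneratorParams(n_residues = 12,
                                            topology = "helix"))
  expect_equal(computeASA(ref), computeASA(rigidMove(ref)),
               tolerance = 1e-6)
})

test_that("ASA agrees with an independent Monte-Carlo oracle within 2%", {
  ref <- makeReference(decoyGeneratorParams(n_residues = 20,
                                            topology = "helix-loop-helix"))
  a <- ref@atoms
  radii <- c(C = 1.7, N = 1.55, O = 1.52)[a$element]
  oracle <- mcSASA(as.matrix(a[, c("x", "y", "z")]), radii,
                   n_points = 30000)
  oracle_res <- as.numeric(tapply(oracle, a$residue, sum))
  mine <- computeASA(ref, n_points = 3840L)
  expect_lt(max(abs(mine - oracle_res) / pmax(oracle_res, 1)), 0.02)
})

test_that("DSSP files parse with 3-state reduction and ACC values", {
  rows <- data.frame(aa = c("A", "G", "A"), ss = c("H", " ", "E"),
                     acc = c(120, 30, 60))
  lines <- c("==== Secondary Structure Definition ====",
             "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC",
             vapply(seq_len(nrow(rows)), function(i)
               paste0(sprintf("%5d%5d %s %s  %s", i, i, "A", rows$aa[i],
                              rows$ss[i]),
                      strrep(" ", 17), sprintf("%4d", rows$acc[i])),
               character(1)))
  path <- tempfile(fileext = ".dssp")
  writeLines(lines, path)
  out <- parseDSSPFile(path)
  expect_equal(out$states, "HCE")
  expect_equal(out$asa, c(120, 30, 60))
  # 8-state G reduces to H
  lines[3] <- sub(" A  H", " A  G", lines[3], fixed = TRUE)
  writeLines(lines, path)
  expect_equal(substr(parseDSSPFile(path)$states, 1, 1), "H")
  # truncated file: header never found
  writeLines(lines[1], path)
  expect_error(parseDSSPFile(path), "format")
})

test_that("DSSP sequence mismatches against a model are alignment errors", {
  m <- readPDB(writeTempPDB(pdbText(triPeptideAtoms())))
  lines <- c("  #  RESIDUE AA STRUCTURE BP1 BP2  ACC",
             vapply(1:3, function(i)
               paste0(sprintf("%5d%5d %s %s  %s", i, i, "A",
                              c("A", "A", "A")[i], "H"),
                      strrep(" ", 17), sprintf("%4d", 10)), character(1)))
  path <- tempfile(fileext = ".dssp")
  writeLines(lines, path)
  expect_error(parseDSSPFile(path, model = m), "alignment.*2")
})

test_that("PSIPRED-style predictions use the max class probability", {
  path <- tempfile(fileext = ".ss2")
  writeLines(c("# PSIPRED VFORMAT",
               "",
               "  1 A H   0.050  0.900  0.050",
               "  2 G C   0.600  0.200  0.200",
               "  3 A E   0.100  0.150  0.750"), path)
  out <- parseSSPrediction(path)
  expect_equal(out$states, "HCE")
  expect_equal(out$confidence, c(0.90, 0.60, 0.75))
})

test_that("generic 3-column predictions scale digit confidences by 9", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("A\tH\t9", "G\tC\t4", "A\tE\t0"), path)
  out <- parseSSPrediction(path)
  expect_equal(out$states, "HCE")
  expect_equal(out$confidence, c(1, 4 / 9, 0))
  writeLines(c("A\tB\t9"), path)
  expect_error(parseSSPrediction(path), "format.*B")
})

test_that("ASA predictions parse absolute and relative forms", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("1\t10.0", "2\t55.2"), path)
  expect_equal(parseASAPrediction(path), c(10.0, 55.2))
  writeLines(c("1\tA\t0.5", "2\tG\t0.25"), path)
  expect_equal(parseASAPrediction(path, relative = TRUE),
               c(0.5 * 129, 0.25 * 104))
  writeLines(c("1\t-3", "2\t5"), path)
  expect_warning(vals <- parseASAPrediction(path), "clamp")
  expect_equal(vals, c(0, 5))
})
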