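# Reading and writing PDB coordinate files into ProteinModel objects.
# Parsing is delegated to bio3d; this layer enforces the conventions the
# feature pipeline relies on: first MODEL only, first alternate location
# only, HETATM dropped, residues renumbered contiguously, CA required.

.AA3 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
          GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
          LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
          SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

#' Read a PDB file into a ProteinModel
#'
#' Keeps only the first MODEL block and the first alternate-location
#' indicator (blank or 'A'); HETATM records are dropped. Residues are
#' renumbered 1..N in file order across all chains (multi-chain files are
#' accepted with a warning); author numbering is retained as metadata.
#' Residues without a CA atom are dropped with a warning.
#'
#' @param path path to a PDB-format file.
#' @param model_id identifier for the model; defaults to the file name.
#' @param target_id identifier of the target the model belongs to.
#' @return a \code{\link{ProteinModel-class}} object.
#' @export
readPDB <- function(path, model_id = basename(path), target_id = "") {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE,
                                          rm.alt = TRUE, hex = FALSE,
                                          verbose = FALSE))
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L)
    stop("format error: no parsable ATOM records in ", path)
  insert <- ifelse(is.na(at$insert), "", at$insert)
  chain <- ifelse(is.na(at$chain), " ", at$chain)
  if (length(unique(chain)) > 1L)
    warning("multiple chains in ", model_id,
            "; concatenating in file order")
  elem <- at$elesy
  elem[is.na(elem) | elem == ""] <- substr(gsub("[0-9]", "",
                                                at$elety[is.na(elem) | elem == ""]),
                                           1, 1)
  key <- paste(chain, at$resno, insert, sep = "\r")
  residue <- match(key, unique(key))
  atoms <- data.frame(residue = residue, name = at$elety,
                      resname = at$resid, chain = chain, resno = at$resno,
                      insert = insert, x = at$x, y = at$y, z = at$z,
                      element = elem, stringsAsFactors = FALSE)
  .newProteinModel(atoms, model_id, target_id)
}

# shared constructor: drop CA-less residues, renumber, validate
.newProteinModel <- function(atoms, model_id, target_id) {
  has_ca <- tapply(atoms$name == "CA", atoms$residue, any)
  bad <- as.integer(names(has_ca)[!has_ca])
  if (length(bad)) {
    warning(sprintf("%s: dropped %d residue(s) without a CA atom",
                    model_id, length(bad)))
    atoms <- atoms[!atoms$residue %in% bad, , drop = FALSE]
  }
  if (nrow(atoms) == 0L)
    stop("format error: all residues lacked CA atoms in ", model_id)
  atoms$residue <- match(atoms$residue, unique(atoms$residue))
  rownames(atoms) <- NULL
  new("ProteinModel", modelId = model_id, targetId = target_id,
      atoms = atoms)
}

#' Write a ProteinModel to a PDB file
#'
#' Emits standard fixed-width ATOM records (first conformer only, as
#' stored). Round-tripping through \code{\link{readPDB}} reproduces
#' coordinates to the PDB precision of 1e-3 Angstrom.
#'
#' @param model a \code{ProteinModel}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writePDB <- function(model, path) {
  a <- model@atoms
  xyz <- as.numeric(t(as.matrix(a[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz, type = "ATOM",
                   resno = a$resno, resid = a$resname,
                   eleno = seq_len(nrow(a)), elety = a$name,
                   chain = ifelse(a$chain == " ", "", a$chain),
                   insert = ifelse(a$insert == "", NA, a$insert),
                   elesy = a$element)
  invisible(path)
}

#' One-letter amino-acid sequence of a model
#'
#' Nonstandard residues map to 'X' by default; selenomethionine (MSE) can
#' optionally map to 'M'.
#'
#' @param model a \code{ProteinModel}.
#' @param mse_as_met map MSE to 'M' instead of 'X' (default FALSE).
#' @return character string of length \code{nResidues(model)}.
#' @export
sequenceOf <- function(model, mse_as_met = FALSE) {
  a <- model@atoms
  res3 <- a$resname[!duplicated(a$residue)]
  one <- unname(.AA3[res3])
  one[is.na(one)] <- "X"
  if (mse_as_met) one[res3 == "MSE"] <- "M"
  paste(one, collapse = "")
}

# per-residue coordinate helpers used throughout the feature code
.atomCoords <- function(model, atom_name) {
  a <- model@atoms
  n <- nResidues(model)
  out <- matrix(NA_real_, n, 3)
  rows <- which(a$name == atom_name)
  rows <- rows[!duplicated(a$residue[rows])] # first matching atom per residue
  out[a$residue[rows], ] <- as.matrix(a[rows, c("x", "y", "z")])
  out
}

#' CA coordinates of a model
#' @param model a \code{ProteinModel}.
#' @return N x 3 matrix of CA coordinates (Angstrom).
#' @export
caCoords <- function(model) .atomCoords(model, "CA")
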