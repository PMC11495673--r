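# Structure I/O: read/write PDB files into an ordered residue representation.
#
# A `protein_structure` is an ordered list of residue records (chains
# concatenated in file order). Each residue record holds its atoms as
# parallel vectors plus an n x 3 coordinate matrix, which keeps the
# geometric feature code vectorized.

# three-letter -> one-letter amino acid codes
.AA321 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)
.AA123 <- stats::setNames(names(.AA321), unname(.AA321))

# default translation for modified residues recorded as HETATM
.DEFAULT_HET_MAP <- c(MSE = "M", SEP = "S", TPO = "T", PTR = "Y", HYP = "P")

#' Construct a residue record
#'
#' @param aa_code one-letter amino-acid code (unknown residues use `"X"`)
#' @param chain_id chain label
#' @param seq_index 0-based position in the concatenated chain order
#' @param atom_names character vector of atom labels (e.g. `"CA"`)
#' @param elements character vector of element symbols
#' @param xyz numeric matrix (n_atoms x 3) of coordinates in Angstrom
#' @param resno residue number in the source file (optional)
#' @param insert insertion code (optional)
#' @return a `residue_record` list
#' @export
residue_record <- function(aa_code, chain_id, seq_index, atom_names, elements,
                           xyz, resno = seq_index + 1L, insert = "") {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  .assert(nrow(xyz) >= 1, "residue must have at least one atom")
  .assert(all(is.finite(xyz)), "atom coordinates must be finite")
  .assert(length(atom_names) == nrow(xyz) && length(elements) == nrow(xyz),
          "atom name/element/coordinate lengths differ")
  is_h <- toupper(elements) %in% c("H", "D")
  structure(list(
    aa = aa_code, chain = chain_id, seq_index = as.integer(seq_index),
    resno = resno, insert = insert,
    atom_names = atom_names, elements = toupper(elements),
    xyz = xyz, is_hydrogen = is_h,
    has_backbone = all(c("N", "CA", "C") %in% atom_names)
  ), class = "residue_record")
}

#' Construct a protein structure from residue records
#'
#' @param residues list of [residue_record()] objects in chain/file order
#' @param source_id identifier string
#' @return a `protein_structure`
#' @export
protein_structure <- function(residues, source_id = "protein") {
  .assert(length(residues) >= 1, "structure must contain at least one residue")
  for (i in seq_along(residues)) residues[[i]]$seq_index <- i - 1L
  structure(list(residues = residues, source_id = source_id),
            class = "protein_structure")
}

#' @export
length.protein_structure <- function(x) length(x$residues)

#' @export
print.protein_structure <- function(x, ...) {
  chains <- unique(vapply(x$residues, function(r) r$chain, ""))
  cat(sprintf("<protein_structure> %s: %d residues, chain(s) %s\n",
              x$source_id, length(x$residues), paste(chains, collapse = ",")))
  invisible(x)
}

# derive an element symbol from a PDB atom name when the element column is
# blank (strip digits/primes; leading digit means 1H-style hydrogen naming)
.element_from_name <- function(name) {
  nm <- gsub("[^A-Za-z]", "", name)
  if (nchar(nm) == 0) return("X")
  first <- substr(nm, 1, 1)
  if (grepl("^[0-9]", name) || first == "H") return("H")
  # two-letter elements occurring in protein files
  two <- toupper(substr(nm, 1, 2))
  if (two %in% c("FE", "ZN", "MG", "MN", "SE", "CL", "BR", "NA", "CA")) {
    # atom name "CA" is alpha carbon, not calcium, in ATOM records
    if (two == "CA") return("C")
    return(two)
  }
  toupper(first)
}

#' Read a protein structure from a PDB file
#'
#' Parses ATOM records (and HETATM records for modified residues present in
#' `het_map`) into one residue per (chain, residue number, insertion code)
#' triple, preserving file order. Only the first MODEL of multi-model files
#' is used. Alternate-location atoms are resolved to the highest occupancy,
#' ties going to the first encountered.
#'
#' @param path path to a PDB file
#' @param chain_filter optional character vector of chain labels to keep
#' @param het_map named character vector mapping modified-residue three-letter
#'   codes to one-letter codes; other HETATM residues are dropped
#' @return a [protein_structure()]
#' @export
read_pdb <- function(path, chain_filter = NULL, het_map = .DEFAULT_HET_MAP) {
  .assert(file.exists(path), sprintf("PDB file not found: %s", path))
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop(sprintf("cannot parse PDB file %s: %s",
                                     path, conditionMessage(e)), call. = FALSE)
  )
  at <- pdb$atom
  keep <- at$type == "ATOM" | (at$type == "HETATM" & at$resid %in% names(het_map))
  at <- at[keep, , drop = FALSE]
  if (nrow(at) == 0)
    stop(sprintf("no ATOM records in %s", path), call. = FALSE)
  if (!is.null(chain_filter)) {
    at <- at[at$chain %in% chain_filter, , drop = FALSE]
    if (nrow(at) == 0)
      stop(sprintf("chain filter {%s} matches no residues in %s",
                   paste(chain_filter, collapse = ","), path), call. = FALSE)
  }
  ins <- at$insert
  ins[is.na(ins)] <- ""
  res_key <- paste(at$chain, at$resno, ins, sep = "|")
  res_levels <- unique(res_key) # file order
  occ <- at$o
  occ[is.na(occ)] <- 1

  residues <- vector("list", length(res_levels))
  for (ri in seq_along(res_levels)) {
    rows <- which(res_key == res_levels[ri])
    sub <- at[rows, , drop = FALSE]
    # altloc: per atom name keep highest occupancy, ties -> first encountered
    if (any(!is.na(sub$alt) & sub$alt != "")) {
      pick <- integer(0)
      for (nm in unique(sub$elety)) {
        idx <- which(sub$elety == nm)
        pick <- c(pick, idx[which.max(occ[rows][idx])])
      }
      sub <- sub[sort(pick), , drop = FALSE]
    }
    elem <- sub$elesy
    blank <- is.na(elem) | elem == ""
    if (any(blank))
      elem[blank] <- vapply(sub$elety[blank], .element_from_name, "")
    resid3 <- sub$resid[1]
    aa <- if (resid3 %in% names(.AA321)) .AA321[[resid3]]
          else if (resid3 %in% names(het_map)) het_map[[resid3]]
          else "X"
    residues[[ri]] <- residue_record(
      aa_code = aa, chain_id = sub$chain[1], seq_index = ri - 1L,
      atom_names = sub$elety, elements = elem,
      xyz = cbind(sub$x, sub$y, sub$z),
      resno = sub$resno[1], insert = ins[rows[1]]
    )
  }
  protein_structure(residues,
                    source_id = sub("\\.pdb$", "", basename(path)))
}

#' Extract the one-letter amino-acid sequence of a structure
#'
#' Non-standard residues appear as `"X"`.
#'
#' @param structure a [protein_structure()]
#' @return character scalar of length `length(structure)`
#' @export
extract_sequence <- function(structure) {
  .assert(inherits(structure, "protein_structure"), "not a protein_structure")
  paste(vapply(structure$residues, function(r) r$aa, ""), collapse = "")
}

#' Write a protein structure to a PDB file
#'
#' The emitted file round-trips through [read_pdb()]: residue counts, atom
#' names, chain labels and amino-acid codes are preserved, coordinates to
#' the PDB fixed-width precision of 1e-3 Angstrom.
#'
#' @param structure a [protein_structure()]
#' @param path output file path
#' @export
write_pdb <- function(structure, path) {
  .assert(inherits(structure, "protein_structure") &&
            length(structure$residues) >= 1,
          "write_pdb needs a non-empty protein_structure")
  res <- structure$residues
  natom <- vapply(res, function(r) nrow(r$xyz), 0L)
  xyz <- do.call(rbind, lapply(res, function(r) r$xyz))
  resid3 <- vapply(res, function(r) {
    if (r$aa %in% names(.AA123)) .AA123[[r$aa]] else "UNK"
  }, "")
  ok <- tryCatch({
    bio3d::write.pdb(
      file = path,
      xyz = as.numeric(t(xyz)),
      type = rep("ATOM", sum(natom)),
      resno = rep(vapply(res, function(r) as.integer(r$resno), 0L), natom),
      resid = rep(resid3, natom),
      chain = rep(vapply(res, function(r) r$chain, ""), natom),
      elety = unlist(lapply(res, function(r) r$atom_names)),
      eleno = seq_len(sum(natom)),
      o = rep(1, sum(natom)), b = rep(0, sum(natom)),
      elesy = unlist(lapply(res, function(r) r$elements))
    )
    TRUE
  }, error = function(e) stop(sprintf("cannot write PDB to %s: %s", path,
                                      conditionMessage(e)), call. = FALSE))
  invisible(path)
}
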