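# Molecule layer: molecules are ChemmineR "SDF" objects (V2000 atom/bond
# blocks, hydrogens implicit). Element symbols live in the atom-block
# rownames ("C_1", "N_2", ...). All SMILES parsing/writing and format
# conversion is delegated to OpenBabel through ChemmineOB; the functions
# here only assemble, edit and inspect the connection table.

# Atom-block numeric columns as produced by ChemmineR's SDF parser
# (coordinates C1-C3, then V2000 flag columns; the element occupies the
# rowname slot, hence no C4).
.pf_atom_cols <- c("C1", "C2", "C3", paste0("C", 5:16))
.pf_bond_cols <- paste0("C", 1:7)

#' @noRd
pf_is_mol <- function(x) methods::is(x, "SDF")

# Format conversion without coordinate regeneration (ChemmineOB's
# default options silently re-layout molecules in 2D).
#' @noRd
pf_convert <- function(from, to, text) {
  ChemmineOB::convertFormat(from, to, text,
                            options = data.frame(names = character(0),
                                                 args = character(0)))
}

# Accept SDF, pur_monomer or pur_oligomer wherever a molecule is expected
#' @noRd
as_mol <- function(x) {
  if (pf_is_mol(x)) return(x)
  if (inherits(x, "pur_monomer") || inherits(x, "pur_oligomer")) return(x$mol)
  stop("not a molecule: expected an SDF, pur_monomer or pur_oligomer object",
       call. = FALSE)
}

#' @noRd
pf_elements <- function(mol) sub("_.*", "", rownames(ChemmineR::atomblock(mol)))

#' @noRd
pf_natoms <- function(mol) nrow(ChemmineR::atomblock(mol))

# Bond table as a plain data.frame (a1, a2, order)
#' @noRd
pf_bonds <- function(mol) {
  bb <- ChemmineR::bondblock(mol)
  if (is.null(bb) || nrow(bb) == 0)
    return(data.frame(a1 = integer(0), a2 = integer(0), order = integer(0)))
  data.frame(a1 = as.integer(bb[, "C1"]), a2 = as.integer(bb[, "C2"]),
             order = as.integer(bb[, "C3"]))
}

# Assemble an SDF object from raw atom/bond blocks, renumbering rownames
#' @noRd
pf_new_sdf <- function(ab, bb, name) {
  elems <- sub("_.*", "", rownames(ab))
  rownames(ab) <- paste0(elems, "_", seq_len(nrow(ab)))
  if (nrow(bb) > 0) rownames(bb) <- as.character(seq_len(nrow(bb)))
  header <- c(Molecule_Name = name, Source = "  purfrag", Comment = "",
              Counts_Line = sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                                    nrow(ab), nrow(bb)))
  methods::new("SDF", header = header, atomblock = ab, bondblock = bb,
               datablock = character(0))
}

#' @noRd
pf_set_name <- function(mol, name) {
  h <- ChemmineR::header(mol)
  h["Molecule_Name"] <- name
  methods::new("SDF", header = h, atomblock = ChemmineR::atomblock(mol),
               bondblock = ChemmineR::bondblock(mol),
               datablock = ChemmineR::datablock(mol))
}

#' @noRd
pf_name <- function(mol) unname(ChemmineR::header(mol)["Molecule_Name"])

# Single-molecule MOL (V2000) text, without the SDF "$$$$" terminator.
# Fixed-width fields are emitted explicitly so whole-number coordinates
# keep their %10.4f layout (required by strict MDL readers).
#' @noRd
pf_mol_text <- function(mol) {
  ab <- ChemmineR::atomblock(mol)
  bb <- ChemmineR::bondblock(mol)
  el <- sub("_.*", "", rownames(ab))
  lines <- c(
    pf_name(mol), " purfrag", "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", nrow(ab),
            if (is.null(bb)) 0L else nrow(bb)),
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            ab[, "C1"], ab[, "C2"], ab[, "C3"], el))
  if (!is.null(bb) && nrow(bb) > 0)
    lines <- c(lines, sprintf("%3d%3d%3d  0  0  0  0",
                              as.integer(bb[, "C1"]),
                              as.integer(bb[, "C2"]),
                              as.integer(bb[, "C3"])))
  paste(c(lines, "M  END"), collapse = "\n")
}

# Multi-record SDF text for a list of molecules
#' @noRd
pf_sdf_text <- function(mols) {
  if (pf_is_mol(mols)) mols <- list(mols)
  paste0(paste(vapply(mols, function(m)
    paste0(pf_mol_text(m), "\n$$$$"), character(1)), collapse = "\n"), "\n")
}

#' @noRd
pf_as_sdfset <- function(mols, ids = NULL) {
  if (pf_is_mol(mols)) mols <- list(mols)
  mols <- lapply(mols, as_mol)
  if (is.null(ids)) ids <- vapply(mols, pf_name, character(1))
  ids <- make.unique(ids)
  methods::new("SDFset", SDF = mols, ID = ids)
}

#' Parse SMILES strings into molecular graphs
#'
#' Thin wrapper around OpenBabel's SMILES reader. Hydrogens stay
#' implicit; aromatic rings come back kekulized in the bond block, with
#' aromaticity re-perceived by OpenBabel whenever needed downstream.
#'
#' @param smiles character vector of SMILES strings.
#' @param names names for the molecules (defaults to the SMILES).
#' @return a list of `SDF` molecule objects.
#' @export
mol_from_smiles <- function(smiles, names = NULL) {
  stopifnot(is.character(smiles), length(smiles) >= 1)
  if (is.null(names)) names <- smiles
  sdfset <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(smiles, names))),
    error = function(e) stop("SMILES parse error for input(s) '",
                             paste(smiles, collapse = "', '"), "': ",
                             conditionMessage(e), call. = FALSE))
  mols <- lapply(seq_along(smiles), function(i) sdfset[[i]])
  bad <- !suppressWarnings(ChemmineR::validSDF(sdfset)) |
    vapply(mols, function(m) pf_natoms(m) == 0, logical(1))
  if (any(bad))
    stop("SMILES parse error: no atoms for input(s) '",
         paste(smiles[bad], collapse = "', '"), "'", call. = FALSE)
  names(mols) <- names
  mols
}

#' Write molecules as canonical SMILES
#'
#' @param mols a molecule or list of molecules.
#' @return named character vector of canonical SMILES (OpenBabel).
#' @export
mol_to_smiles <- function(mols) {
  if (!is.list(mols)) mols <- list(mols)
  mols <- lapply(mols, as_mol)
  out <- pf_convert("SDF", "CAN", pf_sdf_text(mols))
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  if (length(lines) != length(mols))
    stop("SMILES conversion dropped molecules (", length(lines), "/",
         length(mols), " converted)", call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  smis <- vapply(parts, `[`, character(1), 1)
  stats::setNames(trimws(smis), vapply(mols, pf_name, character(1)))
}

# OpenBabel property block (MW, TPSA, formula, ...) for a list of molecules
#' @noRd
pf_props_ob <- function(mols) {
  ChemmineR::propOB(pf_as_sdfset(mols))
}

#' Molecular weight (average atomic masses, implicit hydrogens included)
#'
#' @param mols a molecule or list of molecules.
#' @return numeric vector of molecular weights in u.
#' @export
mol_mw <- function(mols) {
  if (!is.list(mols)) mols <- list(mols)
  mols <- lapply(mols, as_mol)
  p <- pf_props_ob(mols)
  stats::setNames(p$MW, vapply(mols, pf_name, character(1)))
}

# Count unique SMARTS matches per molecule (OpenBabel matcher)
#' @noRd
pf_smarts_count <- function(mols, pattern) {
  if (!is.list(mols)) mols <- list(mols)
  res <- ChemmineR::smartsSearchOB(pf_as_sdfset(lapply(mols, as_mol)),
                                   pattern, uniqueMatches = TRUE)
  as.integer(res)
}

# Per-atom aromatic flags and per-bond aromatic flags, from OpenBabel's
# SYBYL MOL2 typing (".ar" atom types / "ar" bond type). Atom and bond
# order are preserved by the conversion. Returns a list with one element
# per molecule: list(atoms = logical, bonds = logical).
#' @noRd
pf_aromatic_info <- function(mols) {
  if (pf_is_mol(mols)) mols <- list(mols)
  mols <- lapply(mols, as_mol)
  txt <- pf_convert("SDF", "MOL2", pf_sdf_text(mols))
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  starts <- grep("^@<TRIPOS>MOLECULE", lines)
  if (length(starts) != length(mols))
    stop("MOL2 conversion returned ", length(starts), " records for ",
         length(mols), " molecules", call. = FALSE)
  ends <- c(starts[-1] - 1L, length(lines))
  lapply(seq_along(starts), function(i) {
    blk <- lines[starts[i]:ends[i]]
    a0 <- grep("^@<TRIPOS>ATOM", blk)[1]
    b0 <- grep("^@<TRIPOS>BOND", blk)[1]
    sec_end <- grep("^@<TRIPOS>", blk)
    a_end <- min(sec_end[sec_end > a0] - 1L, length(blk))
    b_next <- sec_end[sec_end > b0]
    b_end <- if (length(b_next)) min(b_next) - 1L else length(blk)
    atom_lines <- blk[(a0 + 1L):a_end]
    atom_lines <- atom_lines[nzchar(trimws(atom_lines))]
    types <- vapply(strsplit(trimws(atom_lines), "[[:space:]]+"),
                    `[`, character(1), 6)
    bonds <- data.frame(a1 = integer(0), a2 = integer(0), ar = logical(0))
    if (!is.na(b0) && b0 + 1L <= b_end) {
      bond_lines <- blk[(b0 + 1L):b_end]
      bond_lines <- bond_lines[nzchar(trimws(bond_lines))]
      fl <- strsplit(trimws(bond_lines), "[[:space:]]+")
      bonds <- data.frame(
        a1 = as.integer(vapply(fl, `[`, character(1), 2)),
        a2 = as.integer(vapply(fl, `[`, character(1), 3)),
        ar = vapply(fl, `[`, character(1), 4) == "ar")
    }
    list(atoms = grepl("\\.ar$", types), bonds = bonds)
  })
}

# Implicit hydrogen count per atom from standard valences; kekulized bond
# orders make this exact for neutral organic molecules.
#' @noRd
pf_implicit_h <- function(mol) {
  el <- pf_elements(mol)
  bonds <- pf_bonds(mol)
  val <- c(C = 4, N = 3, O = 2, S = 2, P = 3, F = 1, Cl = 1, Br = 1, I = 1,
           B = 3, Si = 4)
  deg <- numeric(length(el))
  if (nrow(bonds) > 0) {
    for (k in seq_len(nrow(bonds))) {
      deg[bonds$a1[k]] <- deg[bonds$a1[k]] + bonds$order[k]
      deg[bonds$a2[k]] <- deg[bonds$a2[k]] + bonds$order[k]
    }
  }
  v <- val[el]
  v[is.na(v)] <- 0
  pmax(0L, as.integer(v - deg))
}

# Drop atoms from a connection table, remapping bond indices
#' @noRd
pf_delete_atoms <- function(ab, bb, drop) {
  if (length(drop) == 0) return(list(ab = ab, bb = bb))
  keep <- setdiff(seq_len(nrow(ab)), drop)
  map <- integer(nrow(ab))
  map[keep] <- seq_along(keep)
  ab2 <- ab[keep, , drop = FALSE]
  if (nrow(bb) > 0) {
    ok <- !(bb[, "C1"] %in% drop) & !(bb[, "C2"] %in% drop)
    bb2 <- bb[ok, , drop = FALSE]
    if (nrow(bb2) > 0) {
      bb2[, "C1"] <- map[bb2[, "C1"]]
      bb2[, "C2"] <- map[bb2[, "C2"]]
    }
  } else bb2 <- bb
  list(ab = ab2, bb = bb2)
}

# Locate the bond row joining atoms i and j (either order); NA if absent
#' @noRd
pf_find_bond <- function(bb, i, j) {
  hit <- which((bb[, "C1"] == i & bb[, "C2"] == j) |
               (bb[, "C1"] == j & bb[, "C2"] == i))
  if (length(hit) == 0) NA_integer_ else hit[1]
}

#' Test two molecules for graph isomorphism
#'
#' Compares OpenBabel canonical SMILES, i.e. identity of the molecular
#' graph under the package's fixed aromaticity model.
#'
#' @param a,b molecules.
#' @return logical.
#' @export
mol_identical <- function(a, b) {
  s <- unname(mol_to_smiles(list(as_mol(a), as_mol(b))))
  s[1] == s[2]
}
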