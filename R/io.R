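# Structure-file output (MOL/MOL2/SDF/SMILES via OpenBabel conversion)
# and docked-pose input (MOL2/SDF via OpenBabel; PDBQT via a minimal
# coordinate-and-element reader, since the pose analysis needs geometry,
# not docking metadata).

#' Write library structure files
#'
#' Writes one structure file per oligomer (`<id>.mol`, `<id>.mol2`,
#' `<id>.sdf`) and/or a single SMILES list `library.smi`.
#'
#' @param x a `pur_library`, list of oligomers, or list of molecules.
#' @param dir output directory (created if missing).
#' @param formats subset of `c("mol", "mol2", "sdf", "smi")`.
#' @return data.frame manifest with columns `id`, `format`, `path`.
#' @export
write_structures <- function(x, dir, formats = c("mol", "mol2")) {
  if (inherits(x, "pur_library")) x <- x$oligomers
  if (!is.list(x)) x <- list(x)
  mols <- lapply(x, as_mol)
  ids <- vapply(mols, pf_name, character(1))
  bad <- setdiff(formats, c("mol", "mol2", "sdf", "smi"))
  if (length(bad))
    stop("unsupported format tag(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (!dir.exists(dir))
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create directory ", dir, call. = FALSE)
  manifest <- data.frame(id = character(0), format = character(0),
                         path = character(0))
  add <- function(id, format, path)
    manifest <<- rbind(manifest, data.frame(id = id, format = format,
                                            path = path))
  if ("mol" %in% formats) {
    for (i in seq_along(mols)) {
      p <- file.path(dir, paste0(ids[i], ".mol"))
      writeLines(pf_mol_text(mols[[i]]), p)
      add(ids[i], "mol", p)
    }
  }
  if ("sdf" %in% formats) {
    for (i in seq_along(mols)) {
      p <- file.path(dir, paste0(ids[i], ".sdf"))
      writeLines(pf_sdf_text(mols[[i]]), p)
      add(ids[i], "sdf", p)
    }
  }
  if ("mol2" %in% formats) {
    # one batch conversion, then split on molecule records
    txt <- pf_convert("SDF", "MOL2", pf_sdf_text(mols))
    lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
    starts <- grep("^@<TRIPOS>MOLECULE", lines)
    if (length(starts) != length(mols))
      stop("MOL2 conversion produced ", length(starts), " records for ",
           length(mols), " molecules", call. = FALSE)
    ends <- c(starts[-1] - 1L, length(lines))
    for (i in seq_along(mols)) {
      p <- file.path(dir, paste0(ids[i], ".mol2"))
      writeLines(lines[starts[i]:ends[i]], p)
      add(ids[i], "mol2", p)
    }
  }
  if ("smi" %in% formats) {
    p <- file.path(dir, "library.smi")
    smis <- mol_to_smiles(mols)
    writeLines(paste(unname(smis), ids, sep = "\t"), p)
    add("library", "smi", p)
  }
  rownames(manifest) <- NULL
  manifest
}

#' Read a structure file back into molecule objects
#'
#' MOL/SDF are read directly; MOL2 is converted through OpenBabel.
#'
#' @param path file path (`.mol`, `.sdf` or `.mol2`).
#' @return list of `SDF` molecule objects.
#' @export
read_structures <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("mol", "sdf")) {
    txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
    if (ext == "mol") txt <- paste0(txt, "\n$$$$")
    sdfset <- ChemmineR::read.SDFstr(textConnection(txt))
    sdfset <- methods::as(sdfset, "SDFset")
  } else if (ext == "mol2") {
    txt <- paste(c(readLines(path, warn = FALSE), ""), collapse = "\n")
    sdftxt <- pf_convert("MOL2", "SDF", txt)
    sdfset <- ChemmineR::read.SDFstr(textConnection(sdftxt))
    sdfset <- methods::as(sdfset, "SDFset")
  } else stop("unsupported structure format: .", ext, call. = FALSE)
  n <- length(ChemmineR::sdfid(sdfset))
  lapply(seq_len(n), function(i) sdfset[[i]])
}

# AutoDock atom types -> elements (coordinate-only PDBQT reading)
.pf_adt_elements <- c(A = "C", C = "C", N = "N", "NA" = "N", OA = "O",
                      O = "O", HD = "H", H = "H", HS = "H", SA = "S",
                      S = "S", P = "P", F = "F", CL = "Cl", BR = "Br",
                      I = "I", MG = "Mg", ZN = "Zn", MN = "Mn", FE = "Fe")

#' Read docked ligand poses
#'
#' Supports multi-MODEL PDBQT (AutoDock Vina output; coordinates and
#' elements only), multi-record MOL2 and SDF. One pose per MODEL block /
#' molecule record.
#'
#' @param path pose file.
#' @param id ligand identifier to attach to the poses (default: file
#'   base name).
#' @return list of `ligand_pose` objects: `id`, `pose` (index),
#'   `atoms` (data.frame elem/x/y/z) and `bonds` (data.frame a1/a2/order,
#'   `NULL` for PDBQT which has no bond orders).
#' @export
read_poses <- function(path, id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(id)) id <- tools::file_path_sans_ext(basename(path))
  ext <- tolower(tools::file_ext(path))
  if (ext == "pdbqt") return(pf_read_pdbqt(path, id))
  mols <- read_structures(path)
  lapply(seq_along(mols), function(i) {
    ab <- ChemmineR::atomblock(mols[[i]])
    structure(list(id = id, pose = i,
                   atoms = data.frame(elem = sub("_.*", "", rownames(ab)),
                                      x = ab[, "C1"], y = ab[, "C2"],
                                      z = ab[, "C3"], row.names = NULL),
                   bonds = pf_bonds(mols[[i]])),
              class = "ligand_pose")
  })
}

#' @noRd
pf_read_pdbqt <- function(path, id) {
  lines <- readLines(path, warn = FALSE)
  model_starts <- grep("^MODEL", lines)
  blocks <- if (length(model_starts) == 0) {
    list(seq_along(lines))
  } else {
    ends <- c(model_starts[-1] - 1L, length(lines))
    lapply(seq_along(model_starts), function(i) model_starts[i]:ends[i])
  }
  poses <- vector("list", length(blocks))
  for (b in seq_along(blocks)) {
    idx <- blocks[[b]]
    rec <- idx[grepl("^(ATOM|HETATM)", lines[idx])]
    if (length(rec) == 0)
      stop("malformed PDBQT: no ATOM/HETATM records in pose block ", b,
           " of ", path, call. = FALSE)
    n <- length(rec)
    elem <- character(n); x <- numeric(n); y <- numeric(n); z <- numeric(n)
    for (k in seq_len(n)) {
      ln <- lines[rec[k]]
      if (nchar(ln) < 54)
        stop("malformed PDBQT record at line ", rec[k], " of ", path,
             call. = FALSE)
      x[k] <- suppressWarnings(as.numeric(substr(ln, 31, 38)))
      y[k] <- suppressWarnings(as.numeric(substr(ln, 39, 46)))
      z[k] <- suppressWarnings(as.numeric(substr(ln, 47, 54)))
      if (anyNA(c(x[k], y[k], z[k])))
        stop("malformed PDBQT coordinates at line ", rec[k], " of ", path,
             call. = FALSE)
      # AutoDock atom type sits in the last column
      adt <- toupper(trimws(substr(ln, 78, nchar(ln))))
      if (!nzchar(adt)) adt <- toupper(substr(trimws(substr(ln, 13, 16)), 1, 1))
      el <- .pf_adt_elements[adt]
      if (is.na(el)) el <- paste0(substr(adt, 1, 1),
                                  tolower(substr(adt, 2, 2)))
      elem[k] <- el
    }
    poses[[b]] <- structure(
      list(id = id, pose = b,
           atoms = data.frame(elem = elem, x = x, y = y, z = z),
           bonds = NULL),
      class = "ligand_pose")
  }
  poses
}

#' @export
print.ligand_pose <- function(x, ...) {
  cat(sprintf("<ligand_pose> %s #%d: %d atoms%s\n", x$id, x$pose,
              nrow(x$atoms),
              if (is.null(x$bonds)) " (no bond orders)" else ""))
  invisible(x)
}
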