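# Conformer generation: systematic torsion driving (Confab, via the
# OpenBabel CLI) over an initial rule-built 3D structure, keeping
# conformers within an energy window of the best one found and pairwise
# RMSD-diverse. The search is systematic and the 3D builder rule-based,
# so results are deterministic without a random seed. Molecules with
# more rotatable bonds than `rotor_limit` fall back to the single
# embedded, force-field-optimized conformer (the torsion grid would be
# combinatorially intractable), mirroring the intended "as few as one"
# behaviour for large fragments.

#' @noRd
pf_obabel <- function() {
  ob <- Sys.which("obabel")
  if (!nzchar(ob))
    stop("OpenBabel 'obabel' executable not found on PATH; conformer ",
         "generation requires it", call. = FALSE)
  ob
}

#' Generate diverse conformers for a molecule
#'
#' @param mol molecule (or monomer/oligomer).
#' @param max_n maximum number of conformers to return (default 20).
#' @param rmsd_cutoff minimum pairwise heavy-atom RMSD between kept
#'   conformers, in Angstrom (default 0.5).
#' @param energy_window maximum energy above the lowest-energy conformer,
#'   kcal/mol (default 50).
#' @param rotor_limit rotatable-bond count above which the systematic
#'   search is skipped in favour of a single embedded conformer.
#' @return a `conformer_set`: list with `id`, `mol` (input graph),
#'   `conformers` (list of natoms x 3 coordinate matrices, Angstrom),
#'   `energies` (MMFF94, kcal/mol; `NA` if unavailable) and `method`.
#' @examples
#' \dontrun{
#' cs <- generate_conformers(mol_from_smiles("c1ccccc1")[[1]])
#' length(cs$conformers)  # 1: benzene has no rotors
#' }
#' @export
generate_conformers <- function(mol, max_n = 20L, rmsd_cutoff = 0.5,
                                energy_window = 50, rotor_limit = 15L) {
  mol <- as_mol(mol)
  stopifnot(max_n >= 1, rmsd_cutoff >= 0, energy_window > 0)
  ob <- pf_obabel()
  id <- pf_name(mol)
  rot <- pf_smarts_count(mol, .pf_pat$rot_generic) -
    pf_smarts_count(mol, .pf_pat$rot_amide)
  tmp <- tempfile("conf")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE), add = TRUE)
  in_sdf <- file.path(tmp, "in.sdf")
  sdf3d <- file.path(tmp, "embed.sdf")
  out_sdf <- file.path(tmp, "out.sdf")
  writeLines(pf_sdf_text(mol), in_sdf)
  # rule-based 3D embedding + force-field cleanup
  st <- system2(ob, c(in_sdf, "-O", shQuote(sdf3d), "--gen3d"),
                stdout = FALSE, stderr = FALSE)
  if (st != 0 || !file.exists(sdf3d) || file.size(sdf3d) == 0)
    stop("3D embedding failed for molecule '", id, "'", call. = FALSE)
  method <- "confab"
  if (rot > rotor_limit) {
    file.copy(sdf3d, out_sdf)
    method <- "single-embed"
  } else {
    st <- system2(ob, c(sdf3d, "-O", shQuote(out_sdf), "--confab",
                        "--conf", max_n, "--rcutoff", rmsd_cutoff,
                        "--ecutoff", energy_window, "--original"),
                  stdout = FALSE, stderr = FALSE)
    if (st != 0 || !file.exists(out_sdf) || file.size(out_sdf) == 0) {
      # fall back to the embedded conformer rather than failing outright
      file.copy(sdf3d, out_sdf)
      method <- "single-embed"
    }
  }
  confs <- ChemmineR::read.SDFset(out_sdf)
  n_heavy <- pf_natoms(mol)
  # gen3d adds explicit hydrogens after the heavy atoms; keep the heavy
  # coordinates in the parent graph's atom order
  coords <- lapply(seq_along(ChemmineR::sdfid(confs)), function(i) {
    ab <- ChemmineR::atomblock(confs[[i]])
    heavy <- sub("_.*", "", rownames(ab)) != "H"
    m <- ab[heavy, c("C1", "C2", "C3"), drop = FALSE]
    if (nrow(m) != n_heavy)
      stop("conformer atom count mismatch for molecule '", id, "'",
           call. = FALSE)
    colnames(m) <- c("x", "y", "z")
    rownames(m) <- NULL
    m
  })
  if (length(coords) > max_n) coords <- coords[seq_len(max_n)]
  energies <- pf_mmff_energies(out_sdf, length(coords))
  structure(list(id = id, mol = mol, conformers = coords,
                 energies = energies, method = method,
                 rmsd_cutoff = rmsd_cutoff, energy_window = energy_window),
            class = "conformer_set")
}

# MMFF94 single-point energies via obenergy; NA when unavailable
#' @noRd
pf_mmff_energies <- function(sdf_path, n) {
  obe <- Sys.which("obenergy")
  if (!nzchar(obe)) return(rep(NA_real_, n))
  out <- suppressWarnings(system2(obe, c("-ff", "MMFF94", shQuote(sdf_path)),
                                  stdout = TRUE, stderr = FALSE))
  hits <- grep("TOTAL ENERGY", out, value = TRUE)
  vals <- suppressWarnings(as.numeric(sub(".*=\\s*([-0-9.eE+]+).*", "\\1",
                                          hits)))
  if (length(vals) < n) vals <- c(vals, rep(NA_real_, n - length(vals)))
  vals[seq_len(n)]
}

#' @export
print.conformer_set <- function(x, ...) {
  cat(sprintf("<conformer_set> %s: %d conformer(s) [%s]\n",
              x$id, length(x$conformers), x$method))
  invisible(x)
}

#' @export
length.conformer_set <- function(x) length(x$conformers)

#' Write a conformer set as a multi-record SDF
#'
#' @param cs a `conformer_set`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_conformers <- function(cs, path) {
  stopifnot(inherits(cs, "conformer_set"))
  mols <- lapply(seq_along(cs$conformers), function(i) {
    ab <- ChemmineR::atomblock(cs$mol)
    ab[, c("C1", "C2", "C3")] <- cs$conformers[[i]]
    pf_new_sdf(ab, ChemmineR::bondblock(cs$mol),
               sprintf("%s_conf%02d", cs$id, i))
  })
  writeLines(pf_sdf_text(mols), path)
  invisible(path)
}
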