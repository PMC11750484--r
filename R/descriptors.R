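# Per-compound property profile. MW and Ertl TPSA come from OpenBabel;
# cLogP and molar refraction use the package's Wildman-Crippen
# implementation (crippen.R); counts use the SMARTS vocabulary in
# patterns.R under OpenBabel's aromaticity model.

#' Compute the property profile of molecules
#'
#' Returns, per molecule: molecular weight (u), heavy-atom count,
#' rotatable-bond count (non-ring single bonds between non-terminal
#' heavy atoms, excluding amide/carbamate C-N bonds), presence of ester
#' and ether bonds (urethane motifs excluded from both), aromatic-atom
#' count, aromatic proportion (aromatic / heavy atoms), Wildman-Crippen
#' cLogP and molar refraction (cm3/mol), and Ertl topological polar
#' surface area (A2).
#'
#' @param mols a molecule, a list of molecules, or a `pur_library`.
#' @return data.frame with one row per molecule.
#' @examples
#' \dontrun{
#' compute_properties(mol_from_smiles("CNC(=O)OC"))
#' }
#' @export
compute_properties <- function(mols) {
  if (inherits(mols, "pur_library")) mols <- lapply(mols$oligomers, `[[`, "mol")
  if (!is.list(mols)) mols <- list(mols)
  mols <- lapply(mols, as_mol)
  if (length(mols) == 0) {
    return(data.frame(id = character(0), mw = numeric(0),
                      heavy_atoms = integer(0), rotatable_bonds = integer(0),
                      has_ester = logical(0), has_ether = logical(0),
                      aromatic_atoms = integer(0),
                      aromatic_proportion = numeric(0), clogp = numeric(0),
                      mr = numeric(0), tpsa = numeric(0)))
  }
  p <- pf_props_ob(mols)
  arom <- pf_aromatic_info(mols)
  cw <- vapply(seq_along(mols), function(i)
    wildman_crippen(mols[[i]], aromatic = arom[[i]]), numeric(2))
  heavy <- vapply(mols, pf_natoms, integer(1))
  n_arom <- vapply(arom, function(a) sum(a$atoms), integer(1))
  rot <- pf_smarts_count(mols, .pf_pat$rot_generic) -
    pf_smarts_count(mols, .pf_pat$rot_amide)
  data.frame(
    id = vapply(mols, pf_name, character(1)),
    mw = p$MW,
    heavy_atoms = heavy,
    rotatable_bonds = pmax(0L, rot),
    has_ester = pf_smarts_count(mols, .pf_pat$ester) > 0,
    has_ether = pf_smarts_count(mols, .pf_pat$ether) > 0,
    aromatic_atoms = n_arom,
    aromatic_proportion = ifelse(heavy > 0, n_arom / heavy, 0),
    clogp = unname(cw[1, ]),
    mr = unname(cw[2, ]),
    tpsa = p$TPSA,
    row.names = NULL)
}

#' Number of six-membered aromatic carbocycles per molecule
#'
#' @param mols a molecule or list of molecules.
#' @return integer vector.
#' @export
aromatic_ring_count <- function(mols) {
  pf_smarts_count(mols, .pf_pat$benzenoid)
}

#' Property table for a fragment library
#'
#' One row per oligomer, prefixed with provenance columns
#' (`id,smiles,units,isocyanate,alcohol`) followed by the property
#' profile; serializable as the `library.csv` output.
#'
#' @param library a `pur_library` (or list of `pur_oligomer`s).
#' @return data.frame.
#' @export
property_table <- function(library) {
  olis <- if (inherits(library, "pur_library")) library$oligomers else library
  if (length(olis) == 0) {
    props <- compute_properties(list())
    return(cbind(data.frame(id = character(0), smiles = character(0),
                            units = integer(0), isocyanate = character(0),
                            alcohol = character(0)),
                 props[, setdiff(names(props), "id"), drop = FALSE]))
  }
  mols <- lapply(olis, `[[`, "mol")
  props <- compute_properties(mols)
  meta <- data.frame(
    id = vapply(olis, `[[`, character(1), "id"),
    smiles = unname(mol_to_smiles(mols)),
    units = vapply(olis, `[[`, integer(1), "n_units"),
    isocyanate = vapply(olis, `[[`, character(1), "iso_id"),
    alcohol = vapply(olis, `[[`, character(1), "ol_id"),
    row.names = NULL)
  cbind(meta, props[, setdiff(names(props), "id"), drop = FALSE])
}
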