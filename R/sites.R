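# Reactive-group detection on the connection table. These definitions
# drive both monomer validation and chain assembly:
#   isocyanate site: N=C=O, i.e. a carbon with exactly two double bonds,
#     one to nitrogen and one to oxygen.
#   hydroxyl site: an oxygen with a single bond to one sp3 carbon and an
#     implicit hydrogen. Hydroxyls on carbonyl carbons (carboxylic or
#     carbamic acids) and on unsaturated/aromatic carbons (enols,
#     phenols) are not reactive alcohol sites, so a carbamate cap's
#     -C(=O)OH can never re-enter the chain chemistry.

#' Locate isocyanate (N=C=O) sites
#'
#' @param mol a molecule (or monomer/oligomer).
#' @return integer matrix with one row per site and columns `n`, `c`,
#'   `o` (atom indices), ordered by nitrogen atom index.
#' @export
find_isocyanate_sites <- function(mol) {
  mol <- as_mol(mol)
  el <- pf_elements(mol)
  bonds <- pf_bonds(mol)
  out <- matrix(integer(0), ncol = 3, dimnames = list(NULL, c("n", "c", "o")))
  for (ci in which(el == "C")) {
    rows <- which(bonds$a1 == ci | bonds$a2 == ci)
    if (length(rows) != 2 || !all(bonds$order[rows] == 2)) next
    partners <- ifelse(bonds$a1[rows] == ci, bonds$a2[rows], bonds$a1[rows])
    pel <- el[partners]
    if (setequal(pel, c("N", "O"))) {
      ni <- partners[pel == "N"]
      oi <- partners[pel == "O"]
      out <- rbind(out, c(ni, ci, oi))
    }
  }
  out[order(out[, "n"]), , drop = FALSE]
}

#' Locate hydroxyl (C-OH) sites
#'
#' @param mol a molecule (or monomer/oligomer).
#' @return integer matrix with one row per site and columns `o` (the
#'   hydroxyl oxygen) and `c` (its carbon), ordered by oxygen index.
#' @export
find_hydroxyl_sites <- function(mol) {
  mol <- as_mol(mol)
  el <- pf_elements(mol)
  bonds <- pf_bonds(mol)
  out <- matrix(integer(0), ncol = 2, dimnames = list(NULL, c("o", "c")))
  for (oi in which(el == "O")) {
    rows <- which(bonds$a1 == oi | bonds$a2 == oi)
    if (length(rows) != 1 || bonds$order[rows] != 1) next
    ci <- if (bonds$a1[rows] == oi) bonds$a2[rows] else bonds$a1[rows]
    if (el[ci] != "C") next
    crows <- which(bonds$a1 == ci | bonds$a2 == ci)
    if (any(bonds$order[crows] > 1)) next  # carbonyl/enol/aromatic carbon
    out <- rbind(out, c(oi, ci))
  }
  out[order(out[, "o"]), , drop = FALSE]
}

#' Functional-group profile of a molecule
#'
#' @param mol a molecule.
#' @return list with elements `isocyanate_sites` (n/c/o index matrix)
#'   and `hydroxyl_sites` (o/c index matrix).
#' @export
functional_groups <- function(mol) {
  list(isocyanate_sites = find_isocyanate_sites(mol),
       hydroxyl_sites = find_hydroxyl_sites(mol))
}
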