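# Urethane-bond chemistry on the connection table. The coupling is the
# formal addition of an alcohol O-H across an isocyanate N=C=O:
#
#   R-N=C=O  +  HO-R'  ->  R-NH-C(=O)-O-R'
#
# In the implicit-hydrogen graph this is two edits: the N=C double bond
# becomes single (N picks up one implicit H) and a new O-C single bond is
# created (the hydroxyl O loses its implicit H). No atoms are added or
# removed, so mass is conserved by construction.

#' Couple an isocyanate site to a hydroxyl site, forming a urethane bond
#'
#' @param iso molecule (or monomer) providing the isocyanate group.
#' @param iso_site which isocyanate site to react (1-based, sites ordered
#'   by atom index; the default reacts the lowest-index site).
#' @param ol molecule (or monomer) providing the hydroxyl group.
#' @param ol_site which hydroxyl site to react.
#' @param name name for the product molecule.
#' @return the product molecule (`SDF`). Atoms of `iso` keep their
#'   indices; atoms of `ol` follow, offset by the size of `iso`.
#' @examples
#' \dontrun{
#' mics <- mol_from_smiles(c("CN=C=O", "CO"))
#' mol_to_smiles(couple_urethane(mics[[1]], 1, mics[[2]], 1))
#' }
#' @export
couple_urethane <- function(iso, iso_site = 1L, ol, ol_site = 1L,
                            name = "product") {
  iso <- as_mol(iso); ol <- as_mol(ol)
  isoS <- find_isocyanate_sites(iso)
  olS <- find_hydroxyl_sites(ol)
  if (iso_site < 1 || iso_site > nrow(isoS))
    stop("isocyanate site index ", iso_site, " out of range (molecule has ",
         nrow(isoS), " free N=C=O site(s))", call. = FALSE)
  if (ol_site < 1 || ol_site > nrow(olS))
    stop("hydroxyl site index ", ol_site, " out of range (molecule has ",
         nrow(olS), " free C-OH site(s))", call. = FALSE)
  abI <- ChemmineR::atomblock(iso); bbI <- ChemmineR::bondblock(iso)
  abO <- ChemmineR::atomblock(ol);  bbO <- ChemmineR::bondblock(ol)
  n <- nrow(abI)
  site <- isoS[iso_site, ]
  o_ol <- olS[ol_site, "o"] + n
  # N=C -> N-C
  k <- pf_find_bond(bbI, site[["n"]], site[["c"]])
  bbI[k, "C3"] <- 1
  if (nrow(bbO) > 0) {
    bbO[, "C1"] <- bbO[, "C1"] + n
    bbO[, "C2"] <- bbO[, "C2"] + n
  }
  newbond <- matrix(c(site[["c"]], o_ol, 1, rep(0, length(.pf_bond_cols) - 3)),
                    nrow = 1, dimnames = list(NULL, colnames(bbI)))
  bb <- rbind(bbI, bbO, newbond)
  ab <- rbind(abI, abO)
  pf_new_sdf(ab, bb, name)
}

# Per-site molecular-weight change of each cap (u):
#   amine     R-N=C=O -> R-NH2        : lose CO, gain 2 H  = -25.99
#   methyl    R-N=C=O -> R-CH3        : NCO -> CH3         = -26.98
#   carbamate R-N=C=O -> R-NH-C(=O)OH : formal water add   = +18.02
.pf_caps <- c("amine", "methyl", "carbamate")

#' Cap residual isocyanate groups
#'
#' Replaces every remaining N=C=O group with a neutral end group. A
#' molecule without free isocyanate sites passes through unchanged, so
#' the operation is idempotent.
#'
#' @param mol molecule (or monomer/oligomer).
#' @param cap one of `"amine"` (-NH2), `"methyl"` (-CH3) or
#'   `"carbamate"` (-NH-C(=O)OH).
#' @param name optional new molecule name (default: keep).
#' @return the capped molecule.
#' @export
cap_isocyanates <- function(mol, cap = c("amine", "methyl", "carbamate"),
                            name = NULL) {
  cap <- match.arg(cap)
  mol <- as_mol(mol)
  sites <- find_isocyanate_sites(mol)
  if (is.null(name)) name <- pf_name(mol)
  if (nrow(sites) == 0) return(pf_set_name(mol, name))
  ab <- ChemmineR::atomblock(mol)
  bb <- ChemmineR::bondblock(mol)
  drop <- integer(0)
  for (s in seq_len(nrow(sites))) {
    ni <- sites[s, "n"]; ci <- sites[s, "c"]; oi <- sites[s, "o"]
    if (cap == "amine") {
      drop <- c(drop, ci, oi)
    } else if (cap == "methyl") {
      drop <- c(drop, ci, oi)
      rownames(ab)[ni] <- sub("^N", "C", rownames(ab)[ni])
    } else { # carbamate: N=C -> N-C, add hydroxyl O on the carbonyl C
      k <- pf_find_bond(bb, ni, ci)
      bb[k, "C3"] <- 1
      newatom <- matrix(0, nrow = 1, ncol = ncol(ab),
                        dimnames = list("O_new", colnames(ab)))
      ab <- rbind(ab, newatom)
      newbond <- matrix(c(ci, nrow(ab), 1, rep(0, ncol(bb) - 3)),
                        nrow = 1, dimnames = list(NULL, colnames(bb)))
      bb <- rbind(bb, newbond)
    }
  }
  res <- pf_delete_atoms(ab, bb, drop)
  pf_new_sdf(res$ab, res$bb, name)
}

#' Molecular-weight change per capped site
#'
#' @param cap cap tag.
#' @return the per-site MW delta in u.
#' @export
cap_mw_delta <- function(cap = c("amine", "methyl", "carbamate")) {
  cap <- match.arg(cap)
  # average atomic masses: C 12.011, N 14.007, O 15.999, H 1.008
  switch(cap,
         amine     = -(12.011 + 15.999) + 2 * 1.008,            # -25.99
         methyl    = -(14.007 + 12.011 + 15.999) + 12.011 + 3 * 1.008, # -26.98
         carbamate = 15.999 + 2 * 1.008)                         # +18.02
}
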