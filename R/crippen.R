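# Wildman-Crippen atom-contribution model for cLogP and molar
# refraction (MR). Each heavy atom is assigned one of the published
# atom classes from its element, aromaticity, hydrogen count and
# neighbourhood; implicit hydrogens contribute through the H classes,
# typed by the heavy atom that carries them. The class definitions are
# evaluated in the published first-match order. Neutral organic
# molecules (C/H/N/O plus halogens, S, P) are fully covered; formal
# charges are out of scope for this package's chemistry.

# class -> c(logP, MR)
.cw_params <- list(
  C1 = c(0.1441, 2.503),   C2 = c(0, 2.433),       C3 = c(-0.2035, 2.753),
  C4 = c(-0.2051, 2.731),  C5 = c(-0.2783, 5.007), C6 = c(0.1551, 3.513),
  C7 = c(0.0017, 3.888),   C8 = c(0.08452, 2.464), C9 = c(-0.1444, 2.412),
  C10 = c(-0.0516, 2.488), C11 = c(0.1193, 2.582), C12 = c(-0.0967, 2.576),
  C13 = c(-0.5443, 4.041), C14 = c(0, 3.257),      C15 = c(0.245, 3.564),
  C16 = c(0.198, 3.18),    C17 = c(0, 3.104),      C18 = c(0.1581, 3.35),
  C19 = c(0.2955, 4.346),  C20 = c(0.2713, 3.904), C21 = c(0.136, 3.509),
  C22 = c(0.4619, 4.067),  C23 = c(0.5437, 3.853), C24 = c(0.1893, 2.673),
  C25 = c(-0.8186, 3.135), C26 = c(0.264, 4.305),  C27 = c(0.2148, 2.693),
  CS = c(0.08129, 3.243),
  H1 = c(0.123, 1.057),    H2 = c(-0.2677, 1.395), H3 = c(0.2142, 0.9627),
  H4 = c(0.298, 1.805),    HS = c(0.1125, 1.112),
  N1 = c(-1.019, 2.262),   N2 = c(-0.7096, 2.173), N3 = c(-1.027, 2.827),
  N4 = c(-0.5188, 3),      N5 = c(0.08387, 1.757), N6 = c(0.1836, 2.428),
  N7 = c(-0.3187, 1.839),  N8 = c(-0.4458, 2.819), N9 = c(0.01508, 1.725),
  N11 = c(-0.3239, 2.202), NS = c(-0.4806, 2.134),
  O1 = c(0.1552, 1.08),    O2 = c(-0.2893, 0.8238), O3 = c(-0.0684, 1.085),
  O4 = c(-0.4195, 1.182),  O5 = c(0.0335, 3.367),   O8 = c(0.1788, 3.135),
  O9 = c(-0.1526, 0),      O10 = c(0.1129, 0.2215), O11 = c(0.4833, 0.389),
  OS = c(-0.1188, 0.6865),
  F = c(0.4202, 1.108),    Cl = c(0.6895, 5.853),  Br = c(0.8456, 8.927),
  I = c(0.8857, 14.02),    P = c(0.8612, 6.92),
  S1 = c(0.6482, 7.591),   S2 = c(-0.0024, 7.365), S3 = c(0.6237, 6.691),
  Me1 = c(-0.3808, 5.754)
)

.cw_het <- c("N", "O", "P", "S", "F", "Cl", "Br", "I")

#' Wildman-Crippen cLogP and molar refraction
#'
#' @param mol a molecule.
#' @param aromatic optional precomputed aromaticity info (one element of
#'   the internal batch perception); computed when `NULL`.
#' @return numeric vector `c(clogp, mr)`.
#' @export
wildman_crippen <- function(mol, aromatic = NULL) {
  mol <- as_mol(mol)
  if (is.null(aromatic)) aromatic <- pf_aromatic_info(mol)[[1]]
  el <- pf_elements(mol)
  n <- length(el)
  bonds <- pf_bonds(mol)
  ar <- aromatic$atoms
  if (length(ar) != n)
    stop("aromaticity info does not match molecule", call. = FALSE)
  # aromatic-bond lookup keyed on sorted atom pair
  arkey <- character(0)
  if (nrow(aromatic$bonds) > 0) {
    b <- aromatic$bonds[aromatic$bonds$ar, , drop = FALSE]
    arkey <- paste(pmin(b$a1, b$a2), pmax(b$a1, b$a2))
  }
  nH <- pf_implicit_h(mol)
  # neighbourhood tables
  nbrs <- vector("list", n); nord <- vector("list", n); nbar <- vector("list", n)
  if (nrow(bonds) > 0) {
    for (k in seq_len(nrow(bonds))) {
      i <- bonds$a1[k]; j <- bonds$a2[k]; o <- bonds$order[k]
      isar <- paste(min(i, j), max(i, j)) %in% arkey
      nbrs[[i]] <- c(nbrs[[i]], j); nord[[i]] <- c(nord[[i]], o)
      nbar[[i]] <- c(nbar[[i]], isar)
      nbrs[[j]] <- c(nbrs[[j]], i); nord[[j]] <- c(nord[[j]], o)
      nbar[[j]] <- c(nbar[[j]], isar)
    }
  }
  type_of <- vapply(seq_len(n), function(i)
    cw_atom_class(i, el, ar, nH, nbrs, nord, nbar, arkey), character(1))
  htype_of <- vapply(seq_len(n), function(i)
    if (nH[i] > 0) cw_h_class(i, el, ar, nH, nbrs, nord) else NA_character_,
    character(1))
  logp <- 0; mr <- 0
  for (i in seq_len(n)) {
    p <- .cw_params[[type_of[i]]]
    logp <- logp + p[1]; mr <- mr + p[2]
    if (!is.na(htype_of[i])) {
      ph <- .cw_params[[htype_of[i]]]
      logp <- logp + nH[i] * ph[1]; mr <- mr + nH[i] * ph[2]
    }
  }
  c(clogp = logp, mr = mr)
}

# class of one heavy atom (first-match cascade per published table)
#' @noRd
cw_atom_class <- function(i, el, ar, nHv, nbrs, nord, nbar, arkey) {
  e <- el[i]; nb <- nbrs[[i]]; no <- nord[[i]]
  nbel <- el[nb]; nba <- ar[nb]; nH <- nHv[i]
  bar <- if (length(nb)) nbar[[i]] else logical(0)
  if (e == "C") {
    if (!ar[i]) {
      has_dbl <- any(no == 2); has_trp <- any(no == 3)
      if (!has_dbl && !has_trp) { # sp3
        if (length(nb) == 0 || all(nbel == "C" & !nba))
          return(if (nH >= 2) "C1" else "C2")
        het_ali <- nbel %in% .cw_het & !nba
        if (any(het_ali)) {
          if (nH == 3) return("C3")
          if (nH == 2 && all(!nba)) return("C3")
          if (nH <= 1 && all(!nba)) return("C4")
        }
        if (any(nba)) {
          if (nH == 3) return(if (any(nbel == "C" & nba)) "C8" else "C9")
          if (nH == 2) return("C10")
          if (nH == 1) return("C11")
          return("C12")
        }
        if (any(!nba & !(nbel %in% c("C", .cw_het)))) return("C27")
        return("CS")
      }
      # sp2 / sp
      if (any(no == 2 & nbel != "C" & !nba)) return("C5")
      dblC_ali <- no == 2 & nbel == "C" & !nba
      if (any(dblC_ali)) {
        if (nH == 2) return("C6")
        if (sum(no == 2 & nbel == "C") == 2) return("C6") # allene
        oth <- setdiff(seq_along(nb), which(dblC_ali)[1])
        if (nH == 1 && all(!nba[oth])) return("C6")
        if (nH == 0 && length(oth) == 2 && all(!nba[oth])) return("C6")
      }
      if (any(no == 3 & !nba)) return("C7")
      if (any(no == 2 & nbel == "C" & nba)) return("C26") # [C]=c
      if (any(dblC_ali) && any(nba)) return("C26")
      return("CS")
    }
    # aromatic carbon
    nonar <- which(!bar)
    if (nH == 0 && length(nonar) &&
        any(!nba[nonar] & !(nbel[nonar] %in% c("C", "N", "O", "S",
                                               "F", "Cl", "Br", "I"))))
      return("C13")
    if (any(nbel == "F")) return("C14")
    if (any(nbel == "Cl")) return("C15")
    if (any(nbel == "Br")) return("C16")
    if (any(nbel == "I")) return("C17")
    if (nH >= 1) return("C18")
    if (sum(bar) >= 3) return("C19")
    if (length(nonar)) {
      s <- nonar
      if (any(nba[s])) return("C20")
      if (any(nbel[s] == "C" & !nba[s] & no[s] == 1)) return("C21")
      if (any(nbel[s] == "N" & !nba[s] & no[s] == 1)) return("C22")
      if (any(nbel[s] == "O" & !nba[s] & no[s] == 1)) return("C23")
      if (any(nbel[s] == "S" & !nba[s] & no[s] == 1)) return("C24")
      if (any(no[s] == 2 & nbel[s] %in% c("C", "N", "O"))) return("C25")
    }
    return("CS")
  }
  if (e == "N") {
    if (ar[i]) return("N11")
    if (any(no == 3)) return("N9")
    if (nH == 2) {
      if (length(nb) == 0) return("NS")
      return(if (!nba[1]) "N1" else "N3")
    }
    if (nH == 1) {
      if (any(no == 2)) return("N5")
      if (length(nb) == 2) return(if (all(!nba)) "N2" else "N4")
      return("NS")
    }
    if (any(no == 2) && length(nb) == 2) return("N6")
    if (length(nb) == 3 && all(no == 1))
      return(if (any(nba)) "N8" else "N7")
    return("NS")
  }
  if (e == "O") {
    if (ar[i]) return("O1")
    if (nH >= 1) return("O2")
    if (any(no == 2)) {
      p <- nb[no == 2][1]
      if (el[p] %in% c("N", "O")) return("O5")
      if (ar[p]) return("O8")
      if (el[p] == "C") {
        cn <- setdiff(nbrs[[p]], i)
        cel <- el[cn]; car <- ar[cn]; cH <- nHv[p]
        cord <- nord[[p]][match(cn, nbrs[[p]])]
        if (cH >= 1 && any(cel == "C" & !car)) return("O9")
        if (length(cn) == 2 && any(cel == "C" & !car) && all(!car)) return("O9")
        if (cH >= 1 && any(cel %in% c("N", "O"))) return("O9")
        if (cH == 2) return("O9")
        if (length(cn) == 1 && cel[1] == "O" && cord[1] == 2) return("O9") # CO2
        if (cH >= 1 && any(car)) return("O10")
        if (any(cel == "C") && any(car)) return("O10")
        if (length(cn) == 2 && all(cel != "C")) return("O11")
      }
      return("OS")
    }
    if (length(nb) == 2) return(if (all(!nba)) "O3" else "O4")
    return("OS")
  }
  if (e %in% c("F", "Cl", "Br", "I")) return(e)
  if (e == "P") return("P")
  if (e == "S") {
    if (ar[i]) return("S3")
    if (any(no == 2 & nbel %in% c("N", "O", "P", "S"))) return("S2")
    return("S1")
  }
  "Me1"
}

# H class, typed by the heavy atom carrying the implicit hydrogens
#' @noRd
cw_h_class <- function(i, el, ar, nHv, nbrs, nord) {
  e <- el[i]
  if (e == "C") return("H1")
  if (e == "N") return("H3")
  if (e == "O") {
    nb <- nbrs[[i]]
    if (length(nb) == 0) return("H2")
    x <- nb[1]
    if (el[x] == "N") return("H3")
    if (el[x] == "C") {
      if (ar[x]) return("H2")
      xo <- nord[[x]]; xn <- el[nbrs[[x]]]
      if (any(xo == 2 & xn %in% c("C", "N", "O", "S"))) return("H4")
      return("H2")
    }
    if (el[x] %in% c("O", "S")) return("H4")
    return("H2")
  }
  "H2"
}
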