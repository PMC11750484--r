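# Near-attack-configuration (NAC) classification of docked poses
# against a serine-hydrolase active site. A pose is productive when the
# catalytic serine oxygen sits within the threshold of the carbonyl
# carbon of the NEAREST cleavable bond (urethane or ester) AND both
# oxyanion-hole backbone NH probes sit within the threshold of that
# bond's carbonyl oxygen.

#' Read a receptor structure (PDB)
#'
#' @param path PDB file.
#' @return a `bio3d` `pdb` object.
#' @export
read_receptor <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  bio3d::read.pdb(path)
}

# "A:130:OG" -> list(chain, resno, atom); "A:60" -> list(chain, resno)
#' @noRd
pf_parse_locator <- function(s, need_atom = FALSE) {
  parts <- strsplit(s, ":", fixed = TRUE)[[1]]
  if (length(parts) < 2 || (need_atom && length(parts) < 3))
    stop("bad residue locator '", s, "' (expected CHAIN:RESNO[:ATOM])",
         call. = FALSE)
  list(chain = parts[1], resno = as.integer(parts[2]),
       atom = if (length(parts) >= 3) parts[3] else NA_character_)
}

#' Specify a serine-hydrolase active site
#'
#' @param serine locator of the catalytic serine side-chain oxygen,
#'   `"CHAIN:RESNO:ATOM"` (e.g. `"A:130:OG"`).
#' @param oxyanion character vector of exactly two oxyanion-hole residue
#'   locators, `"CHAIN:RESNO"`.
#' @param probe probe atom for the oxyanion NH groups: `"H"` (backbone
#'   amide hydrogen), `"N"` (backbone nitrogen) or `"auto"` (H when the
#'   receptor is protonated, else N).
#' @return an `active_site_spec`.
#' @export
active_site <- function(serine, oxyanion, probe = c("auto", "H", "N")) {
  probe <- match.arg(probe)
  if (length(oxyanion) != 2)
    stop("exactly two oxyanion residues are required", call. = FALSE)
  structure(list(serine = pf_parse_locator(serine, need_atom = TRUE),
                 oxyanion = lapply(oxyanion, pf_parse_locator),
                 probe = probe),
            class = "active_site_spec")
}

#' @export
print.active_site_spec <- function(x, ...) {
  cat(sprintf("<active_site_spec> Ser %s:%d:%s; oxyanion %s:%d, %s:%d; probe %s\n",
              x$serine$chain, x$serine$resno, x$serine$atom,
              x$oxyanion[[1]]$chain, x$oxyanion[[1]]$resno,
              x$oxyanion[[2]]$chain, x$oxyanion[[2]]$resno, x$probe))
  invisible(x)
}

# resolve one atom in the receptor; errors when absent or ambiguous
#' @noRd
pf_receptor_atom <- function(receptor, chain, resno, atom_name,
                             required = TRUE) {
  a <- receptor$atom
  hit <- which(a$chain == chain & a$resno == resno & a$elety == atom_name)
  if (length(hit) > 1)
    stop("ambiguous receptor atom ", chain, ":", resno, ":", atom_name,
         call. = FALSE)
  if (length(hit) == 0) {
    if (required)
      stop("unresolvable receptor atom ", chain, ":", resno, ":", atom_name,
           call. = FALSE)
    return(NULL)
  }
  c(a$x[hit], a$y[hit], a$z[hit])
}

# serine O + two oxyanion probe coordinates; returns list with probe used
#' @noRd
pf_resolve_site <- function(receptor, site) {
  ser <- pf_receptor_atom(receptor, site$serine$chain, site$serine$resno,
                          site$serine$atom)
  probe <- site$probe
  if (probe == "auto") {
    hs <- vapply(site$oxyanion, function(o)
      !is.null(pf_receptor_atom(receptor, o$chain, o$resno, "H",
                                required = FALSE)), logical(1))
    probe <- if (all(hs)) "H" else "N"
  }
  oxy <- lapply(site$oxyanion, function(o)
    pf_receptor_atom(receptor, o$chain, o$resno, probe))
  list(ser = ser, oxy1 = oxy[[1]], oxy2 = oxy[[2]], probe = probe)
}

#' Find cleavable (hydrolysable) bonds in a ligand graph
#'
#' Urethane: N-C(=O)-O-C. Ester: C-C(=O)-O-C with the carbonyl carbon
#' not bonded to nitrogen. Each motif is reported once, keyed by its
#' carbonyl atoms.
#'
#' @param mol a molecule, or a `ligand_pose` carrying bond orders.
#' @return data.frame with columns `kind`, `carbonyl_c`, `carbonyl_o`
#'   (atom indices); zero rows when none.
#' @export
find_cleavable_bonds <- function(mol) {
  if (inherits(mol, "ligand_pose")) {
    if (is.null(mol$bonds))
      stop("pose carries no bond orders; supply the ligand graph",
           call. = FALSE)
    el <- mol$atoms$elem
    bonds <- mol$bonds
  } else {
    mol <- as_mol(mol)
    el <- pf_elements(mol)
    bonds <- pf_bonds(mol)
  }
  out <- data.frame(kind = character(0), carbonyl_c = integer(0),
                    carbonyl_o = integer(0))
  for (ci in which(el == "C")) {
    rows <- which(bonds$a1 == ci | bonds$a2 == ci)
    partners <- ifelse(bonds$a1[rows] == ci, bonds$a2[rows], bonds$a1[rows])
    dbl_o <- partners[bonds$order[rows] == 2 & el[partners] == "O"]
    if (length(dbl_o) != 1) next
    sing <- partners[bonds$order[rows] == 1]
    has_n <- any(el[sing] == "N")
    has_c <- any(el[sing] == "C")
    # single-bonded O that continues to a carbon (the leaving-group O)
    ester_o <- FALSE
    for (oi in sing[el[sing] == "O"]) {
      orows <- which(bonds$a1 == oi | bonds$a2 == oi)
      opart <- ifelse(bonds$a1[orows] == oi, bonds$a2[orows], bonds$a1[orows])
      if (any(el[setdiff(opart, ci)] == "C")) ester_o <- TRUE
    }
    if (!ester_o) next
    if (has_n) {
      out <- rbind(out, data.frame(kind = "urethane", carbonyl_c = ci,
                                   carbonyl_o = dbl_o))
    } else if (has_c) {
      out <- rbind(out, data.frame(kind = "ester", carbonyl_c = ci,
                                   carbonyl_o = dbl_o))
    }
  }
  out
}

#' Classify one docked pose as productive or not
#'
#' Selects the cleavable bond whose carbonyl carbon is nearest to the
#' catalytic serine oxygen, measures the two oxyanion probe distances to
#' that bond's carbonyl oxygen, and applies the (inclusive) distance
#' threshold to all three.
#'
#' @param pose a `ligand_pose`.
#' @param receptor a `pdb` receptor (from [read_receptor()]).
#' @param site an `active_site_spec`.
#' @param threshold NAC distance threshold in Angstrom (default 4.5).
#' @param mol optional ligand graph supplying bond orders when the pose
#'   format has none (PDBQT); heavy-atom count and element sequence
#'   must match the pose.
#' @return one-row data.frame: `ligand`, `pose`, `bond_kind`, `d_ser`,
#'   `d_oxy1`, `d_oxy2`, `productive`, `probe`.
#' @export
classify_pose <- function(pose, receptor, site, threshold = 4.5,
                          mol = NULL) {
  stopifnot(inherits(pose, "ligand_pose"),
            inherits(site, "active_site_spec"))
  res <- pf_resolve_site(receptor, site)
  heavy <- pose$atoms[pose$atoms$elem != "H", , drop = FALSE]
  if (!is.null(mol)) {
    mol <- as_mol(mol)
    el <- pf_elements(mol)
    if (nrow(heavy) != length(el) || !all(heavy$elem == el))
      stop("ligand graph does not match pose '", pose$id,
           "' (heavy-atom sequence differs)", call. = FALSE)
    bonds_src <- mol
  } else bonds_src <- pose
  cb <- find_cleavable_bonds(bonds_src)
  base <- data.frame(ligand = pose$id, pose = pose$pose,
                     stringsAsFactors = FALSE)
  if (nrow(cb) == 0) {
    return(cbind(base, data.frame(bond_kind = "none", d_ser = NA_real_,
                                  d_oxy1 = NA_real_, d_oxy2 = NA_real_,
                                  productive = FALSE, probe = res$probe)))
  }
  xyz <- as.matrix(heavy[, c("x", "y", "z")])
  d_ser_all <- sqrt(colSums((t(xyz[cb$carbonyl_c, , drop = FALSE]) -
                             res$ser)^2))
  best <- which.min(d_ser_all)
  co <- xyz[cb$carbonyl_o[best], ]
  d1 <- sqrt(sum((co - res$oxy1)^2))
  d2 <- sqrt(sum((co - res$oxy2)^2))
  out <- cbind(base, data.frame(
    bond_kind = cb$kind[best],
    d_ser = d_ser_all[best], d_oxy1 = d1, d_oxy2 = d2,
    productive = max(d_ser_all[best], d1, d2) <= threshold,
    probe = res$probe))
  rownames(out) <- NULL
  out
}

#' Classify a batch of poses
#'
#' @param poses list of `ligand_pose` objects.
#' @param receptor receptor structure.
#' @param site `active_site_spec`.
#' @param threshold distance threshold (Angstrom).
#' @param mols optional named list of ligand graphs (by ligand id) for
#'   pose formats without bond orders.
#' @return data.frame with one row per pose.
#' @export
classify_poses <- function(poses, receptor, site, threshold = 4.5,
                           mols = NULL) {
  rows <- lapply(poses, function(p) {
    m <- if (!is.null(mols)) mols[[p$id]] else NULL
    classify_pose(p, receptor, site, threshold = threshold, mol = m)
  })
  do.call(rbind, rows)
}

#' Summarize pose classifications
#'
#' Aggregates a classification table into (a) the overall percentage of
#' productive poses, (b) productive percentages per isocyanate class,
#' (c) among productive poses of ligands that contain both urethane and
#' ester bonds, the percentage whose attacked bond is the urethane, and
#' (d) the serine-carbonyl distances for histogramming.
#'
#' @param classifications data.frame from [classify_poses()].
#' @param metadata optional data.frame with columns `id`,
#'   `isocyanate_class` and `has_ester` mapping ligand ids; required for
#'   the per-class and urethane-preference summaries.
#' @return a `pose_summary` list.
#' @export
summarize_poses <- function(classifications, metadata = NULL) {
  cl <- classifications
  stopifnot(is.data.frame(cl), nrow(cl) >= 1)
  out <- list(
    n_poses = nrow(cl),
    pct_productive = 100 * mean(cl$productive),
    pct_nonproductive = 100 * mean(!cl$productive),
    d_ser = cl$d_ser)
  if (!is.null(metadata)) {
    missing_ids <- setdiff(unique(cl$ligand), metadata$id)
    if (length(missing_ids))
      stop("ligand id(s) missing from metadata: ",
           paste(missing_ids, collapse = ", "), call. = FALSE)
    m <- match(cl$ligand, metadata$id)
    if ("isocyanate_class" %in% names(metadata)) {
      cls <- metadata$isocyanate_class[m]
      agg <- stats::aggregate(cl$productive, by = list(class = cls),
                              FUN = function(z) 100 * mean(z))
      names(agg)[2] <- "pct_productive"
      out$by_class <- agg
    }
    if ("has_ester" %in% names(metadata)) {
      both <- cl[metadata$has_ester[m] & cl$productive &
                 cl$bond_kind != "none", , drop = FALSE]
      out$n_productive_both <- nrow(both)
      out$pct_urethane_nac <- if (nrow(both) > 0)
        100 * mean(both$bond_kind == "urethane") else NA_real_
    }
  }
  structure(out, class = "pose_summary")
}

#' @export
print.pose_summary <- function(x, ...) {
  cat(sprintf("<pose_summary> %d poses: %.1f%% productive\n",
              x$n_poses, x$pct_productive))
  if (!is.null(x$by_class)) {
    for (i in seq_len(nrow(x$by_class)))
      cat(sprintf("  %-6s %.1f%%\n", x$by_class$class[i],
                  x$by_class$pct_productive[i]))
  }
  if (!is.null(x$pct_urethane_nac) && !is.na(x$pct_urethane_nac))
    cat(sprintf("  urethane NAC preference (both-bond ligands): %.1f%%\n",
                x$pct_urethane_nac))
  invisible(x)
}
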