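# Deterministic synthetic receptors, poses and monomer sets: every
# analysis path is testable without downloads or docking runs. The
# geometries are minimal, not physically realistic protein models.

#' Build a minimal receptor/pose pair realizing requested NAC distances
#'
#' Constructs a one-urethane ligand (methyl N-methylcarbamate) posed at
#' the origin, a catalytic serine whose side-chain OG lies exactly
#' `d_ser` from the carbonyl carbon, and two oxyanion residues whose
#' backbone amide H atoms lie exactly `d_oxy1` / `d_oxy2` from the
#' carbonyl oxygen (backbone N placed 1.01 A behind each H). Receptor
#' (PDB, standard SER/OG and backbone N/H naming) and pose (MOL2) are
#' also written to files so the real parsers are exercised.
#'
#' @param d_ser,d_oxy1,d_oxy2 requested distances in Angstrom
#'   (non-negative; values are realized exactly in memory and to 1e-3 A
#'   in the PDB/MOL2 files).
#' @param dir output directory for the fixture files.
#' @return list with `receptor` (bio3d `pdb`), `pose` (`ligand_pose`),
#'   `ligand` (molecule graph), `site` (`active_site_spec`), and file
#'   paths `receptor_file`, `pose_file`.
#' @export
make_site_fixture <- function(d_ser, d_oxy1, d_oxy2,
                              dir = tempfile("sitefix")) {
  d <- c(d_ser = d_ser, d_oxy1 = d_oxy1, d_oxy2 = d_oxy2)
  if (any(!is.finite(d)) || any(d < 0))
    stop("infeasible geometry: distances must be finite and >= 0",
         call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  # ligand: CNC(=O)OC with carbonyl C at the origin, carbonyl O on +y
  lig <- mol_from_smiles("CNC(=O)OC", "nac_probe")[[1]]
  # atom order from the SMILES: C1(methyl) N2 C3(carbonyl) O4(carbonyl)
  # O5(ester) C6(methyl)
  coords <- rbind(
    c(-2.40, -1.10, 0), # C1
    c(-1.20, -0.60, 0), # N2
    c( 0.00,  0.00, 0), # C3 carbonyl C
    c( 0.00,  1.23, 0), # O4 carbonyl O
    c( 1.20, -0.60, 0), # O5
    c( 2.40,  0.10, 0)) # C6
  ab <- ChemmineR::atomblock(lig)
  ab[, c("C1", "C2", "C3")] <- coords
  lig <- pf_new_sdf(ab, ChemmineR::bondblock(lig), "nac_probe")
  # receptor: serine OG below the carbonyl carbon (off-plane), oxyanion
  # amide H atoms flanking the carbonyl oxygen along +/- x
  og <- c(0, 0, -d_ser)
  h1 <- c(d_oxy1, 1.23, 0)
  h2 <- c(-d_oxy2, 1.23, 0)
  atoms <- data.frame(
    elety = c("N", "CA", "CB", "OG", "N", "H", "N", "H"),
    resid = c("SER", "SER", "SER", "SER", "TYR", "TYR", "MET", "MET"),
    chain = "A",
    resno = c(130, 130, 130, 130, 60, 60, 131, 131))
  xyz <- rbind(og + c(-2.0, -1.0, -1.5),
               og + c(-1.0, -0.5, -1.0),
               og + c(-0.8, 0.3, -0.5),
               og,
               h1 + c(0, 1.01, 0), h1,
               h2 + c(0, 1.01, 0), h2)
  receptor_file <- file.path(dir, "receptor.pdb")
  bio3d::write.pdb(file = receptor_file, xyz = as.numeric(t(xyz)),
                   resno = atoms$resno, chain = atoms$chain,
                   resid = atoms$resid, elety = atoms$elety,
                   o = rep(1, nrow(atoms)), b = rep(0, nrow(atoms)))
  pose_file <- file.path(dir, "pose.mol2")
  m2 <- pf_convert("SDF", "MOL2", pf_sdf_text(lig))
  writeLines(m2, pose_file)
  # in-memory receptor built from the exact geometry (the PDB file
  # rounds to 1e-3 A); same bio3d structure as read.pdb would return
  receptor <- bio3d::read.pdb(receptor_file)
  receptor$atom$x <- xyz[, 1]
  receptor$atom$y <- xyz[, 2]
  receptor$atom$z <- xyz[, 3]
  pose <- structure(
    list(id = "nac_probe", pose = 1L,
         atoms = data.frame(elem = pf_elements(lig), x = coords[, 1],
                            y = coords[, 2], z = coords[, 3]),
         bonds = pf_bonds(lig)),
    class = "ligand_pose")
  list(receptor = receptor, pose = pose, ligand = lig,
       site = active_site("A:130:OG", c("A:60", "A:131")),
       receptor_file = receptor_file, pose_file = pose_file)
}

# deterministic RNG scope (does not disturb the caller's RNG state)
#' @noRd
pf_with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Generate a random aliphatic monomer set with a fixed functionality split
#'
#' Builds simple linear/branched aliphatic isocyanates and alcohols with
#' exactly the requested numbers of mono- and difunctional members.
#' Reproducible per seed.
#'
#' @param n_iso,n_iso_di total / difunctional isocyanate counts.
#' @param n_ol,n_ol_di total / difunctional alcohol counts.
#' @param seed integer seed.
#' @return list with `isos` and `ols` (lists of `pur_monomer`).
#' @export
make_monomer_set <- function(n_iso, n_iso_di, n_ol, n_ol_di, seed = 1L) {
  stopifnot(n_iso >= 0, n_ol >= 0, n_iso_di <= n_iso, n_ol_di <= n_ol,
            n_iso_di >= 0, n_ol_di >= 0)
  pf_with_seed(seed, {
    chain <- function(k, branch) {
      s <- strrep("C", k)
      if (branch && k >= 2) sub("CC", "C(C)C", s) else s
    }
    mk <- function(n, n_di, smi_mono, smi_di, role, tag) {
      out <- vector("list", n)
      for (i in seq_len(n)) {
        di <- i <= n_di
        k <- sample(2:8, 1)
        br <- stats::runif(1) < 0.3
        smi <- if (di) smi_di(chain(k, br)) else smi_mono(chain(k, br))
        out[[i]] <- parse_monomer(smi, role, sprintf("%s_%d", tag, i))
      }
      out
    }
    isos <- mk(n_iso, n_iso_di,
               function(c) paste0("O=C=N", c),
               function(c) paste0("O=C=N", c, "N=C=O"),
               "isocyanate", "iso")
    ols <- mk(n_ol, n_ol_di,
              function(c) paste0("O", c),
              function(c) paste0("OC", c, "CO"),
              "alcohol", "ol")
    list(isos = isos, ols = ols)
  })
}
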