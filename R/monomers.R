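# Building blocks. A monomer is a validated SMILES with a role
# (isocyanate or alcohol) and a detected functionality; only mono- and
# difunctional monomers are admitted for library enumeration, matching
# the linear (non-crosslinking) chain chemistry.

#' Parse and validate a building block
#'
#' Detects the reactive groups for the declared role (N=C=O for
#' isocyanates, aliphatic C-OH for alcohols) and flags pre-existing
#' ester/ether bonds (used later to mark polyester-/polyether-derived
#' fragments).
#'
#' @param smiles SMILES string.
#' @param role `"isocyanate"` or `"alcohol"`.
#' @param id identifier (defaults to the SMILES).
#' @return a `pur_monomer` object: list with `id`, `smiles`, `role`,
#'   `functionality`, `has_ester`, `has_ether`, `mol`.
#' @examples
#' \dontrun{
#' parse_monomer("O=C=NCCCCCCN=C=O", "isocyanate", "HDI")$functionality  # 2
#' }
#' @export
parse_monomer <- function(smiles, role = c("isocyanate", "alcohol"),
                          id = smiles) {
  role <- match.arg(role)
  mol <- mol_from_smiles(smiles, id)[[1]]
  fg <- functional_groups(mol)
  n_iso <- nrow(fg$isocyanate_sites)
  n_oh <- nrow(fg$hydroxyl_sites)
  fun <- if (role == "isocyanate") n_iso else n_oh
  if (fun == 0)
    stop("validation error: '", id, "' (", smiles, ") declared as ", role,
         " but has no ", if (role == "isocyanate") "N=C=O" else "C-OH",
         " group", call. = FALSE)
  structure(list(id = id, smiles = smiles, role = role,
                 functionality = fun,
                 has_ester = pf_smarts_count(mol, .pf_pat$ester) > 0,
                 has_ether = pf_smarts_count(mol, .pf_pat$ether) > 0,
                 mol = mol),
            class = "pur_monomer")
}

#' @export
print.pur_monomer <- function(x, ...) {
  cat(sprintf("<pur_monomer> %s  [%s, functionality %d]%s%s\n  %s\n",
              x$id, x$role, x$functionality,
              if (x$has_ester) ", ester" else "",
              if (x$has_ether) ", ether" else "", x$smiles))
  invisible(x)
}

#' Read building blocks from a SMILES list file
#'
#' One record per line: `SMILES<TAB>id` (a single space also works; the
#' id is optional). Lines starting with `#` are skipped.
#'
#' @param path file path.
#' @param role monomer role for every record in the file.
#' @return list of `pur_monomer` objects.
#' @export
read_monomers <- function(path, role = c("isocyanate", "alcohol")) {
  role <- match.arg(role)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) stop("no records in ", path, call. = FALSE)
  parts <- strsplit(lines, "[\t ]+")
  lapply(parts, function(p)
    parse_monomer(p[1], role, if (length(p) > 1) p[2] else p[1]))
}

#' Default isocyanate set (10 structures)
#'
#' Industrially common isocyanates: methyl isocyanate (MIC) and benzyl
#' isocyanate (BIC) are monofunctional; the MDI isomers (4,4'-, 2,4'-,
#' 2,2'-), TDI isomers (2,4-, 2,6-), HDI, IPDI and HMDI are
#' difunctional.
#'
#' @return list of `pur_monomer` objects.
#' @export
default_isocyanates <- function() {
  pf_cached("default_isocyanates", read_monomers(
    system.file("extdata", "isocyanates.smi", package = "purfrag",
                mustWork = TRUE), "isocyanate"))
}

#' Default alcohol set (16 structures, 9 mono- and 7 difunctional)
#'
#' All-aliphatic alcohols and diols emulating commercial polyol
#' chemistry, including polyether-like (ether-containing) and
#' polyester-like (ester-containing) members. This set is the package's
#' own composition satisfying the documented functionality split; see
#' the methods vignette.
#'
#' @return list of `pur_monomer` objects.
#' @export
default_alcohols <- function() {
  pf_cached("default_alcohols", read_monomers(
    system.file("extdata", "alcohols.smi", package = "purfrag",
                mustWork = TRUE), "alcohol"))
}

# simple package-level memo cache
.pf_cache <- new.env(parent = emptyenv())
pf_cached <- function(key, value) {
  if (!exists(key, envir = .pf_cache)) assign(key, value, envir = .pf_cache)
  get(key, envir = .pf_cache)
}
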