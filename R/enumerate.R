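# Combinatorial chain assembly. Chain lengths are counted in comonomer
# units; the admissible topologies follow from functionality:
#   IA    (2 units): any isocyanate x any alcohol, one urethane bond.
#   IAI   (3 units): diol in the middle, two copies of one isocyanate.
#   AIA   (3 units): diisocyanate in the middle, two alcohol copies.
#   IAIA  (4 units): alternating chain; both monomers difunctional.
# Exactly one product is generated per (isocyanate, alcohol, topology):
# reaction sites are consumed deterministically in lowest-atom-index
# order, so asymmetric diisocyanates (2,4-TDI, 2,4'-MDI) contribute a
# single regioisomer. Residual N=C=O groups are capped afterwards;
# residual hydroxyls are left as-is.

.pf_topologies <- data.frame(
  topology = c("IA", "IAI", "AIA", "IAIA"),
  n_units = c(2L, 3L, 3L, 4L),
  urethane_bonds = c(1L, 2L, 2L, 3L),
  stringsAsFactors = FALSE)

#' Closed-form library size
#'
#' Twin of [enumerate_library()] used as a counting oracle: for each
#' requested length, the number of admissible (isocyanate, alcohol,
#' topology) combinations.
#'
#' @param n_iso,n_ol total numbers of isocyanates / alcohols.
#' @param n_iso_di,n_ol_di how many of them are difunctional.
#' @param lengths subset of `c(2, 3, 4)`.
#' @return integer count.
#' @examples
#' count_expected(10, 8, 16, 7)  # 414
#' @export
count_expected <- function(n_iso, n_iso_di, n_ol, n_ol_di,
                           lengths = c(2, 3, 4)) {
  stopifnot(length(lengths) >= 1, all(lengths %in% 2:4))
  counts <- c(n_iso, n_iso_di, n_ol, n_ol_di)
  if (any(counts < 0)) stop("negative monomer counts", call. = FALSE)
  if (n_iso_di > n_iso || n_ol_di > n_ol)
    stop("difunctional counts exceed totals", call. = FALSE)
  total <- 0L
  if (2 %in% lengths) total <- total + n_iso * n_ol
  if (3 %in% lengths) total <- total + n_iso * n_ol_di + n_iso_di * n_ol
  if (4 %in% lengths) total <- total + n_iso_di * n_ol_di
  as.integer(total)
}

# assemble one oligomer for a given topology (uncapped)
#' @noRd
pf_assemble <- function(iso, ol, topology, name) {
  m <- switch(topology,
    IA = couple_urethane(iso, 1L, ol, 1L, name = name),
    IAI = {
      m1 <- couple_urethane(iso, 1L, ol, 1L)
      couple_urethane(iso, 1L, m1, 1L, name = name)
    },
    AIA = {
      m1 <- couple_urethane(iso, 1L, ol, 1L)
      couple_urethane(m1, 1L, ol, 1L, name = name)
    },
    IAIA = {
      m1 <- couple_urethane(iso, 1L, ol, 1L)
      m2 <- couple_urethane(iso, 1L, m1, 1L)
      couple_urethane(m2, 1L, ol, 1L, name = name)
    },
    stop("unknown topology: ", topology, call. = FALSE))
  m
}

#' Enumerate a polyurethane fragment library
#'
#' Systematically combines every isocyanate with every alcohol under
#' all admissible chain topologies for the requested lengths, forming
#' urethane bonds explicitly and capping residual isocyanate groups.
#' Output order and fragment ids are deterministic for a given input
#' order: within each length class fragments are numbered sequentially
#' over (isocyanate order, alcohol order, topology IAI-before-AIA).
#'
#' @param isos list of isocyanate `pur_monomer`s.
#' @param ols list of alcohol `pur_monomer`s.
#' @param lengths chain lengths to generate, subset of `c(2, 3, 4)`.
#' @param cap capping group for residual N=C=O: `"amine"`, `"methyl"`,
#'   `"carbamate"` or `"none"`.
#' @return a `pur_library`: list with `oligomers` (list of
#'   `pur_oligomer`) and `table` (provenance data.frame).
#' @examples
#' \dontrun{
#' lib <- enumerate_library(default_isocyanates(), default_alcohols())
#' length(lib)  # 414
#' }
#' @export
enumerate_library <- function(isos, ols, lengths = c(2, 3, 4),
                              cap = c("amine", "methyl", "carbamate",
                                      "none")) {
  cap <- match.arg(cap)
  if (inherits(isos, "pur_monomer")) isos <- list(isos)
  if (inherits(ols, "pur_monomer")) ols <- list(ols)
  if (length(isos) == 0) stop("validation error: empty isocyanate list",
                              call. = FALSE)
  if (length(ols) == 0) stop("validation error: empty alcohol list",
                             call. = FALSE)
  stopifnot(all(vapply(isos, inherits, logical(1), "pur_monomer")),
            all(vapply(ols, inherits, logical(1), "pur_monomer")))
  if (any(vapply(c(isos, ols), `[[`, integer(1), "functionality") > 2))
    stop("validation error: monomers with more than two functional groups ",
         "are excluded from enumeration", call. = FALSE)
  lengths <- sort(unique(as.integer(lengths)))
  stopifnot(length(lengths) >= 1, all(lengths %in% 2:4))
  prefix <- c(`2` = "dimer", `3` = "trimer", `4` = "tetramer")
  oligomers <- list()
  for (len in lengths) {
    counter <- 0L
    for (iso in isos) {
      for (ol in ols) {
        topos <- .pf_topologies[.pf_topologies$n_units == len, "topology"]
        for (tp in topos) {
          if (tp %in% c("IAI", "IAIA") && ol$functionality < 2) next
          if (tp %in% c("AIA", "IAIA") && iso$functionality < 2) next
          counter <- counter + 1L
          id <- paste0(prefix[[as.character(len)]], "_", counter)
          mol <- pf_assemble(iso, ol, tp, id)
          if (cap != "none") mol <- cap_isocyanates(mol, cap)
          oligomers[[id]] <- structure(
            list(id = id, mol = mol, iso_id = iso$id, ol_id = ol$id,
                 topology = tp, cap = cap, n_units = len,
                 urethane_bonds = .pf_topologies$urethane_bonds[
                   .pf_topologies$topology == tp]),
            class = "pur_oligomer")
        }
      }
    }
  }
  if (length(oligomers) == 0) {
    tab <- data.frame(id = character(0), units = integer(0),
                      topology = character(0), isocyanate = character(0),
                      alcohol = character(0), urethane_bonds = integer(0),
                      cap = character(0))
    return(structure(list(oligomers = oligomers, table = tab, cap = cap),
                     class = "pur_library"))
  }
  tab <- data.frame(
    id = vapply(oligomers, `[[`, character(1), "id"),
    units = vapply(oligomers, `[[`, integer(1), "n_units"),
    topology = vapply(oligomers, `[[`, character(1), "topology"),
    isocyanate = vapply(oligomers, `[[`, character(1), "iso_id"),
    alcohol = vapply(oligomers, `[[`, character(1), "ol_id"),
    urethane_bonds = vapply(oligomers, `[[`, integer(1), "urethane_bonds"),
    cap = cap, row.names = NULL)
  structure(list(oligomers = oligomers, table = tab, cap = cap),
            class = "pur_library")
}

#' @export
length.pur_library <- function(x) length(x$oligomers)

#' @export
print.pur_library <- function(x, ...) {
  cat("<pur_library> ", length(x), " fragments (cap: ", x$cap, ")\n", sep = "")
  print(table(units = x$table$units))
  invisible(x)
}

#' @export
as.data.frame.pur_library <- function(x, ...) x$table

#' @export
print.pur_oligomer <- function(x, ...) {
  cat(sprintf("<pur_oligomer> %s  [%d units, %s, %s + %s, cap %s]\n",
              x$id, x$n_units, x$topology, x$iso_id, x$ol_id, x$cap))
  invisible(x)
}

# default isocyanate id -> class used in the published grouping
.pf_iso_classes <- c(
  "MIC" = "MIC", "BIC" = "BIC", "HDI" = "HDI", "IPDI" = "IPDI",
  "HMDI" = "HMDI",
  "4,4'-MDI" = "MDI", "2,4'-MDI" = "MDI", "2,2'-MDI" = "MDI",
  "2,4-TDI" = "TDI", "2,6-TDI" = "TDI")

#' Group an oligomer by its isocyanate class
#'
#' Maps the fragment's isocyanate building block to one of the seven
#' grouping tags (MIC, BIC, MDI, TDI, HDI, IPDI, HMDI); MDI and TDI
#' collect their positional isomers. Custom building-block sets supply
#' their own mapping.
#'
#' @param x a `pur_oligomer` or an isocyanate id string.
#' @param mapping named character vector (id -> class); defaults to the
#'   packaged building-block mapping, with a pattern fallback matching
#'   ids that contain "MDI"/"TDI".
#' @return class tag (character).
#' @export
assign_isocyanate_class <- function(x, mapping = NULL) {
  id <- if (inherits(x, "pur_oligomer")) x$iso_id else as.character(x)
  map <- c(mapping, .pf_iso_classes)
  if (id %in% names(map)) return(unname(map[[id]]))
  if (grepl("MDI", id, fixed = TRUE)) return("MDI")
  if (grepl("TDI", id, fixed = TRUE)) return("TDI")
  stop("unknown isocyanate id '", id,
       "': supply a mapping for custom building-block sets", call. = FALSE)
}
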