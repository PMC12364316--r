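# Atom selections: ligand, binding pocket, protein, heavy atoms.
#
# Conventions: "protein" means all polymer (non-hetero) atoms; waters and
# ions are excluded everywhere; density and CC computations consume heavy
# atoms only (maps in the 2.7-3.7 Angstrom range carry no hydrogen signal).

.residueKey <- function(a) paste(a$chain, a$resseq, a$resname, sep = "\r")

#' Select the ligand
#'
#' Selects every atom of the named hetero residue. With `ligandName =
#' "auto"`, picks the largest non-water, non-ion hetero residue by
#' heavy-atom count.
#'
#' @param structure a [Structure-class].
#' @param ligandName residue name, or `"auto"` (default).
#' @return A [Selection-class] labelled `"ligand"`.
#' @export
selectLigand <- function(structure, ligandName = "auto") {
  a <- structure@atoms
  het <- a$hetero & !(toupper(a$resname) %in% c(.WATER_NAMES, .ION_NAMES))
  if (ligandName == "auto") {
    if (!any(het))
      stop("no hetero residues present; cannot auto-select a ligand")
    key <- .residueKey(a)
    counts <- tapply(a$element[het] != "H", key[het], sum)
    bestKey <- names(counts)[which.max(counts)]
    idx <- which(key == bestKey)
  } else {
    idx <- which(a$hetero & toupper(a$resname) == toupper(ligandName))
    if (!length(idx)) {
      present <- unique(a$resname[a$hetero])
      stop(sprintf("no hetero residue named '%s'; present: %s", ligandName,
                   if (length(present)) paste(present, collapse = ", ")
                   else "(none)"))
    }
  }
  Selection(idx, "ligand")
}

#' Select the binding pocket
#'
#' All atoms of every protein residue having at least one atom within
#' `cutoff` of at least one ligand atom. Whole residues are included. An
#' empty result is permitted.
#'
#' @param structure a [Structure-class].
#' @param ligand a [Selection-class] (the ligand).
#' @param cutoff distance cutoff in Angstrom (default 4).
#' @return A [Selection-class] labelled `"pocket"`.
#' @export
selectPocket <- function(structure, ligand, cutoff = 4) {
  stopifnot(length(ligand) > 0L)
  a <- structure@atoms
  prot <- which(!a$hetero)
  if (!length(prot)) return(Selection(integer(0), "pocket"))
  pc <- coords(structure)[prot, , drop = FALSE]
  lc <- coords(structure)[ligand@indices, , drop = FALSE]
  # min distance from each protein atom to any ligand atom
  d2min <- cpp_min_dist2(pc, lc)
  close <- prot[d2min < cutoff^2]
  if (!length(close)) return(Selection(integer(0), "pocket"))
  key <- .residueKey(a)
  idx <- which(!a$hetero & key %in% unique(key[close]))
  Selection(idx, "pocket")
}

#' Select all polymer atoms
#'
#' All non-hetero atoms (waters and ions are hetero and thus excluded).
#'
#' @param structure a [Structure-class].
#' @return A [Selection-class] labelled `"protein"`.
#' @export
selectProtein <- function(structure) {
  Selection(which(!structure@atoms$hetero), "protein")
}

#' Restrict a selection to heavy atoms
#'
#' @param selection a [Selection-class].
#' @param structure the [Structure-class] it indexes.
#' @return A [Selection-class] with hydrogens removed (label preserved).
#' @export
heavyAtoms <- function(selection, structure) {
  el <- structure@atoms$element[selection@indices]
  new("Selection", indices = selection@indices[el != "H"],
      label = selection@label)
}
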