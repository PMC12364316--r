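# PDB and minimal mmCIF structure I/O.
#
# PDB columns follow wwPDB format v3.3. mmCIF support is read-only and
# limited to the atom_site loop. Altloc policy: keep the highest-occupancy
# conformer; ties keep the first encountered.

#' Read an atomic structure
#'
#' Reads all ATOM/HETATM records from a PDB file, or the `atom_site` loop of
#' a minimal mmCIF file. Elements are taken from the element column when
#' present, otherwise inferred from the atom name. Alternate locations are
#' collapsed to the highest-occupancy conformer (ties: first encountered).
#'
#' @param path file path.
#' @param format `"pdb"`, `"mmcif"` or `"auto"` (by extension, default).
#' @return A [Structure-class].
#' @export
readStructure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
  }
  if (format == "pdb") .readPDB(path) else .readmmCIF(path)
}

.finishAtoms <- function(atoms, path) {
  if (nrow(atoms) == 0L) stop("no ATOM/HETATM records found in ", path)
  # resolve elements: blank -> infer from atom name
  blank <- is.na(atoms$element) | atoms$element == ""
  if (any(blank)) atoms$element[blank] <- .elementFromAtomName(atoms$name[blank])
  bad <- is.na(atoms$element) | !.isKnownElement(atoms$element)
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf("unknown element for atom serial %d (name '%s', residue %s %d)",
                 atoms$serial[i], atoms$name[i], atoms$resname[i],
                 atoms$resseq[i]))
  }
  atoms$element <- toupper(atoms$element)
  # collapse altlocs: within (chain, resseq, resname, name) keep best occupancy
  if (any(atoms$altloc != "")) {
    key <- paste(atoms$chain, atoms$resseq, atoms$resname, atoms$name, sep = "\r")
    keep <- rep(TRUE, nrow(atoms))
    for (k in unique(key[duplicated(key)])) {
      idx <- which(key == k)
      best <- idx[which.max(atoms$occupancy[idx])]  # tie -> first
      keep[setdiff(idx, best)] <- FALSE
    }
    atoms <- atoms[keep, , drop = FALSE]
  }
  atoms$altloc <- NULL
  atoms$mass <- elementMass(atoms$element)
  if (anyDuplicated(atoms$serial)) atoms$serial <- seq_len(nrow(atoms))
  Structure(atoms, metadata = list(source = path))
}

.readPDB <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  sel <- which(rec == "ATOM  " | rec == "HETATM")
  # stop at the first ENDMDL so multi-model files yield model 1
  endmdl <- which(rec == "ENDMDL")
  if (length(endmdl)) sel <- sel[sel < endmdl[1]]
  if (!length(sel)) stop("no ATOM/HETATM records found in ", path)
  ln <- lines[sel]
  num <- function(s) suppressWarnings(as.numeric(s))
  xyz <- cbind(num(substr(ln, 31, 38)), num(substr(ln, 39, 46)),
               num(substr(ln, 47, 54)))
  if (anyNA(xyz)) {
    bad <- sel[which(is.na(rowSums(xyz)))[1]]
    stop(sprintf("cannot parse coordinates at line %d of %s", bad, path))
  }
  occ <- num(substr(ln, 55, 60))
  occ[is.na(occ)] <- 1
  atoms <- data.frame(
    serial = suppressWarnings(as.integer(substr(ln, 7, 11))),
    name = trimws(substr(ln, 13, 16)),
    altloc = trimws(substr(ln, 17, 17)),
    resname = trimws(substr(ln, 18, 20)),
    chain = trimws(substr(ln, 22, 22)),
    resseq = suppressWarnings(as.integer(substr(ln, 23, 26))),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    occupancy = occ,
    element = trimws(substr(ln, 77, 78)),
    hetero = substr(ln, 1, 6) == "HETATM",
    charge = 0,
    stringsAsFactors = FALSE)
  if (anyNA(atoms$serial)) atoms$serial <- seq_len(nrow(atoms))
  .finishAtoms(atoms, path)
}

.readmmCIF <- function(path) {
  lines <- readLines(path, warn = FALSE)
  # locate the atom_site loop
  tagIdx <- grep("^_atom_site\\.", lines)
  if (!length(tagIdx)) stop("no _atom_site loop found in ", path)
  tags <- sub("^_atom_site\\.", "", trimws(lines[tagIdx]))
  dataStart <- max(tagIdx) + 1L
  rows <- character(0)
  for (i in dataStart:length(lines)) {
    l <- trimws(lines[i])
    if (l == "" || startsWith(l, "#") || startsWith(l, "_") ||
        startsWith(l, "loop_") || startsWith(l, "data_")) break
    rows <- c(rows, l)
  }
  if (!length(rows)) stop("empty atom_site loop in ", path)
  fields <- strsplit(rows, "[[:space:]]+")
  nf <- lengths(fields)
  if (any(nf != length(tags)))
    stop(sprintf("malformed atom_site row %d in %s",
                 which(nf != length(tags))[1], path))
  m <- do.call(rbind, fields)
  colnames(m) <- tags
  col <- function(nm, alt = NULL) {
    if (nm %in% tags) m[, nm]
    else if (!is.null(alt) && alt %in% tags) m[, alt]
    else rep(NA_character_, nrow(m))
  }
  clean <- function(v) ifelse(v %in% c(".", "?"), "", v)
  occ <- suppressWarnings(as.numeric(clean(col("occupancy"))))
  occ[is.na(occ)] <- 1
  atoms <- data.frame(
    serial = suppressWarnings(as.integer(col("id"))),
    name = gsub('"', "", clean(col("label_atom_id", "auth_atom_id"))),
    altloc = clean(col("label_alt_id")),
    resname = clean(col("label_comp_id", "auth_comp_id")),
    chain = clean(col("auth_asym_id", "label_asym_id")),
    resseq = suppressWarnings(as.integer(clean(col("auth_seq_id", "label_seq_id")))),
    x = suppressWarnings(as.numeric(col("Cartn_x"))),
    y = suppressWarnings(as.numeric(col("Cartn_y"))),
    z = suppressWarnings(as.numeric(col("Cartn_z"))),
    occupancy = occ,
    element = clean(col("type_symbol")),
    hetero = col("group_PDB") == "HETATM",
    charge = 0,
    stringsAsFactors = FALSE)
  if (anyNA(atoms$x + atoms$y + atoms$z))
    stop("cannot parse Cartn_x/y/z coordinates in ", path)
  if (anyNA(atoms$serial)) atoms$serial <- seq_len(nrow(atoms))
  if (anyNA(atoms$resseq)) atoms$resseq[is.na(atoms$resseq)] <- 0L
  .finishAtoms(atoms, path)
}

#' Write a structure in PDB format
#'
#' Standard single-model PDB output. Chain identifiers longer than one
#' character raise an error rather than being silently truncated.
#'
#' @param structure a [Structure-class].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
writeStructure <- function(structure, path) {
  stopifnot(is(structure, "Structure"))
  validObject(structure)
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot open for writing: ", path, " (", conditionMessage(e), ")"))
  on.exit(close(con))
  writeLines(.pdbRecords(structure), con)
  writeLines("END", con)
  invisible(path)
}

.pdbRecords <- function(structure) {
  a <- structure@atoms
  if (any(nchar(a$chain) > 1L))
    stop("PDB chain ids must be a single character; offending chain(s): ",
         paste(unique(a$chain[nchar(a$chain) > 1L]), collapse = ", "))
  if (any(abs(c(a$x, a$y, a$z)) >= 10000))
    stop("coordinates out of PDB fixed-column range")
  # atom name justification: start in column 14 unless 4 chars / 2-char element
  nm <- vapply(seq_len(nrow(a)), function(i) {
    n <- a$name[i]
    if (nchar(n) >= 4L || nchar(a$element[i]) == 2L)
      sprintf("%-4s", substr(n, 1, 4))
    else sprintf(" %-3s", n)
  }, character(1))
  sprintf("%-6s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          ifelse(a$hetero, "HETATM", "ATOM"),
          a$serial %% 100000L, nm, "", substr(a$resname, 1, 3), a$chain,
          a$resseq %% 10000L, "", a$x, a$y, a$z, a$occupancy, 0,
          .elementDisplay(a$element))
}

#' Write a trajectory as a multi-model PDB
#'
#' @param trajectory a [Trajectory-class].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
writeTrajectory <- function(trajectory, path) {
  stopifnot(is(trajectory, "Trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  s <- trajectory@template
  for (i in seq_along(trajectory@frames)) {
    coords(s) <- trajectory@frames[[i]]
    writeLines(sprintf("MODEL     %4d", i), con)
    writeLines(.pdbRecords(s), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
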