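## Output artifacts of the workflow: frcmod parameter-modification files,
## parmed command scripts, TRIPOS mol2 coordinate/charge files, JSON atom
## maps, and two-column tabulated torsion profiles.

#' Write an AMBER frcmod parameter-modification file
#'
#' Emits the fitted torsion types in the DIHE section using the AMBER
#' continuation convention: in a multi-component dihedral every line except
#' the last carries a negative periodicity. The divider is always written as
#' 1 with barrier heights pre-divided, so the file round-trips exactly.
#' Components with an amplitude below `pruneFloor` are dropped (logged via
#' `message`).
#'
#' @param fits list of [FitResult-class] objects (or a single one).
#' @param path output path.
#' @param title first line of the file.
#' @param pruneFloor amplitude floor in kcal/mol below which a Fourier
#'   component is not emitted.
#' @return `path`, invisibly.
#' @export
writeFrcmod <- function(fits, path, title = "torsionsmith fitted torsions",
                        pruneFloor = 0.005) {
  if (is(fits, "FitResult")) fits <- list(fits)
  lines <- c(title, "", "MASS", "", "BOND", "", "ANGLE", "", "DIHE")
  for (fr in fits) {
    comp <- fr@components
    drop <- comp$vn < pruneFloor
    if (any(drop)) {
      message(sprintf("frcmod: dropping %d component(s) of %s below %g kcal/mol",
                      sum(drop), fr@key$typeQuad, pruneFloor))
      comp <- comp[!drop, , drop = FALSE]
    }
    if (!nrow(comp)) next
    ty <- strsplit(fr@key$typeQuad, "-", fixed = TRUE)[[1]]
    tyStr <- paste(sprintf("%-2s", ty), collapse = "-")
    for (r in seq_len(nrow(comp))) {
      per <- comp$n[r] * if (r < nrow(comp)) -1 else 1
      lines <- c(lines, sprintf(
        "%s   1  %10.5f  %8.3f  %6.1f    SCEE=%.4f SCNB=%.4f",
        tyStr, comp$vn[r], comp$gamma[r], per, comp$scee[r], comp$scnb[r]))
    }
  }
  lines <- c(lines, "", "IMPROPER", "", "NONBON", "")
  writeLines(lines, path)
  invisible(path)
}

#' Read back a frcmod DIHE section
#'
#' Parses the DIHE records written by [writeFrcmod()] into a list of
#' per-type component tables, folding continuation lines (negative
#' periodicity) into multi-component terms.
#'
#' @param path frcmod file path.
#' @return named list (by type quadruple string, `a -b -c -d` collapsed to
#'   `a-b-c-d`) of data.frames with columns vn, n, gamma, scee, scnb.
#' @export
readFrcmod <- function(path) {
  lines <- readLines(path)
  dstart <- match("DIHE", trimws(lines))
  if (is.na(dstart)) stop("frcmod has no DIHE section")
  out <- list()
  i <- dstart + 1L
  while (i <= length(lines)) {
    ln <- lines[i]
    if (!nzchar(trimws(ln))) break
    ty <- gsub(" ", "", substr(ln, 1, 11))
    rest <- strsplit(trimws(substr(ln, 12, nchar(ln))), "\\s+")[[1]]
    scee <- as.numeric(sub("SCEE=", "", grep("^SCEE=", rest, value = TRUE)))
    scnb <- as.numeric(sub("SCNB=", "", grep("^SCNB=", rest, value = TRUE)))
    num <- suppressWarnings(as.numeric(rest))
    num <- num[!is.na(num)]
    row <- data.frame(vn = num[2] / num[1], n = abs(as.integer(num[4])),
                      gamma = num[3],
                      scee = if (length(scee)) scee else 1.2,
                      scnb = if (length(scnb)) scnb else 2.0)
    out[[ty]] <- rbind(out[[ty]], row)
    i <- i + 1L
  }
  out
}

#' Apply frcmod dihedral records to a topology
#'
#' Replaces the Fourier components of every torsion type present in the
#' frcmod with the file's components.
#'
#' @param topology a [MoleculeTopology-class].
#' @param frcmod result of [readFrcmod()] or a file path.
#' @return the updated topology.
#' @export
applyFrcmod <- function(topology, frcmod) {
  if (is.character(frcmod)) frcmod <- readFrcmod(frcmod)
  for (ty in names(frcmod)) {
    key <- list(typeQuad = ty)
    topology <- setTorsionComponents(topology, key, frcmod[[ty]])
  }
  topology
}

#' Write a parmed command script applying fitted torsion types
#'
#' One consolidated deleteDihedral/addDihedral script per run. When several
#' fit results update the same type quadruple, `mergePolicy = "last"` (the
#' default) keeps the last-fitted parameters and logs the conflict;
#' identical duplicates are emitted once. Fits obtained on fragments are
#' addressed to the parent ligand's atom types through the fragment atom
#' map (types are copied from the parent, so the mapped type quadruple is
#' looked up and must resolve).
#'
#' @param fits list of [FitResult-class] objects.
#' @param path output path.
#' @param topologyFile name of the topology the script should modify.
#' @param outFile name of the topology the script writes.
#' @param mergePolicy only "last" is implemented.
#' @return `path`, invisibly.
#' @export
writeParmedScript <- function(fits, path, topologyFile = "ligand.prmtop",
                              outFile = "ligand.fitted.prmtop",
                              mergePolicy = c("last", "error")) {
  mergePolicy <- match.arg(mergePolicy)
  if (is(fits, "FitResult")) fits <- list(fits)
  byType <- list()
  for (fr in fits) {
    ty <- fr@key$typeQuad
    if (!is.null(byType[[ty]])) {
      if (identical(byType[[ty]]@components, fr@components)) next
      if (mergePolicy == "error")
        stop("conflicting updates for torsion type ", ty)
      message("parmed script: conflicting updates for ", ty,
              "; keeping last-fitted parameters")
    }
    byType[[ty]] <- fr
  }
  lines <- c(sprintf("parm %s", topologyFile))
  for (ty in names(byType)) {
    t4 <- strsplit(ty, "-", fixed = TRUE)[[1]]
    masks <- sprintf("@%%%s", t4)
    lines <- c(lines, paste("deleteDihedral", paste(masks, collapse = " ")))
    comp <- byType[[ty]]@components
    for (r in seq_len(nrow(comp))) {
      lines <- c(lines, sprintf(
        "addDihedral %s %.6f %d %.4f %.4f %.4f",
        paste(masks, collapse = " "), comp$vn[r], comp$n[r], comp$gamma[r],
        comp$scee[r], comp$scnb[r]))
    }
  }
  lines <- c(lines, sprintf("outparm %s", outFile))
  writeLines(lines, path)
  invisible(path)
}

#' Write a TRIPOS mol2 file
#'
#' @param topology a [MoleculeTopology-class].
#' @param conformation N x 3 coordinates.
#' @param path output path.
#' @param charges per-atom charges; defaults to the topology charges.
#' @param name molecule name.
#' @return `path`, invisibly.
#' @export
writeMol2 <- function(topology, conformation, path,
                      charges = topology@atoms$charge, name = "MOL") {
  at <- topology@atoms
  stopifnot(length(charges) == nrow(at))
  bd <- topology@bonds
  lines <- c("@<TRIPOS>MOLECULE", name,
             sprintf("%5d %5d %5d %5d %5d", nrow(at), nrow(bd), 1, 0, 0),
             "SMALL", "USER_CHARGES", "", "@<TRIPOS>ATOM")
  for (i in seq_len(nrow(at))) {
    lines <- c(lines, sprintf(
      "%7d %-8s %10.4f %10.4f %10.4f %-6s %3d %-8s %10.6f",
      i, at$name[i], conformation[i, 1], conformation[i, 2],
      conformation[i, 3], at$type[i], 1, "MOL", charges[i]))
  }
  lines <- c(lines, "@<TRIPOS>BOND")
  for (b in seq_len(nrow(bd))) {
    ordStr <- if (bd$order[b] == 2) "2" else if (bd$order[b] == 3) "3" else "1"
    lines <- c(lines, sprintf("%6d %5d %5d %4s", b, bd$i[b], bd$j[b], ordStr))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read atoms/charges/coordinates back from a TRIPOS mol2 file
#'
#' @param path mol2 file path.
#' @return list with `atoms` data.frame (name, type, charge), `coords`
#'   N x 3 matrix, `bonds` data.frame (i, j, order).
#' @export
readMol2 <- function(path) {
  lines <- readLines(path)
  aStart <- grep("@<TRIPOS>ATOM", lines, fixed = TRUE)
  bStart <- grep("@<TRIPOS>BOND", lines, fixed = TRUE)
  sectionEnd <- function(start) {
    nxt <- grep("@<TRIPOS>", lines, fixed = TRUE)
    nxt <- nxt[nxt > start]
    if (length(nxt)) nxt[1] - 1L else length(lines)
  }
  aLines <- lines[(aStart + 1L):sectionEnd(aStart)]
  aLines <- aLines[nzchar(trimws(aLines))]
  tok <- strsplit(trimws(aLines), "\\s+")
  atoms <- data.frame(
    name = vapply(tok, `[`, "", 2),
    type = vapply(tok, `[`, "", 6),
    charge = as.numeric(vapply(tok, `[`, "", 9)))
  coords <- t(vapply(tok, function(v) as.numeric(v[3:5]), numeric(3)))
  bonds <- data.frame(i = integer(), j = integer(), order = integer())
  if (length(bStart)) {
    bLines <- lines[(bStart + 1L):sectionEnd(bStart)]
    bLines <- bLines[nzchar(trimws(bLines))]
    btok <- strsplit(trimws(bLines), "\\s+")
    bonds <- data.frame(
      i = as.integer(vapply(btok, `[`, "", 2)),
      j = as.integer(vapply(btok, `[`, "", 3)),
      order = suppressWarnings(as.integer(vapply(btok, `[`, "", 4))))
    bonds$order[is.na(bonds$order)] <- 1L
  }
  list(atoms = atoms, coords = coords, bonds = bonds)
}

#' Write / read a fragment atom map as JSON
#'
#' Maps are serialized with 0-based indices and an explicit `caps` array;
#' the in-memory representation is 1-based.
#'
#' @param map list with `pairs` (two-column matrix: fragment, parent) and
#'   `caps` (fragment indices), plus optional `fragmentId`.
#' @param path JSON path.
#' @return `path` invisibly / the map list.
#' @name atomMapIO
NULL

#' @rdname atomMapIO
#' @export
writeAtomMap <- function(map, path) {
  obj <- list(
    fragment_id = if (!is.null(map$fragmentId)) map$fragmentId else "frag",
    pairs = unname(lapply(seq_len(nrow(map$pairs)), function(r)
      c(map$pairs[r, 1] - 1L, map$pairs[r, 2] - 1L))),
    caps = as.list(as.integer(map$caps) - 1L))
  jsonlite::write_json(obj, path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname atomMapIO
#' @export
readAtomMap <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  pairs <- matrix(as.integer(unlist(obj$pairs)), ncol = 2, byrow = TRUE) + 1L
  if (anyDuplicated(pairs[, 1]) || anyDuplicated(pairs[, 2]))
    stop("atom map is not injective")
  list(fragmentId = obj$fragment_id, pairs = pairs,
       caps = as.integer(unlist(obj$caps)) + 1L)
}

#' Tabulated torsion profile interchange
#'
#' Two-column whitespace-separated text (angle in degrees, energy in
#' kcal/mol), `#` comments allowed.
#'
#' @param profile a [ScanProfile-class] (write) / file path (read).
#' @param path output path.
#' @param grid optional [makeGrid()] the read profile must match.
#' @return `path` invisibly / a [ScanProfile-class] with empty geometries.
#' @name profileIO
NULL

#' @rdname profileIO
#' @export
writeProfileTable <- function(profile, path) {
  writeLines(c(sprintf("# torsion %s backend %s",
                       paste(profile@key$quad, collapse = "-"),
                       profile@backend),
               "# angle_deg  energy_kcal_mol",
               sprintf("%8.2f  %14.8f", profile@grid@angles,
                       profile@energies)), path)
  invisible(path)
}

#' @rdname profileIO
#' @export
readProfileTable <- function(path, grid = NULL) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  tok <- strsplit(trimws(lines), "\\s+")
  ang <- vapply(tok, function(v) as.numeric(v[1]), 0)
  en <- vapply(tok, function(v) as.numeric(v[2]), 0)
  if (is.null(grid)) {
    sp <- unique(round(diff(sort(ang)), 8))
    grid <- makeGrid(sp[1])
  }
  ord <- match(round(grid@angles, 6), round(wrapAngle(ang), 6))
  if (anyNA(ord)) stop("tabulated profile does not cover the grid")
  new("ScanProfile", key = list(quad = NA_integer_, typeQuad = "tabulated"),
      grid = grid, energies = en[ord] - min(en), geometries = list(),
      backend = "tabulated", centroid = NA_integer_, degraded = FALSE)
}
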