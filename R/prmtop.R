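## AMBER prmtop (%FLAG/%FORMAT sectioned) reader and a minimal writer.
## The writer emits the standard flag set for a single-residue gas-phase
## molecule and exists chiefly so fixtures and fragments can round-trip
## through the reader; the reader accepts any conforming prmtop.

AMBER_CHARGE_UNIT <- 18.2223

ELEMENT_NUMBERS <- c(H = 1, C = 6, N = 7, O = 8, F = 9, P = 15, S = 16,
                     Cl = 17, Br = 35, I = 53)

fmtFortran <- function(x, spec) {
  if (spec$type == "a") sprintf(sprintf("%%-%ds", spec$width), x)
  else if (spec$type == "I") sprintf(sprintf("%%%dd", spec$width), x)
  else sprintf(sprintf("%%%d.%dE", spec$width, spec$dec), x)
}

writeSection <- function(con, flag, format, values, spec) {
  writeLines(sprintf("%%FLAG %s", flag), con)
  writeLines(sprintf("%%FORMAT(%s)", format), con)
  if (length(values) == 0L) { writeLines("", con); return(invisible()) }
  txt <- fmtFortran(values, spec)
  rows <- split(txt, (seq_along(txt) - 1L) %/% spec$perLine)
  writeLines(vapply(rows, paste0, "", collapse = ""), con)
}

## Wider-than-stock float format (declared in the %FORMAT record, so any
## conforming reader handles it): keeps fixture round trips at full double
## precision.
SPEC_E <- list(type = "E", width = 24, dec = 16, perLine = 3)
SPEC_I <- list(type = "I", width = 8, dec = 0, perLine = 10)
SPEC_A <- list(type = "a", width = 4, dec = 0, perLine = 20)

#' Write a MoleculeTopology as an AMBER prmtop file
#'
#' Emits the standard flag set (POINTERS, CHARGE, MASS, bonded terms,
#' Lennard-Jones coefficient tables, exclusion list, dihedral scee/scnb
#' sections) for a single-residue gas-phase molecule. Charges are stored in
#' internal AMBER units (multiplied by 18.2223), angles and phases in
#' radians, following the prmtop convention.
#'
#' @param topology a [MoleculeTopology-class].
#' @param path output file path.
#' @param title TITLE section content.
#' @return `path`, invisibly.
#' @export
writePrmtop <- function(topology, path, title = "torsionsmith topology") {
  at <- topology@atoms
  natom <- nrow(at)
  types <- unique(at$type)
  tIdx <- match(at$type, types)
  ntypes <- length(types)

  bd <- topology@bonds
  bKey <- paste(bd$kb, bd$l0)
  bTypes <- unique(bKey); bTi <- match(bKey, bTypes)
  bH <- at$element[bd$i] == "H" | at$element[bd$j] == "H"

  an <- topology@angles
  aKey <- paste(an$ka, an$theta0)
  aTypes <- unique(aKey); aTi <- match(aKey, aTypes)
  aH <- at$element[an$i] == "H" | at$element[an$k] == "H"

  to <- topology@torsions
  dKey <- paste(to$vn, to$n, to$gamma, to$scee, to$scnb)
  dTypes <- if (nrow(to)) unique(dKey) else character()
  dTi <- match(dKey, dTypes)
  dH <- if (nrow(to)) at$element[to$i] == "H" | at$element[to$j] == "H" |
    at$element[to$k] == "H" | at$element[to$l] == "H" else logical()

  ## per-atom exclusion lists (1-2, 1-3, 1-4; j > i)
  exAll <- rbind(topology@excluded,
                 topology@pairs14[, c("i", "j"), drop = FALSE])
  exList <- lapply(seq_len(natom), function(i) {
    js <- sort(c(exAll$j[exAll$i == i], exAll$i[exAll$j == i]))
    js[js > i]
  })
  nExcl <- vapply(exList, length, 0L)
  exFlat <- unlist(lapply(exList, function(v) if (length(v)) v else 0L))
  nnb <- length(exFlat)

  ptr <- integer(31)
  ptr[1] <- natom; ptr[2] <- ntypes
  ptr[3] <- sum(bH); ptr[4] <- sum(!bH)
  ptr[5] <- sum(aH); ptr[6] <- sum(!aH)
  ptr[7] <- sum(dH); ptr[8] <- sum(!dH)
  ptr[11] <- nnb; ptr[12] <- 1L
  ptr[13] <- sum(!bH); ptr[14] <- sum(!aH); ptr[15] <- sum(!dH)
  ptr[16] <- length(bTypes); ptr[17] <- length(aTypes)
  ptr[18] <- length(dTypes); ptr[19] <- ntypes
  ptr[29] <- natom

  ## LJ coefficient tables with Lorentz-Berthelot combination
  nbIdx <- matrix(0L, ntypes, ntypes)
  acoef <- bcoef <- numeric(ntypes * (ntypes + 1) / 2)
  cnt <- 0L
  for (ii in seq_len(ntypes)) for (jj in seq_len(ii)) {
    cnt <- cnt + 1L
    ai <- match(TRUE, tIdx == ii); aj <- match(TRUE, tIdx == jj)
    rmin <- at$rminHalf[ai] + at$rminHalf[aj]
    eps <- sqrt(at$epsilon[ai] * at$epsilon[aj])
    acoef[cnt] <- eps * rmin^12
    bcoef[cnt] <- 2 * eps * rmin^6
    nbIdx[ii, jj] <- nbIdx[jj, ii] <- cnt
  }

  packBonds <- function(rows) {
    if (!length(rows)) return(integer())
    as.integer(t(cbind(3 * (bd$i[rows] - 1L), 3 * (bd$j[rows] - 1L),
                       bTi[rows])))
  }
  packAngles <- function(rows) {
    if (!length(rows)) return(integer())
    as.integer(t(cbind(3 * (an$i[rows] - 1L), 3 * (an$j[rows] - 1L),
                       3 * (an$k[rows] - 1L), aTi[rows])))
  }
  packDihedrals <- function(rows) {
    if (!length(rows)) return(integer())
    out <- integer()
    for (r in rows) {
      qd <- c(to$i[r], to$j[r], to$k[r], to$l[r])
      needK <- !to$calc14[r] || to$improper[r]
      needL <- to$improper[r]
      if ((needK && qd[3] == 1L) || (needL && qd[4] == 1L)) qd <- rev(qd)
      if ((needK && qd[3] == 1L) || (needL && qd[4] == 1L))
        stop("cannot encode dihedral sign flags: atom 1 in signed slot both ways")
      kS <- if (needK) -1L else 1L
      lS <- if (needL) -1L else 1L
      out <- c(out, 3L * (qd[1] - 1L), 3L * (qd[2] - 1L),
               kS * 3L * (qd[3] - 1L), lS * 3L * (qd[4] - 1L), dTi[r])
    }
    out
  }
  ## multi-term dihedrals: only the calc14-owning row computes the 1-4 pair;
  ## every other row gets a negative third index (continuation convention).
  dRowOrder <- function(h) {
    rows <- which(if (h) dH else !dH)
    rows[order(to$i[rows], to$j[rows], to$k[rows], to$l[rows],
               !to$calc14[rows])]
  }

  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%%VERSION  VERSION_STAMP = V0001.000  DATE = %s",
                     format(Sys.Date(), "%m/%d/%y")), con)
  writeSection(con, "TITLE", "20a4", title, SPEC_A)
  writeSection(con, "POINTERS", "10I8", ptr, SPEC_I)
  writeSection(con, "ATOM_NAME", "20a4", at$name, SPEC_A)
  writeSection(con, "CHARGE", "3E24.16", at$charge * AMBER_CHARGE_UNIT, SPEC_E)
  writeSection(con, "ATOMIC_NUMBER", "10I8",
               as.integer(ELEMENT_NUMBERS[at$element]), SPEC_I)
  writeSection(con, "MASS", "3E24.16", at$mass, SPEC_E)
  writeSection(con, "ATOM_TYPE_INDEX", "10I8", tIdx, SPEC_I)
  writeSection(con, "NUMBER_EXCLUDED_ATOMS", "10I8", nExcl, SPEC_I)
  writeSection(con, "NONBONDED_PARM_INDEX", "10I8",
               as.integer(t(nbIdx)), SPEC_I)
  writeSection(con, "RESIDUE_LABEL", "20a4", "MOL", SPEC_A)
  writeSection(con, "RESIDUE_POINTER", "10I8", 1L, SPEC_I)
  writeSection(con, "BOND_FORCE_CONSTANT", "3E24.16",
               as.numeric(vapply(strsplit(bTypes, " "), function(v)
                 as.numeric(v[1]), 0)), SPEC_E)
  writeSection(con, "BOND_EQUIL_VALUE", "3E24.16",
               as.numeric(vapply(strsplit(bTypes, " "), function(v)
                 as.numeric(v[2]), 0)), SPEC_E)
  writeSection(con, "ANGLE_FORCE_CONSTANT", "3E24.16",
               as.numeric(vapply(strsplit(aTypes, " "), function(v)
                 as.numeric(v[1]), 0)), SPEC_E)
  writeSection(con, "ANGLE_EQUIL_VALUE", "3E24.16",
               as.numeric(vapply(strsplit(aTypes, " "), function(v)
                 as.numeric(v[2]), 0)) * DEG, SPEC_E)
  dPart <- function(k) as.numeric(vapply(strsplit(dTypes, " "), function(v)
    as.numeric(v[k]), 0))
  writeSection(con, "DIHEDRAL_FORCE_CONSTANT", "3E24.16", dPart(1), SPEC_E)
  writeSection(con, "DIHEDRAL_PERIODICITY", "3E24.16", dPart(2), SPEC_E)
  writeSection(con, "DIHEDRAL_PHASE", "3E24.16", dPart(3) * DEG, SPEC_E)
  writeSection(con, "SCEE_SCALE_FACTOR", "3E24.16", dPart(4), SPEC_E)
  writeSection(con, "SCNB_SCALE_FACTOR", "3E24.16", dPart(5), SPEC_E)
  writeSection(con, "LENNARD_JONES_ACOEF", "3E24.16", acoef, SPEC_E)
  writeSection(con, "LENNARD_JONES_BCOEF", "3E24.16", bcoef, SPEC_E)
  writeSection(con, "BONDS_INC_HYDROGEN", "10I8", packBonds(which(bH)),
               SPEC_I)
  writeSection(con, "BONDS_WITHOUT_HYDROGEN", "10I8", packBonds(which(!bH)),
               SPEC_I)
  writeSection(con, "ANGLES_INC_HYDROGEN", "10I8", packAngles(which(aH)),
               SPEC_I)
  writeSection(con, "ANGLES_WITHOUT_HYDROGEN", "10I8",
               packAngles(which(!aH)), SPEC_I)
  writeSection(con, "DIHEDRALS_INC_HYDROGEN", "10I8",
               packDihedrals(dRowOrder(TRUE)), SPEC_I)
  writeSection(con, "DIHEDRALS_WITHOUT_HYDROGEN", "10I8",
               packDihedrals(dRowOrder(FALSE)), SPEC_I)
  writeSection(con, "EXCLUDED_ATOMS_LIST", "10I8", exFlat, SPEC_I)
  writeSection(con, "AMBER_ATOM_TYPE", "20a4", at$type, SPEC_A)
  invisible(path)
}

parsePrmtopSections <- function(path) {
  lines <- readLines(path)
  flagAt <- grep("^%FLAG", lines)
  sections <- list()
  for (s in seq_along(flagAt)) {
    name <- trimws(sub("^%FLAG\\s+", "", lines[flagAt[s]]))
    end <- if (s < length(flagAt)) flagAt[s + 1] - 1L else length(lines)
    body <- lines[(flagAt[s] + 1L):end]
    fmtLine <- grep("^%FORMAT", body, value = TRUE)
    if (!length(fmtLine))
      stop(sprintf("prmtop format error: section %s has no %%FORMAT", name))
    fmt <- regmatches(fmtLine[1],
                      regexec("\\(\\s*(\\d+)([aAiIeEfF])(\\d+)", fmtLine[1]))[[1]]
    width <- as.integer(fmt[4])
    type <- toupper(fmt[3])
    data <- body[!grepl("^%", body)]
    vals <- unlist(lapply(data, function(ln) {
      if (!nzchar(trimws(ln))) return(character())
      starts <- seq(1, nchar(ln), by = width)
      substring(ln, starts, pmin(starts + width - 1L, nchar(ln)))
    }))
    vals <- vals[nzchar(trimws(vals))]
    sections[[name]] <- switch(type,
      A = trimws(vals),
      I = as.integer(vals),
      as.numeric(vals))
  }
  sections
}

#' Read an AMBER prmtop topology
#'
#' Parses a %FLAG/%FORMAT sectioned AMBER topology into a
#' [MoleculeTopology-class]. Charges are converted from internal AMBER
#' charge units to elementary charges (divided by 18.2223); angle
#' equilibrium values and dihedral phases are converted from radians to
#' degrees. The 1-4 pair list is reconstructed from the dihedral records,
#' skipping continuation (negative third index) and improper (negative
#' fourth index) entries.
#'
#' @param path path to a prmtop file.
#' @return a [MoleculeTopology-class].
#' @export
readTopology <- function(path) {
  sec <- parsePrmtopSections(path)
  need <- c("POINTERS", "CHARGE", "MASS", "ATOM_TYPE_INDEX",
            "BOND_FORCE_CONSTANT", "BOND_EQUIL_VALUE",
            "ANGLE_FORCE_CONSTANT", "ANGLE_EQUIL_VALUE",
            "DIHEDRAL_FORCE_CONSTANT", "DIHEDRAL_PERIODICITY",
            "DIHEDRAL_PHASE", "LENNARD_JONES_ACOEF", "LENNARD_JONES_BCOEF",
            "NONBONDED_PARM_INDEX", "EXCLUDED_ATOMS_LIST",
            "NUMBER_EXCLUDED_ATOMS", "AMBER_ATOM_TYPE")
  missing <- setdiff(need, names(sec))
  if (length(missing))
    stop("prmtop format error: missing mandatory section(s) ",
         paste(missing, collapse = ", "))
  ptr <- sec$POINTERS
  natom <- ptr[1]; ntypes <- ptr[2]
  if (length(sec$CHARGE) != natom || length(sec$MASS) != natom ||
      length(sec$ATOM_TYPE_INDEX) != natom)
    stop("prmtop format error: per-atom section length disagrees with POINTERS")
  if (length(sec$NUMBER_EXCLUDED_ATOMS) != natom)
    stop("prmtop format error: NUMBER_EXCLUDED_ATOMS length mismatch")

  ## per-type LJ from the diagonal of the coefficient tables
  nbIdx <- matrix(sec$NONBONDED_PARM_INDEX, ntypes, ntypes, byrow = TRUE)
  rminHalfT <- epsT <- numeric(ntypes)
  for (tt in seq_len(ntypes)) {
    idx <- nbIdx[tt, tt]
    A <- sec$LENNARD_JONES_ACOEF[idx]; B <- sec$LENNARD_JONES_BCOEF[idx]
    if (A > 0 && B > 0) {
      rmin <- (2 * A / B)^(1 / 6)
      rminHalfT[tt] <- rmin / 2
      epsT[tt] <- B^2 / (4 * A)
    }
  }
  element <- if (!is.null(sec$ATOMIC_NUMBER)) {
    names(ELEMENT_NUMBERS)[match(sec$ATOMIC_NUMBER, ELEMENT_NUMBERS)]
  } else ifelse(sec$MASS < 2, "H", "C")
  nameCol <- if (!is.null(sec$ATOM_NAME)) sec$ATOM_NAME else
    paste0(element, seq_len(natom))
  atoms <- data.frame(
    name = nameCol, element = element, type = sec$AMBER_ATOM_TYPE,
    charge = sec$CHARGE / AMBER_CHARGE_UNIT, mass = sec$MASS,
    rminHalf = rminHalfT[sec$ATOM_TYPE_INDEX],
    epsilon = epsT[sec$ATOM_TYPE_INDEX])

  unpack3 <- function(v) {
    if (is.null(v) || !length(v)) return(NULL)
    m <- matrix(v, ncol = 3, byrow = TRUE)
    data.frame(i = m[, 1] / 3 + 1L, j = m[, 2] / 3 + 1L, t = m[, 3])
  }
  unpack4 <- function(v) {
    if (is.null(v) || !length(v)) return(NULL)
    m <- matrix(v, ncol = 4, byrow = TRUE)
    data.frame(i = m[, 1] / 3 + 1L, j = m[, 2] / 3 + 1L,
               k = m[, 3] / 3 + 1L, t = m[, 4])
  }
  bRaw <- rbind(unpack3(sec$BONDS_INC_HYDROGEN),
                unpack3(sec$BONDS_WITHOUT_HYDROGEN))
  bonds <- if (is.null(bRaw)) {
    data.frame(i = integer(), j = integer(), kb = numeric(), l0 = numeric())
  } else data.frame(i = as.integer(bRaw$i), j = as.integer(bRaw$j),
                    kb = sec$BOND_FORCE_CONSTANT[bRaw$t],
                    l0 = sec$BOND_EQUIL_VALUE[bRaw$t])
  aRaw <- rbind(unpack4(sec$ANGLES_INC_HYDROGEN),
                unpack4(sec$ANGLES_WITHOUT_HYDROGEN))
  angles <- if (is.null(aRaw)) {
    data.frame(i = integer(), j = integer(), k = integer(),
               ka = numeric(), theta0 = numeric())
  } else data.frame(i = as.integer(aRaw$i), j = as.integer(aRaw$j),
                    k = as.integer(aRaw$k),
                    ka = sec$ANGLE_FORCE_CONSTANT[aRaw$t],
                    theta0 = sec$ANGLE_EQUIL_VALUE[aRaw$t] / DEG)

  dRawV <- c(sec$DIHEDRALS_INC_HYDROGEN, sec$DIHEDRALS_WITHOUT_HYDROGEN)
  if (length(dRawV)) {
    m <- matrix(dRawV, ncol = 5, byrow = TRUE)
    scee <- if (!is.null(sec$SCEE_SCALE_FACTOR)) sec$SCEE_SCALE_FACTOR[m[, 5]]
      else rep(1.2, nrow(m))
    scnb <- if (!is.null(sec$SCNB_SCALE_FACTOR)) sec$SCNB_SCALE_FACTOR[m[, 5]]
      else rep(2.0, nrow(m))
    torsions <- data.frame(
      i = as.integer(m[, 1] / 3 + 1L), j = as.integer(m[, 2] / 3 + 1L),
      k = as.integer(abs(m[, 3]) / 3 + 1L),
      l = as.integer(abs(m[, 4]) / 3 + 1L),
      vn = sec$DIHEDRAL_FORCE_CONSTANT[m[, 5]],
      n = as.integer(round(sec$DIHEDRAL_PERIODICITY[m[, 5]])),
      gamma = sec$DIHEDRAL_PHASE[m[, 5]] / DEG,
      scee = scee, scnb = scnb,
      improper = m[, 4] < 0)
  } else {
    torsions <- data.frame(i = integer(), j = integer(), k = integer(),
                           l = integer(), vn = numeric(), n = integer(),
                           gamma = numeric(), scee = numeric(),
                           scnb = numeric(), improper = logical())
  }
  ## drop zero-amplitude placeholder components unless they are the only
  ## component of their quadruple
  moleculeTopology(atoms, bonds, angles, torsions)
}
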