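#' @import methods
#' @importFrom stats optim hclust cutree dist sd setNames
#' @importFrom utils head tail write.table read.table
NULL

## Central data containers. Atom indices are 1-based everywhere inside R;
## file formats that use other conventions convert at the I/O boundary.

#' MoleculeTopology: an AMBER-style molecular mechanics topology
#'
#' Holds everything needed to evaluate the gas-phase AMBER potential:
#' per-atom charges, masses and Lennard-Jones parameters, harmonic bond and
#' angle terms, Fourier dihedral terms with per-term 1-4 scaling divisors
#' (scee, scnb), and the derived nonbonded pair classification (1-2/1-3
#' excluded, 1-4 scaled, all further pairs full strength).
#'
#' @slot atoms data.frame with columns `name`, `element`, `type`, `charge`
#'   (elementary charges), `mass` (amu), `rminHalf` (Angstrom),
#'   `epsilon` (kcal/mol).
#' @slot bonds data.frame with columns `i`, `j`, `kb` (kcal/mol/A^2),
#'   `l0` (Angstrom), `order` (bond order, used only by the fragmenter).
#' @slot angles data.frame with columns `i`, `j`, `k`, `ka` (kcal/mol/rad^2),
#'   `theta0` (degrees).
#' @slot torsions data.frame, one row per Fourier component, with columns
#'   `i`, `j`, `k`, `l`, `vn` (kcal/mol), `n` (periodicity), `gamma`
#'   (degrees), `scee`, `scnb`, `improper` (logical), `calc14` (logical:
#'   this component owns the quadruple's 1-4 pair).
#' @slot pairs14 data.frame with columns `i`, `j`, `scee`, `scnb`.
#' @slot excluded data.frame with columns `i`, `j` (1-2 and 1-3 pairs).
#' @slot nbPairs data.frame of all unordered atom pairs subject to nonbonded
#'   interaction, with columns `i`, `j`, `scee`, `scnb` (1 for full pairs).
#' @export
setClass("MoleculeTopology",
  representation(atoms = "data.frame", bonds = "data.frame",
                 angles = "data.frame", torsions = "data.frame",
                 pairs14 = "data.frame", excluded = "data.frame",
                 nbPairs = "data.frame"))

setValidity("MoleculeTopology", function(object) {
  msgs <- character()
  at <- object@atoms
  if (nrow(at) == 0L) msgs <- c(msgs, "topology has no atoms")
  if (any(at$epsilon < 0)) msgs <- c(msgs, "lj epsilon must be >= 0")
  if (any(at$rminHalf < 0)) msgs <- c(msgs, "lj rmin/2 must be >= 0")
  bd <- object@bonds
  if (nrow(bd)) {
    if (any(bd$i == bd$j)) msgs <- c(msgs, "bond with identical atoms")
    if (any(bd$kb <= 0) || any(bd$l0 <= 0))
      msgs <- c(msgs, "bond kb and l0 must be positive")
  }
  an <- object@angles
  if (nrow(an) && (any(an$ka <= 0) || any(an$theta0 <= 0) ||
                   any(an$theta0 > 180)))
    msgs <- c(msgs, "angle ka must be > 0 and 0 < theta0 <= 180")
  to <- object@torsions
  if (nrow(to)) {
    if (any(to$n < 1 | to$n > 6))
      msgs <- c(msgs, "torsion periodicity must lie in 1..6")
    if (any(to$scee <= 0) || any(to$scnb <= 0))
      msgs <- c(msgs, "scee and scnb must be positive")
    key <- paste(to$i, to$j, to$k, to$l, to$improper)
    if (any(vapply(split(to$n, key), anyDuplicated, 0L) > 0L))
      msgs <- c(msgs, "duplicate periodicity within one torsion term")
  }
  idx <- unlist(list(bd$i, bd$j, an$i, an$j, an$k, to$i, to$j, to$k, to$l))
  if (length(idx) && (any(idx < 1L) || any(idx > nrow(at))))
    msgs <- c(msgs, "term refers to atom index outside topology")
  if (length(msgs)) msgs else TRUE
})

#' ConformerEnsemble: a set of conformations of one topology
#'
#' @slot conformations list of N x 3 coordinate matrices (Angstrom).
#' @slot energies numeric, kcal/mol (NA until minimized).
#' @slot backend character tag of the generating/minimizing backend.
#' @slot seed integer generation seed.
#' @export
setClass("ConformerEnsemble",
  representation(conformations = "list", energies = "numeric",
                 backend = "character", seed = "integer"))

setValidity("ConformerEnsemble", function(object) {
  n <- length(object@conformations)
  if (n == 0L) return("ensemble is empty")
  nat <- vapply(object@conformations, nrow, 0L)
  if (length(unique(nat)) != 1L) return("conformations differ in atom count")
  if (length(object@energies) != n) return("energies length mismatch")
  TRUE
})

#' CentroidSet: representative conformers with relative energies and weights
#'
#' @slot conformations list of N x 3 coordinate matrices.
#' @slot deltaE numeric relative energies E_k - E_min (kcal/mol, min is 0).
#' @slot weights numeric Boltzmann weights (sum to 1).
#' @slot ids integer ids of the centroids (stable across filtering).
#' @export
setClass("CentroidSet",
  representation(conformations = "list", deltaE = "numeric",
                 weights = "numeric", ids = "integer"))

setValidity("CentroidSet", function(object) {
  k <- length(object@conformations)
  if (k == 0L) return("centroid set is empty")
  if (length(object@deltaE) != k) return("deltaE length mismatch")
  if (abs(min(object@deltaE)) > 1e-9) return("min deltaE must be 0")
  if (length(object@weights) != k) return("weights length mismatch")
  if (abs(sum(object@weights) - 1) > 1e-8) return("weights must sum to 1")
  TRUE
})

#' ScanGrid: uniform dihedral grid over a full rotation
#'
#' @slot spacing degrees between consecutive points (must divide 360).
#' @slot angles ordered angles in (-180, 180].
#' @export
setClass("ScanGrid",
  representation(spacing = "numeric", angles = "numeric"))

setValidity("ScanGrid", function(object) {
  if (length(object@angles) * object@spacing != 360)
    return("grid does not cover a full rotation")
  TRUE
})

#' ScanProfile: a torsional energy profile on a scan grid
#'
#' @slot key list TorsionKey (quad, bond, typeQuad, depth).
#' @slot grid ScanGrid.
#' @slot energies numeric relative energies, minimum shifted to 0 (kcal/mol).
#' @slot geometries list of per-point coordinate matrices (may be empty for
#'   tabulated profiles).
#' @slot backend character backend tag.
#' @slot centroid integer id of the originating centroid (NA if none).
#' @slot degraded logical: TRUE when any point failed and was interpolated.
#' @export
setClass("ScanProfile",
  representation(key = "list", grid = "ScanGrid", energies = "numeric",
                 geometries = "list", backend = "character",
                 centroid = "integer", degraded = "logical"))

setValidity("ScanProfile", function(object) {
  if (length(object@energies) != length(object@grid@angles))
    return("energies/grid length mismatch")
  if (length(object@energies) && abs(min(object@energies)) > 1e-9)
    return("profile energies must be shifted to min 0")
  TRUE
})

#' FragmentSpec: a capped sub-molecule serving one torsion region
#'
#' @slot topology MoleculeTopology of the fragment (caps parameterized from a
#'   generic sp3 table).
#' @slot conformation N x 3 seed coordinates inherited from the parent.
#' @slot map list with `pairs` (two-column matrix fragment index, parent
#'   index) and `caps` (fragment indices of cap atoms).
#' @slot cleaved data.frame of parent bonds that were severed.
#' @slot region list of torsion keys (parent indexing) the fragment serves.
#' @export
setClass("FragmentSpec",
  representation(topology = "MoleculeTopology", conformation = "matrix",
                 map = "list", cleaved = "data.frame", region = "list"))

#' FitResult: outcome of fitting one torsion's Fourier components
#'
#' @slot key list TorsionKey of the fitted torsion.
#' @slot components data.frame of fitted components (`vn`, `n`, `gamma`,
#'   `scee`, `scnb`), pruned of negligible amplitudes.
#' @slot rmseInitial,rmseFinal numeric profile RMSE vs the reference
#'   (kcal/mol) before and after fitting.
#' @slot cycles integer outer cycles run.
#' @slot converged logical.
#' @slot trace numeric per-cycle profile RMSD change.
#' @export
setClass("FitResult",
  representation(key = "list", components = "data.frame",
                 rmseInitial = "numeric", rmseFinal = "numeric",
                 cycles = "integer", converged = "logical",
                 trace = "numeric"))

## ---- show methods -------------------------------------------------------

setMethod("show", "MoleculeTopology", function(object) {
  cat(sprintf(
    "MoleculeTopology: %d atoms, %d bonds, %d angles, %d torsion components (%d improper)\n",
    nrow(object@atoms), nrow(object@bonds), nrow(object@angles),
    nrow(object@torsions), sum(object@torsions$improper)))
  cat(sprintf("  1-4 pairs: %d, excluded pairs: %d, total charge: %+.4f e\n",
              nrow(object@pairs14), nrow(object@excluded),
              sum(object@atoms$charge)))
})

setMethod("show", "ConformerEnsemble", function(object) {
  cat(sprintf("ConformerEnsemble: %d conformers of %d atoms (backend '%s')\n",
              length(object@conformations),
              nrow(object@conformations[[1]]), object@backend))
})

setMethod("show", "CentroidSet", function(object) {
  cat(sprintf("CentroidSet: %d centroids, deltaE range [0, %.3f] kcal/mol\n",
              length(object@conformations), max(object@deltaE)))
})

setMethod("show", "ScanProfile", function(object) {
  cat(sprintf(
    "ScanProfile: %s over %d points (spacing %g deg), backend '%s'%s\n",
    paste(object@key$quad, collapse = "-"), length(object@energies),
    object@grid@spacing, object@backend,
    if (isTRUE(object@degraded)) ", DEGRADED" else ""))
})

setMethod("show", "FitResult", function(object) {
  cat(sprintf(
    "FitResult: %s, RMSE %.4f -> %.4f kcal/mol in %d cycle(s)%s\n",
    paste(object@key$quad, collapse = "-"), object@rmseInitial,
    object@rmseFinal, object@cycles,
    if (object@converged) "" else " (NOT converged)"))
})

## ---- accessors ----------------------------------------------------------

#' Accessors for torsionsmith classes
#'
#' Small read-only accessors for the package's S4 containers.
#'
#' @param x the object.
#' @return the requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
atoms <- function(x) x@atoms

#' @rdname accessors
#' @export
bonds <- function(x) x@bonds

#' @rdname accessors
#' @export
torsions <- function(x) x@torsions

#' @rdname accessors
#' @export
conformations <- function(x) x@conformations

#' @rdname accessors
#' @export
energies <- function(x) x@energies

#' @rdname accessors
#' @export
deltaE <- function(x) x@deltaE

#' @rdname accessors
#' @export
weights <- function(x) x@weights

#' @rdname accessors
#' @export
gridAngles <- function(x) x@grid@angles

#' @rdname accessors
#' @export
profileEnergies <- function(x) x@energies

#' @rdname accessors
#' @export
atomMap <- function(x) x@map

#' @rdname accessors
#' @export
fragmentTopology <- function(x) x@topology

#' @rdname accessors
#' @export
fittedComponents <- function(x) x@components
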