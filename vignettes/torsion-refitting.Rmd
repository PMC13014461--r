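---
title: "Refitting small-molecule torsion parameters: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Refitting small-molecule torsion parameters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the potential and its conventions, the selection and fitting procedures,
the tunable parameters and why their defaults are what they are, what the
synthetic fixtures do and do not emulate, and the numerical choices made
where the design was genuinely open.

## The potential and its conventions

`torsionsmith` evaluates the classical AMBER gas-phase potential: harmonic
bonds `k_b (l - l0)^2` and angles `k_a (theta - theta0)^2`, dihedrals as a
Fourier series `sum_n V_n/2 [1 + cos(n omega - gamma_n)]`, and pairwise
Lennard-Jones plus Coulomb terms over all atom pairs not excluded by the
topology. Conventions that the literature leaves implicit are pinned down
as follows:

* **Coulomb prefactor** fixed at 332.0522173 kcal·Å/(mol·e²), the AMBER
  ecosystem's value, so energies are bit-comparable with AMBER tools.
  The vacuum permittivity never appears explicitly.
* **Combining rules**: Lorentz–Berthelot as AMBER applies them,
  `r_min,ij = r_min,i/2 + r_min,j/2` and `eps_ij = sqrt(eps_i eps_j)`.
* **Exclusions**: 1–2 and 1–3 pairs excluded; 1–4 pairs scaled by the
  owning dihedral's `scee` (Coulomb divisor) and `scnb` (LJ divisor);
  1–5 and beyond at full strength. Pairs are classified once per topology
  by graph distance on the bond network, which automatically handles the
  ring double-counting problem.
* **Dihedral sign**: IUPAC convention — cis is 0°, angles in (−180°, 180°],
  and a quadruple read backwards gives the same angle.
* **Impropers** are evaluated identically to propers (AMBER convention)
  and never enter fitting.
* No cutoffs, no periodic boundary conditions, no Ewald summation: every
  system treated here is a single gas-phase molecule, and all-pairs
  evaluation is both exact and affordable at that size.

Gradients of every term are analytic. The dihedral gradient uses the
standard rigid-rotor formulas and is validated against central finite
differences (relative agreement better than 1e-6 at step 1e-5 Å) across
seeded random topologies. Minimization is Cartesian L-BFGS-B with
convergence on the maximum gradient component (default 1e-4 kcal/mol/Å);
constrained internal-coordinate machinery would buy nothing at these
system sizes, and the dihedral restraint below provides the same contract
— a constrained local minimum — with far less machinery.

## The dihedral restraint

Scans enforce the target dihedral with a flat-bottom harmonic restraint:
zero penalty while the wrapped deviation is within the tolerance, then
`k (|delta| - tol)^2` with delta in radians. Defaults: k = 500
kcal/mol/rad² with a ±0.5° tolerance band — stiff enough that every scan
point sits within the band plus a small slack (the suite asserts ≤ 2.5°
everywhere), soft enough not to distort the minimization. Angular
deviations are always wrapped to (−180°, 180°] before evaluation; the
restraint works in radians internally and degrees at the API boundary.

## Conformers, centroids, weights

The ensemble stage exists to answer one question: which dihedrals actually
move across the molecule's low-energy conformations? The default
generation backend randomizes every rotatable dihedral from the input 3D
geometry (seeded, hence reproducible), then each conformer is energy
minimized. Distance-geometry embedding is the natural default in
toolkit-rich environments; here the inputs always carry a chemically
sensible 3D structure, and torsion-space sampling from it reaches the same
rotameric diversity for the molecule sizes the workflow targets. The
backend is pluggable (`fixture` passthrough or any user function) for
anything the default does not cover.

Clustering represents each conformer by two features — heavy-atom RMSD to
the lowest-energy conformer after Kabsch superposition, and its relative
energy — L2-normalizes each feature column (a unit-free way to combine Å
with kcal/mol), and applies Ward hierarchical clustering on Euclidean
distances. Two details are deliberate:

* **Dendrogram cut.** No principled cluster count exists for this problem,
  so the tree is cut at a configurable fraction of the maximum merge
  height (default 0.25), bounded by 1 and `min(K, 10)` clusters. The cut
  is logged and overridable; the downstream stages are insensitive to
  modest changes because every centroid seeds its own scan and only the
  smoothest profile survives.
* **Degenerate features.** An all-zero feature column (all energies equal,
  say) is left as zeros rather than divided by zero, so clustering
  degrades gracefully to the other feature.

Each cluster's lowest-energy member is its centroid; centroids above a
relative-energy window (default 3.5 kcal/mol, boundary inclusive — "keep
low-energy" reads as keep-at-threshold) are discarded, and the minimum is
always retained. Boltzmann weights over the surviving centroids use
`w_k ∝ exp(-ΔE_k / k_B T)` with k_B = 0.0019872041 kcal/mol/K and
T = 298 K by default; the same weights drive the conformer-averaged
charges.

## Significant torsions

Candidates are all bonded paths i–j–k–l. A torsion is *significant* when
its wrapped dihedral dispersion across the centroid set — the maximum
pairwise `|((a-b+180) mod 360) - 180|` — strictly exceeds the cutoff
(default 30°; "exceeds" read strictly, so a dispersion of exactly 30°
does not qualify). Survivors are pruned:

* **Terminal torsions** (an end atom is hydrogen or a heavy atom with one
  heavy neighbor) are dropped by default: their large dispersions are
  quasi-free rotations, not fitting targets. Configurable.
* **Ring torsions** are dropped when all four atoms are ring members or
  when the central bond itself lies in a ring — a ring bond is never
  rotatable, so fitting it is meaningless. Ring membership comes from
  bridge detection on the bond graph (an edge is in a ring iff it is not
  a bridge), which is equivalent to smallest-ring membership for this
  purpose and independent of ring size. Note the consequence: a
  biphenyl-like inter-ring torsion, whose four atoms all sit in (two
  different) rings, is excluded by the all-atoms rule even though its
  central bond rotates.
* **Per-bond deduplication** keeps, among torsions sharing a central bond,
  the most backbone-like: the one whose end atoms lie deepest in the
  heavy-atom framework, measured as the minimum graph distance from an end
  atom to the nearest terminal heavy atom. The literature names the
  concept without a formula; this depth is our documented stand-in. Ties
  break on the lower canonical key, so output never depends on input
  order.

The longest heavy-atom chain (exhaustive longest simple path with a
lexicographic tie rule — exact, affordable below ~25 heavy atoms)
identifies *backbone-connected* torsions, which in turn inform the
fragmentation decision.

## Fragmentation

Significant torsions partition into *regions* — connected components of
their central bonds under shared-atom adjacency. Fragmentation triggers
when there are at least two regions, or when the molecule exceeds 35 heavy
atoms and a region is localized to less than half of them (the size
threshold is ours; the criteria the workflow needs are stated in the
literature only as existing). Cleavage sites must be acyclic single bonds
outside the region's atoms, at least two bonds from every member torsion's
central bond, not incident to a ring atom bearing an exocyclic double
bond, and not inside a protected functional group. The protected groups
(amide, ester, sulfonamide, nitro, carboxylate, guanidinium) are matched
by named structural rules on the element/bond-order graph; the rule list
is configurable by name. Severed neighbors become methyl caps — a carbon
along the severed bond vector at 1.526 Å completed with three tetrahedral
hydrogens at 1.09 Å, carrying generic sp3 parameters and a net-zero cap
charge. The fragment is only ever used to scan and fit its own region's
torsions, whose full 1–4 environment it preserves; atom maps (JSON,
0-based on disk, bijective on non-cap atoms) route fitted parameters back
to the parent types.

## Scans and profile selection

Each significant torsion is scanned over a uniform grid (default 20°,
18 points) starting from the grid point nearest the starting geometry's
dihedral and proceeding sequentially around the circle, every point seeded
from its predecessor — standard torsion-drive practice that minimizes the
discontinuities the smoothness score exists to catch. Profile energies are
the plain MM energies at the restrained geometries, shifted so the minimum
is zero (zeroing at the first point would make the profile depend on the
scan's entry point). A failed point is linearly interpolated from its
circular neighbors and the profile marked degraded.

Scans start from *every* centroid, and one profile per torsion survives, a
composite smoothness score deciding: the RMS residual of a least-squares
fit to a Fourier basis of order 4, plus 0.5 × the largest circular jump of
that residual, plus 0.5 × the RMS circular second difference of the
residual. Computing the jump and curvature terms on the residual (not the
raw energies) makes a genuinely smooth, in-basis profile score exactly
zero while spikes and high-frequency jaggedness are penalized; all three
components scale linearly with energy, so the ranking is scale-invariant.
The weights and the order are package choices, exposed as arguments.
Degraded profiles lose all ties; remaining ties go to the lowest centroid
id.

## Fitting

The fitted object is one atom-type quadruple's Fourier components over a
fixed periodicity basis (default {1,2,3,4}; an amplitude driven to zero
retires a periodicity — this keeps the "periodicity adjustment"
differentiable instead of an integer search), optionally together with
that type's `scee`/`scnb`. Every torsion instance sharing the type moves
together, which is exactly the semantics of a `frcmod` edit. Granularity
of the 1–4 scaling is per type, matching how the divisors are stored.

The objective is the sum of squared differences between the MM and
reference profiles after mean-centering both — centering eliminates the
arbitrary energy offset analytically and keeps the objective smooth, and
it is invariant to any constant added to either profile. On frozen
geometries the model is linear in `(V_n/2 cos gamma_n, V_n/2 sin gamma_n)`,
so the full-mode inner fit warm-starts from that exact linear solution and
lets bounded L-BFGS-B polish within the boxes
`V ∈ [0, 20]`, `gamma ∈ [0°, 360°)`, `scee ∈ [0.5, 3]`,
`scnb ∈ [0.5, 4]` (negative amplitudes are expressed as a 180° phase
shift instead). Gradients of the objective are analytic and
finite-difference-verified. The optimizer's initial step scale defaults to
0.05; it is exposed in `fitSpec()` but not load-bearing for correctness.

Geometry handling is the one genuinely open design point: whether scan
geometries relax inside the optimization loop. The package resolves it
with an alternating scheme. Inner: fit on frozen geometries (seeded from
the reference profile's own scan geometries when available — reusing the
reference structures keeps both profiles on the same conformational
branch). Outer: re-relax every scan point under the updated parameters and
repeat until the MM profile changes by less than 0.001 kcal/mol RMSD
(default) or 10 cycles, closing with one more frozen-geometry fit on the
converged geometries so the reported parameters are optimal for the
geometries they are reported with. `maxOuter = 1` therefore degenerates to
a pure frozen-geometry least squares — which is exactly what the
linear-oracle equivalence test exercises. A fit that would end worse than
its starting point returns the initial parameters with a warning; fitted
components below 0.005 kcal/mol are pruned from the result.

`torsion_only` mode frees only the amplitudes; phases and 1–4 scaling are
bitwise untouched — a robust option when ligand-specific nonbonded tuning
is not wanted.

## Synthetic fixtures and what passing tests mean

All tests run on built-in united-atom fixtures with hand-specified,
physically plausible round-number parameters (they are not real GAFF2
values, and do not need to be): an alkane chain whose central rotor is
butane-like, a biphenyl-like ring pair, an amide-interrupted chain, a
two-region molecule, a rigid ring, and a zero-background four-atom probe
for clean recovery experiments. Reference data come either from closed-form
Fourier profiles (optionally with seeded Gaussian noise) or from a *mock
reference backend*: the same MM engine run under a seeded perturbation of
the torsion amplitudes, so end-to-end recovery has an exactly known ground
truth.

What this establishes: the machinery — selection, scanning, smoothness
ranking, fitting, merging, file round trips — is correct and deterministic
wherever an independent oracle exists. What it does not establish: that
fitted parameters reproduce quantum-chemical torsion profiles of real
drug-like molecules. The fixtures have no electronic structure; a real
application must supply reference profiles from a quantum backend (the
scan-backend interface and the tabulated two-column profile format exist
precisely so such references can be plugged in or read from disk).

## Problem sizes and determinism

The shipped test suite and the acceptance script run entirely on the
fixtures: 20 random 6-atom topologies for the oracle checks, 18-point
scans, ensembles of 6–40 conformers, and molecules of 4–16 atoms. These
sizes make every oracle exhaustive (all-partition Ward checks, brute-force
path enumeration, double-loop energies) while keeping full runs in
seconds. Every stochastic step — conformer generation, noise, mock
perturbations, optimizer jitter — draws from an explicit seed through one
RNG-scoping helper, and repeated full pipeline runs with the same
configuration produce byte-identical `frcmod` files; that property is
asserted, not assumed.

## Known limitations

* Bond, angle, LJ and charge parameters are consumed, never fitted; charge
  *computation* (AM1-BCC and relatives) is out of scope — per-conformer
  charge sets are inputs, and only their Boltzmann average is formed.
* No periodic systems, no cutoffs: the engine is for single gas-phase
  molecules.
* The longest-path and region machinery is exact but exponential in the
  worst case; it is intended for drug-like sizes, not polymers.
* Macrocycle-aware ring handling is not attempted; ring torsions are
  excluded wholesale.
* GROMACS/CHARMM export and force-field library (`.lib`) emission are not
  implemented; the outputs are `frcmod`, a `parmed` script, `mol2`, and
  JSON atom maps.
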