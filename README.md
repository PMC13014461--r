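# torsionsmith

Ligand-specific torsion reparameterization for AMBER/GAFF2-style force
fields, in R.

Generic small-molecule force fields assign dihedral parameters by atom
type, and for any particular ligand the assigned Fourier terms can misplace
barriers, minima and phases of the torsional potential — errors that
propagate directly into conformational ensembles and binding free-energy
estimates. The standard remedy is ligand-specific refitting: drive each
chemically important dihedral through a full rotation with restrained
minimizations, compare the molecular-mechanics profile against a reference
profile, and re-solve for the Fourier coefficients. `torsionsmith`
implements that workflow end to end for users who prepare AMBER topologies
of small molecules: computational chemists running free-energy campaigns,
and method developers who need a transparent, fully scriptable fitting
engine with every intermediate inspectable.

## The model

The package evaluates the gas-phase AMBER potential

```
E = Σ_bonds k_b (l − l₀)²
  + Σ_angles k_a (θ − θ₀)²
  + Σ_dihedrals Σ_n (V_n / 2) [1 + cos(n ω − γ_n)]
  + Σ_{i<j} { ε_ij [ (r_min,ij / r_ij)¹² − 2 (r_min,ij / r_ij)⁶ ] / s_ij^LJ
            + k_C q_i q_j / (s_ij^C r_ij) }
```

with 1–2 and 1–3 pairs excluded, 1–4 pairs divided by the owning
dihedral's `scnb` (Lennard-Jones) and `scee` (Coulomb) factors, all more
distant pairs at full strength, and k_C = 332.0522173 kcal·Å/(mol·e²).
Gradients are analytic, so restrained minimizations and the fitting
objective are exact to machine precision.

The object being fitted is the Fourier torsion term (V_n, n, γ_n) of one
atom-type quadruple — optionally together with that type's `scee`/`scnb` —
minimizing the mean-centered sum of squared differences between the MM
torsional profile and a reference profile on a uniform dihedral grid
(default 20°, 18 points over 360°), by bounded quasi-Newton (L-BFGS-B)
warm-started from the exact linear solution in the cos/sin
parameterization.

The workflow around the fit:

1. generate a conformer ensemble (seeded torsion-space sampling or a
   pluggable backend) and minimize it;
2. cluster conformers by (heavy-atom RMSD to the minimum, relative energy),
   both features L2-normalized, with Ward linkage; keep each cluster's
   lowest-energy member; drop centroids above a 3.5 kcal/mol window;
3. flag *significant torsions*: wrapped dihedral dispersion across
   centroids above 30°, then prune terminal, ring, and per-bond duplicate
   definitions (most backbone-like wins);
4. optionally fragment the molecule around connected torsion regions,
   cleaving distal acyclic single bonds (never rings or protected
   functional groups) and capping with methyls, with JSON atom maps;
5. run 360° restrained scans (force constant 500 kcal/mol/rad², ±0.5°
   flat bottom) from every centroid and keep the smoothest profile per
   torsion (composite of Fourier residual, residual jumps, residual
   curvature);
6. fit each torsion and emit `frcmod`, a `parmed` update script, `mol2`,
   and the atom maps.

## Worked example

Fit the central rotor of a butane-like alkane fixture against a seeded
"mock reference" backend whose torsion parameters are deliberately
perturbed — so the right answer is known exactly:

```r
library(torsionsmith)

fx <- makeFixture("butane_like")
fx$topology
#> MoleculeTopology: 6 atoms, 5 bonds, 4 angles, 3 torsion components (0 improper)
#>   1-4 pairs: 3, excluded pairs: 9, total charge: +0.0000 e

cfg <- runConfig(nConformers = 20, seed = 5, referenceBackend = "mock-qm")
report <- runPipeline(fx$topology, fx$conformation, cfg, "demo_run")
fi <- report$fits[[1]]
cat(sprintf("fitted torsion %s: RMSE %.4f -> %.2e kcal/mol in %d cycle(s)\n",
            fi$typeQuad, fi$rmseInitial, fi$rmseFinal, fi$cycles))
#> fitted torsion c3-c3-c3-c3: RMSE 0.0834 -> 1.99e-06 kcal/mol in 2 cycle(s)

cat(readLines("demo_run/step10_outputs/fitted.frcmod")[9:11], sep = "\n")
#> DIHE
#> c3-c3-c3-c3   1     0.05000     0.000     3.0    SCEE=1.2007 SCNB=2.0000
```

The profile RMSE against the reference drops from 0.083 kcal/mol (the
unfitted force field) to 2·10⁻⁶ kcal/mol, and the emitted `frcmod` line
carries the recovered barrier height (the mock backend's true V₃ for this
seed is 0.0500 kcal/mol). Every step of the run is persisted under
`demo_run/step01_…`–`step10_…` for inspection, and
`resumePipeline("demo_run", step)` recomputes from any step.

A thin CLI wraps the same functions:

```sh
inst/cli/torsionsmith run --topology lig.prmtop --molecule lig.mol2 \
    --config run.yaml --out run_dir/
inst/cli/torsionsmith report --out run_dir/
```

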