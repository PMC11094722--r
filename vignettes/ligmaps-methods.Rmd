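---
title: "Ligand-derived grid maps for virtual screening: models, parameters, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ligand-derived grid maps for virtual screening: models, parameters, design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ligmaps)
```

## The problem and the model

Ligand-based virtual screening ranks a compound library by similarity to
one or more known active ligands when no target structure is available.
`ligmaps` casts that similarity as *map fit*: the reference ligand, in its
bioactive conformation, is converted into volumetric grid maps, and each
library compound is ranked by the score of its best-fitting pose and
conformation inside those maps. The reference plays the role a receptor
plays in grid-based docking; the search machinery (precomputed grids,
trilinear interpolation, a Lamarckian genetic algorithm over pose and
torsion genes) is the standard docking machinery, but the fields are
derived from a ligand, not a protein.

### Affinity maps

One map per AutoDock atom type in the vocabulary
`r paste(ad_atom_types(), collapse = ", ")`. At each grid point a
*pseudosphere* of radius 1.54 Å (a carbon covalent diameter) is scanned
for reference atoms of the map's type. With members sorted by distance,
the pseudopotential accumulates as

$$E_0 = 0, \qquad E_n = E_{n-1} - \frac{1}{d_n},$$

so the stored value is $-\sum_n 1/\max(d_n, d_\min)$. The value is exactly
0 when the pseudosphere is empty, strictly negative otherwise, and grows
more negative when atoms of that type are **closer** or **more numerous**
— the two monotonicities the whole method rests on, both asserted as
randomized property tests. Affinity maps therefore contain no positive
values anywhere: a compound is rewarded where it overlays reference
features and merely *not rewarded* elsewhere, so a large library compound
is never penalized for extending beyond a small reference.

Atom types absent from the reference get all-zero *general* maps. They
carry no information but guarantee that a library compound containing,
say, chlorine can still be scored against a chlorine-free reference.

### Electrostatic map

The same pseudosphere, all atoms regardless of type:

$$e(\mathbf{r}) = \sum_n \frac{Q_n}{\varepsilon\, d_n},$$

with Gasteiger partial charges $Q_n$ and the constant dielectric factor
$\varepsilon = -0.1465$ (the conventional grid-docking default). A pose
atom contributes $q_i \cdot e(\mathbf{r}_i)$, so with the negative
$\varepsilon$, like-charge overlap of a pose atom with reference charges
is rewarded (negative contribution) and opposite-charge overlap penalized
— the reference's own charge pattern is the template being matched.

### Scoring, search, similarity

A pose scores the sum of per-atom trilinear map lookups; atoms outside
the box add a fixed penalty (default 1000) rather than aborting, so the
search can recover from boundary violations. The score contains *only*
these intermolecular grid terms: no intramolecular energy, no torsional
entropy, no desolvation. Normalization by the reference self-score
cancels any constant offset such terms would add.

Each compound is screened with `n_runs` independent LGA runs; each run
evolves a population of genomes — centroid translation (Å), rigid
orientation (unit quaternion), one torsion increment per rotatable bond —
through tournament selection, block crossover, Gaussian mutation, and a
Solis–Wets local search applied to the current best individuals whose
accepted moves are written back into the genome (the Lamarckian step,
with adaptive step scaling and directional bias). The best score across
runs is $S_\text{init}$, and

$$S_\text{sim} = \frac{S_\text{init}}{\sum_r S_\text{ref}^{(r)}}.$$

$S_\text{ref}$ is the reference scored against its own maps. Two modes
are provided because the ceiling can be defined two ways: `"fixed"`
(default) scores the reference's input coordinates — deterministic, makes
the reference's own similarity exactly 1, and makes unit tests exact —
while `"selfdock"` self-docks the reference with the same stochastic
search a library compound gets, mirroring a production screen. The
self-docked score can come out slightly *deeper* than the fixed pose
(the interpolated field between grid nodes can exceed the input pose's
value), which is why similarities are reported unclamped with a flag
whenever they leave $[0, 1]$, never silently truncated.

In multi-reference mode, pre-aligned references are concatenated without
re-alignment (alignment is an input requirement — the package validates
centroid spread and warns, but never aligns). Near-coincident atoms of
one type are deliberately kept: by count monotonicity they deepen the map
exactly where references agree, which is the pharmacophore-amplification
effect the composite exists for. The similarity denominator is the sum of
per-constituent self-scores against the composite maps.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| grid spacing | 0.375 | Å | conventional grid-docking default; halving it quadruples map memory for little ranking gain |
| pseudosphere radius | 1.54 | Å | carbon covalent diameter; the support of every map feature |
| distance clamp `d_min` | 0.01 | Å | caps $1/d$ when a grid node coincides with an atom |
| dielectric $\varepsilon$ | −0.1465 | — | conventional electrostatic grid factor; sign sets the charge-matching convention |
| out-of-box penalty | 1000 | score | dominates any attainable map gain at desk scale while leaving the search a finite gradient back into the box |
| `n_runs` | 5 | — | desk-scale default; 100 is the conventional full-scale setting |
| population / generations / SW iterations | 50 / 40 / 40 | — | desk-scale LGA budget (~15k evaluations per run) |

Box dimensions are the per-axis maximum extent over reference and library,
rounded **up** to the nearest even integer (even dimensions are required
by the grid machinery; rounding up buys sampling headroom). Grid
intervals per axis are `npts = dims/spacing` rounded up to the nearest
even integer, guaranteeing the box is covered.

## Numerical choices

- **Sphere boundary:** atoms at exactly 1.54 Å are *included* (closed
  ball). A measure-zero choice, fixed for determinism.
- **Distance sorting:** stable sort by (distance, atom index), so maps are
  bit-reproducible whatever the atom order.
- **Trilinear interpolation** never extrapolates: out-of-box points
  signal the caller instead.
- **Kinematics order:** each torsion gene is a *dihedral increment* applied along the tree first, then rigid
  rotation about the post-torsion centroid, then translation. Translation
  is an absolute centroid displacement, so the identity genome reproduces
  the input conformation exactly; the initial population samples
  displacements that place the centroid uniformly inside the box.
- **Reproducibility:** per-run and per-compound seeds derive from the
  master seed by a counter scheme, so results are independent of
  evaluation order and identical across reruns; the screen is serial by
  construction, which makes scheduling irrelevant to results.
- **Degenerate inputs:** a reference whose self-score is not strictly
  negative is rejected (nothing to normalize by); single-atom molecules
  optimize translation only; empty libraries yield empty results; one
  corrupt SDF record or one failing compound is logged and skipped, never
  fatal.
- **Hot path:** pose kinematics and grid scoring are implemented in C++
  (Rcpp) for the search loop; the R-level `score_pose()`/`apply_genome()`
  are the reference implementations, and the suite asserts both paths
  agree to 1e-9.

## Ligand preparation

Charges, AutoDock atom types, nonpolar-hydrogen merging (with charge
transfer to the parent heavy atom, conserving net charge) and the torsion
tree are delegated to Open Babel (`obabel -opdbqt --partialcharge
gasteiger`), the tool a practitioner would use for this step; aromatic
carbons are typed `A` by its ring-aromaticity perception. Inputs are
assumed protonated at the intended pH — no protonation or tautomer logic
is attempted, and a molecule with no hydrogens at all triggers a warning
only. References are prepared rigid (all torsional freedom removed);
library compounds keep their torsion trees.

## What the synthetic benchmark does and does not show

`make_benchmark()` emulates an actives/decoys screen at desk scale:
actives are torsion-jittered, noise-perturbed conformers of the reference
(same topology, types, charges — jitter SD 0.3 rad, coordinate noise
0.05 Å), and decoys are random branched C/N/O molecules of matched
heavy-atom size with rough random 3D embeddings. Because actives share
the reference's exact feature geometry and decoys are topologically
random, the benchmark separates cleanly (AUROC ≈ 1 under default
settings); its purpose is to make regressions in map construction or
search quality visible, not to estimate screening accuracy on real
libraries. Real benchmark decoys are property-matched to actives and
real actives are *not* conformers of the reference, so real-data
AUROC/EF values are substantially lower and cannot be inferred from these
tests. The generator is deterministic under its seed, and its defaults
(5 actives, 50 decoys) keep a full screen within minutes on one CPU.

Problem sizes used by the test suite: a 13-atom (10 heavy) reference with
2 rotatable bonds; grids of roughly 23–29 nodes per axis; 55-compound
screens at the default search budget; 20-seed repetition for the
self-docking recovery check.

## Known limitations

- The score is a similarity, not an energy: no desolvation, no
  directional hydrogen bonding, no intramolecular strain. Self-overlapping
  conformers of highly flexible compounds are not penalized.
- Map quality is only as good as the reference conformation and its
  protonation; a non-bioactive reference conformation poisons every map.
- Multi-reference mode requires externally aligned inputs.
- Gasteiger charges are fast but crude; polarized systems (zwitterions,
  metals) are outside the supported atom-type vocabulary.
- The LGA defaults are sized for interactive use; production screens of
  large libraries should raise `n_runs` toward the conventional 100 and
  scale population/generations accordingly.
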