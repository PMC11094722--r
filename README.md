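# ligmaps

Ligand-based virtual screening (LBVS) with ligand-derived grid maps. When
no target structure is available but one or more active ligands are known,
`ligmaps` turns the reference ligand(s) — in their bioactive, protonated
conformations — into volumetric pseudopotential maps and ranks a compound
library by how well each compound's *optimized* 3D conformation fits those
maps. Unlike conformer-library approaches, every library compound is
treated as conformationally flexible: a Lamarckian genetic algorithm (LGA)
searches translation, rigid rotation and torsion genes against the maps,
so conformations are optimized toward the reference rather than
pre-enumerated. It is aimed at computational chemists running
early-stage hit finding or method prototyping in R.

## The method

**Grid box.** The box is centered on the reference centroid; each axis
dimension is the maximum axis-aligned extent over the reference and all
library compounds, rounded up to the nearest even integer (e.g. extents
(60.5, 49.5, 60.0) Å give a (62, 50, 60) Å box), with grid spacing 0.375 Å.

**Affinity maps.** For every AutoDock atom type *t* present in the
reference, each grid point gets a pseudopotential from the reference atoms
of type *t* inside its pseudosphere of radius 1.54 Å. With the members
sorted by distance d₁ ≤ d₂ ≤ …, the value accumulates as

    E₀ = 0,   Eₙ = Eₙ₋₁ − 1/dₙ,

i.e. E = −Σₙ 1/max(dₙ, 0.01). An empty pseudosphere gives exactly 0; the
value grows more negative as same-type atoms are closer or more numerous.
Types absent from the reference get all-zero *general* maps so any library
compound can be scored. There are no positive map values anywhere, which
keeps large library compounds from being penalized for outgrowing a small
reference.

**Electrostatic map.** At each grid point, e(r) = Σₙ Qₙ/(ε·dₙ) over all
atoms within 1.54 Å, with Gasteiger charges Qₙ and dielectric factor
ε = −0.1465.

**Scoring and search.** A pose scores
Σᵢ [ A_{tᵢ}(rᵢ) + qᵢ·e(rᵢ) ] by trilinear interpolation, with a fixed
penalty per atom outside the box. Each compound is screened with `n_runs`
independent LGA runs (selection, block crossover, Gaussian mutation, and a
Solis–Wets local search whose improvements are written back into the
genome); the lowest score across runs is S_init.

**Similarity.** The reference self-score S_ref (its own pose against its
own maps) is the theoretical ceiling of S_init, and

    S_sim = S_init / Σ S_ref

normalizes every compound into [0, 1] (1 = reference-like; values outside
the range are flagged, not clamped). With multiple pre-aligned references,
maps are built from their concatenated atoms — recurring atom positions
(pharmacophores) accumulate deeper pseudopotentials — and the denominator
sums the per-reference self-scores. Ranked screens are evaluated with
AUROC and the enrichment factor
EF_x% = (NA_top/N_top)/(NA_total/N_total).

## Worked example

```r
library(ligmaps)
library(dplyr)

ref   <- prepare_ligand(make_example_ligand())      # charges, types, torsion tree
bench <- make_benchmark(ref, n_actives = 5, n_decoys = 50, seed = 7)
lib   <- c(bench$actives, bench$decoys)

ms  <- build_mapset(ref, lib)                       # affinity + electrostatic maps
res <- screen_library(lib, ms, search_config(), seed = 71)
sim <- normalize_similarity(res, reference_score(ref, ms))

ranked <- screen_ranking(inner_join(tidy(sim), bench$labels, by = "compound"))
glance(ranked, ef_percent = c(1, 10))
#> # A tibble: 1 × 5
#>   n_total n_actives auroc  ef_1 ef_10
#>     <int>     <int> <dbl> <dbl> <dbl>
#> 1      55         5     1    11  9.17
```

The five actives are torsion-jittered conformers of the reference; all
five outrank every random decoy (AUROC 1), and the single top-1% pick is
an active (EF₁% = 11, the maximum 55/5 being unreachable with one pick).
`autoplot(ranked)` draws the ROC curve; `autoplot(ms$affinity[["A"]])`
shows a slice through the aromatic-carbon map.

A command-line front end with the same stages
(`prepare`, `make-maps`, `screen`, `normalize`, `evaluate`, `fixtures`,
`run`) is installed at `inst/cli/ligmaps`.

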