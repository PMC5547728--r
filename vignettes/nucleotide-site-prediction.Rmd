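---
title: "Template-based prediction of nucleotide binding sites: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Template-based prediction of nucleotide binding sites: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucsite)
```

## The problem

ATP, ADP and AMP bind proteins through a small number of contact residues, and
proteins with entirely different folds often arrange those residues in very
similar local geometries (the P-loop being the canonical example). `nucsite`
exploits this: instead of requiring a template protein with a similar overall
fold, it asks whether any *binding site* in a template library — just the
cloud of interacting atoms around a bound nucleotide — can be fitted onto a
local surface patch of the target. A site found this way immediately yields a
ligand placement, which an energy function can then vet.

The input is a protein structure with all non-hydrogen atom coordinates; the
output is a ranked list of predicted binding-site centers and a per-residue
binding score.

## The model

**Binding sites and templates.** A protein atom is an *interacting atom* of a
bound nucleotide if it lies within 3.9 Å of a non-hydrogen ligand atom; the
binding site is the set of interacting atoms of one ligand copy. A template
stores those atoms (coordinates plus their atom name and residue type), the
ligand atoms, the geometric ligand center, and two derived radii: `R`, the
maximal center-to-site-atom distance (the radius covering the whole site),
and `r`, the minimal one (the distance from the ligand center to the protein
surface).

**Grid screening.** Candidate ligand-center positions are lattice points
(2 Å spacing) in the solvent shell: more than 1.6 Å from every protein atom
and within 10 Å of at least one. A grid point `g` survives screening against
a template when:

1. *Surface distance*: `|r − r₁| ≤ 2 Å`, where `r₁` is the distance from `g`
   to the nearest protein atom. If the point sat at the true ligand center,
   its surface distance would be close to the template's `r`.
2. *Triangle matching*: triangles are formed by two site atoms plus the
   ligand center (template side) or two patch atoms plus `g` (target side),
   where the patch is every protein atom within `R + 2 Å` of `g`. A template
   triangle matches a patch triangle when both non-apex vertices agree in
   (atom name, residue type) and all three corresponding edge lengths agree
   within 2 Å. The point survives if the number of matched template
   triangles reaches `max(⌈0.25·T⌉, min(50, T))` of the `T` template
   triangles.

The triangle count threshold deserves a note. A literal floor of 50 matched
triangles is impossible for sites with fewer than 11 atoms (`T = n(n−1)/2 <
50`), so the floor is capped at `T`: small sites must then match *all* their
triangles, while for any site with 11+ atoms the familiar 50-triangle floor
is operative. The 25% fraction dominates once `T > 200`.

**Seeds.** Surviving grid points are clustered by single linkage with
lattice-neighbor adjacency (distance ≤ step). The three largest clusters are
kept (ties broken by the cluster centroid's distance to the protein surface,
then lexicographically), and each emits up to two seeds: the member nearest
the centroid and the member with the highest match count.

**Maximal common substructure.** For each seed, a correspondence graph is
built: vertices are (site atom, patch atom) pairs with equal (atom name,
residue type) keys; two vertices are adjacent when their intra-set distances
agree within 2 Å and they reuse neither atom. A clique of this graph is a
distance-consistent common substructure, and the maximum clique is found by
exhaustive backtracking with a branch-and-bound cut, vertices ordered by
degree. The search is exact unless a node-expansion budget (10⁶) is hit, in
which case the best clique found is used and flagged. Cliques smaller than 4
atoms are rejected: 3 points are the geometric minimum for a rigid fit, and
requiring one more atom suppresses spurious placements.

**Superposition and poses.** The clique's atom pairs are superposed by the
SVD-based least-squares rigid fit (with the determinant correction that
excludes reflections), and the template's ligand is mapped through the
fitted transform with its conformation unchanged. When several maximum
cliques exist, the one with the lowest fitted RMSD wins.

**Energy filter.** Each pose is scored against the whole target with an
AMBER-style nonbonded energy — Lennard-Jones plus Coulomb over
protein–ligand atom pairs within 12 Å:

E = Σᵢⱼ εᵢⱼ[(Rmin,ij/rᵢⱼ)¹² − 2(Rmin,ij/rᵢⱼ)⁶] + k·qᵢqⱼ/(εᵣ(r)·rᵢⱼ),

with εᵢⱼ = √(εᵢεⱼ), Rmin,ij = Rmin,i/2 + Rmin,j/2, and k = 332.0637
kcal·Å/(mol·e²). Poses with E ≥ 0 kcal/mol (not net-attractive, including
steric clashes) are discarded.

**Sites and residues.** Surviving pose centers are clustered by single
linkage with strict `< 4 Å` adjacency; clusters are ranked by member count
(ties by best member energy, then lexicographic center) and the top 5
reported, each represented by the mean of its member centers. Every target
residue is scored by the number of surviving poses it contacts at ≤ 3.9 Å —
a pose counts once regardless of how many atom contacts it makes — and a
binary binding call uses a strict `score > threshold` cut.

## Parameters

| key | default | unit | role |
|---|---|---|---|
| `grid.step` | 2 | Å | lattice spacing; also the grid-cluster adjacency distance |
| `grid.inner` / `grid.outer` | 1.6 / 10 | Å | solvent shell around the protein |
| `match.center_tol` | 2 | Å | allowed `|r − r₁|`; absorbs the lattice discretization |
| `match.edge_tol` | 2 | Å | triangle edge and correspondence-graph distance tolerance |
| `match.frac` / `match.min_triangles` | 0.25 / 50 | — | triangle-count pass threshold (floor capped at `T`) |
| `seeds.top_clusters` | 3 | — | grid clusters carried forward |
| `clique.min_size` | 4 | atoms | smallest acceptable common substructure |
| `clique.budget` | 10⁶ | expansions | exactness guarantee bound for the clique search |
| `energy.dielectric` | distance (εᵣ = 4r) | — | hydrogen-free rigid scoring default; `constant` available |
| `energy.cutoff` | 12 | Å | nonbonded pair cutoff |
| `energy.threshold` | 0 | kcal/mol | discard bound: keep net-attractive poses only |
| `sites.link_dist` | 4 | Å | strict pose-center linkage distance |
| `sites.top_n` | 5 | — | reported sites |
| `contact.cutoff` | 3.9 | Å | interacting-atom / binding-residue definition |

The energy model is deliberately minimal. The bundled parameter table
(`inst/extdata/nonbonded_params.tsv`) carries ff99-style Lennard-Jones
classes and *class-level group charges*: because hydrogens are dropped at
parse time, each heavy atom's charge folds in its hydrogens (Lys NZ(H₃)⁺ is
+0.55 e, a hydroxyl oxygen −0.21 e). These are not residue-specific RESP
charges; the energy backs a keep/discard filter and a ranking tie-break, not
free-energy estimates. Atoms without parameters fall back to element-level
defaults (ε = 0.1, Rmin/2 = 1.7, q = 0) with a warning, or error if the
fallback is disabled.

## Homology-filtered template selection

Template-based prediction is only honest if the library is not allowed to
contain the answer. `filter_library()` removes, for a given target, templates
in the same 40%-sequence-identity cluster (`identity40`) or sharing the
target's SCOP-style family / superfamily / fold label; at the homology levels
unlabeled templates are also removed, and the target's own structure is
always removed (jackknife). Sequence clustering and SCOP labels are consumed
as metadata (TSV: `structure_id`, `chain`, `cluster40`, `family`,
`superfamily`, `fold`) — the package does not compute them.

## Evaluation utilities

- `dcc_success()`: per native site, the minimal distance from its ligand
  center to the selected predictions (top *n* = the protein's native-site
  count, or top 5); a site counts as correctly predicted at cutoff `D` when
  that distance is ≤ `D` (we use ≤; results differ from a strict `<` only on
  measure-zero ties). Success rates are reported on a 0.5–10 Å grid.
- `residue_metrics()`: precision, recall and MCC from pooled binary calls;
  zero-denominator metrics report 0 with a flag. Aggregation across proteins
  is micro-averaged (counts pooled before the ratio).
- `match_operating_point()`: sweeps the integer score threshold to match a
  reference precision or recall — the smallest value at or above the
  reference when attainable, ties resolved to the higher (more conservative)
  threshold — so methods can be compared at an equal operating point.
- `capped_distance_pairs()`: paired per-site distances of two methods with
  everything beyond 10 Å rounded down to 10 (all far-off predictions are
  equally wrong), then a Wilcoxon signed-rank test (delegated to
  `stats::wilcox.test`); identical capped vectors are flagged degenerate
  instead of tested.

## The synthetic generator: what it does and does not establish

`make_complex()` builds a toy complex: an idealized rigid nucleotide
(polygon-based adenine and ribose rings, a 1–3 unit phosphate chain;
literature-ish bond lengths, not a crystallographic conformer) at a random
orientation, a contact shell of `n_shell_atoms` protein atoms placed
3.3–3.9 Å from the ligand, and a decoy cloud (6–16 Å from the ligand center,
≥ 4.5 Å from every ligand atom, no atom pair anywhere closer than 2.5 Å).
`make_planted_target()` copies a template's site atoms into a fresh decoy
cloud at a random rigid placement and records the transformed ligand center
and contact residues as ground truth; the target itself is apo.

Three generator choices emulate specific features of real sites:

- *Contact window 3.3–3.9 Å*: heavy-atom contacts in real structures sit
  near the van der Waals minimum. Sampling closer than ~3.3 Å would place
  atoms inside the repulsive wall, making the "native" complex score
  positive — something no real binder does.
- *Charge complementarity*: shell atoms anchored to a phosphate group draw
  from a donor/cation pool (Lys NZ, Arg NH, Ser/Thr OG, backbone N — a
  P-loop-like coordination); other shell atoms and all decoys draw from a
  neutral pool. Additionally every placed atom must be individually
  non-repulsive to the ligand under the bundled parameters.
- *Truncated noise*: site jitter (`noise_sigma`) redraws any displacement
  that would land an atom within 3.1 Å of the ligand, since structural
  variation between homologous sites does not create atomic overlaps.

Defaults — 12 shell atoms (66 template triangles, so the 50-triangle floor
is operative), 60 decoy atoms for complexes, 40/30 for targets, zero noise —
describe a small but non-trivial world. All randomness flows through one
explicit seed; identical seeds give byte-identical files.

What a green planted-site test establishes: the whole chain (grid, triangle
screen, clique, superposition, energy, clustering, scoring) recovers a site
whose geometry genuinely is in the library, at the 2 Å tolerance the grid
step implies, and loses it when the homology filter removes the matching
template. What it does not establish: performance on real structures —
conformational variation between remote homologs, crowded pockets, partial
occupancy, waters and cofactors are all absent from the toy world, and the
fixture shells are far more charge-ideal than real sites.

## Numerical choices

- All "within X Å" comparisons are inclusive (≤), with a 1e-9 Å guard on the
  screening and contact boundaries so exactly-constructed boundary cases are
  not lost to decimal floating-point representation. The pose-center
  clustering distance is strictly `<` with no guard, as its semantics demand
  a split at exactly 4.0 Å.
- PDB parsing keeps the first model of multi-model files and, per altloc
  group, the highest-occupancy conformer (ties by altloc letter). Waters,
  monoatomic ions and all hydrogens are removed. These policies are ours;
  they make parsing deterministic.
- Collinearity (second singular value < 1e-4 after centering) makes a rigid
  fit degenerate; such cliques are discarded with the pose rather than
  fitted.
- Every ordering that could tie is given a deterministic tie-break
  (documented on each function); two runs on identical inputs produce
  byte-identical output files.

## Known limitations

- The ligand conformation is always copied rigidly from the template; no
  flexible fitting or conformer generation.
- Atom typing is (PDB atom name, residue type) — the finest type available
  without a chemical perception engine; nonstandard residues fall back to
  element-level energy parameters.
- The clique search is worst-case exponential; the budget keeps it bounded
  but large, promiscuous patches may get a best-effort (flagged) answer.
- mmCIF input, hydrogen placement, protonation states and assembly
  generation are out of scope.
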