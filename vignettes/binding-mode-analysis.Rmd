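---
title: "Binding-mode analysis of protein-ligand MD trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Binding-mode analysis of protein-ligand MD trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bindmode)
library(dplyr)
```

## The problem

When a protein-ligand complex has no experimental structure, multi-replica
molecular dynamics started from analogous complexes can propose a binding
mode. The proposal is only as good as the analysis that condenses the
trajectories: which residues interact with the ligand and how often, what a
conserved pocket water does, which side-chain states the pocket visits, and
which single frame best represents the ensemble. `bindmode` implements that
analysis layer as composable, pipeable functions returning tibbles, with a
synthetic-trajectory generator that plants known truth for every stage.

The motivating system is the switch-II pocket (SII-P) of KRAS(G12C) bound by
covalent inhibitors: a cryptic pocket beneath the flexible switch-II region,
with a crystallographically recurrent water near Thr58/Gly10 and a
well-documented set of pocket residues (Lys16, Glu62, Glu63, Tyr64, Asp69,
His95, Tyr96). Nothing in the package is specific to KRAS, but defaults
(anchor residues 58 and 10, the key-residue thresholds) follow that use case.

## Interaction criteria

Each detector applies explicit geometric criteria per frame:

* **Hydrogen bond** — hydrogen-acceptor distance ≤ 2.5 Å; donor angle
  D–H···A ≥ 120°; acceptor angle H···A–X ≥ 90°, maximized over the
  acceptor's bonded heavy atoms X. Both donor directions are scanned.
  The distance criterion is deliberately read as **H···A**: a 2.5 Å cutoff
  on the donor-acceptor distance would reject nearly every real hydrogen
  bond (typical D–A separations are 2.8-3.2 Å), so the quoted 2.5 Å figure
  only makes sense against the hydrogen. The acceptor angle takes the
  maximum over X — the most permissive reading — because conventions differ
  between tools; both choices are configurable in `interaction_criteria()`.
* **Water bridge** — one water simultaneously satisfying the hydrogen-bond
  geometry to a protein residue and to a ligand atom, at 2.8 Å / ≥ 110° /
  ≥ 90°. Only single-water bridges are counted: the stated criterion is a
  single distance/angle set, which does not define a two-water chain.
* **π–π** — ring-centroid distance ≤ 4.4 Å with folded interplanar angle
  ≤ 30° (face-to-face), or ≤ 5.5 Å with the angle in 60-120°
  (edge-to-face). These two distance thresholds are not part of the quoted
  criteria anywhere; 4.4/5.5 Å with a 30° plane tolerance are conventional
  stacking ranges and fully configurable. Ring normals come from the SVD of
  the centered ring coordinates and are sign-ambiguous, hence the folding of
  the interplanar angle into [0°, 90°].
* **π–cation** — charged-group centroid to ring centroid ≤ 4.5 Å.
* **Hydrophobic / ionic** — nonpolar carbon pairs ≤ 3.6 Å (one event per
  residue per frame); oppositely charged groups with closest atoms ≤ 3.7 Å.
  These two thresholds are common fingerprinting defaults.

Distances honor the periodic box via the minimum-image convention (exact for
triclinic cells: fractional wrapping followed by a 27-image search); angles
use the unwrapped coordinates, assuming molecules are whole. Hydrogens are
required on donors — a topology without polar hydrogens is rejected for
hydrogen-bond analysis rather than silently rebuilt, because adding hydrogens
is a system-preparation step outside this package's scope.

**Aggregation.** Fractions are per (residue, type): the number of analyzed
frames, pooled equally over replicas, with at least one event of that type,
divided by the total frames analyzed. Multiple same-type contacts in one
frame count once; totals over types may exceed 1. Totals > 0.2 flag a
residue *displayed*, > 0.5 *key* (strict inequalities).

## Water site, states, representative frame

The conserved-water site is a sphere (default radius 3 Å, configurable)
around the unweighted centroid of anchor atoms recomputed every frame, so
the site moves with the protein. Anchors default to the side-chain heavy
atoms of residues 58 and 10. Glycine has no side-chain heavy atoms, so
`sidechain_or_ca()` substitutes the Cα — the construction must be total, and
within a 3 Å radius the statistic is fairly insensitive to this choice; it
is nonetheless the main degree of freedom when comparing against numbers
produced by other tools. Occupancy is judged by water **oxygens** only
(conventional hydration-site practice), at the analysis stride (1 ns), so
sub-stride exchange events are invisible by construction: "unique waters per
replica" undercounts fast exchange and is an exchange-rate proxy, not a
kinetic observable.

The Thr58-type flip descriptor is the distance from the side-chain oxygen to
the reference residue's amide hydrogen and the angle at Cβ between that
oxygen and that hydrogen. The default native region — distance ≤ 4 Å and
angle in [60°, 180°], boundary closed on the native side — is a package
choice: the partition is drawn, not printed, in the source material, so the
boundary is an explicit, fully exposed parameter, and any quantitative
comparison of conditional occupancies must treat it as free. Density grids
normalize by the total frame count (masked cells included), so masking can
never distort the fractions; cells below 0.05 are masked and their frames
returned as raw points.

Representative-frame selection builds S(i,j) = −RMSD(i,j)² (fit on the
protein backbone, measured over key residues plus ligand heavy atoms,
without re-fitting) over the pooled, evenly time-subsampled frames of all
replicas, clusters by affinity propagation, and walks clusters by descending
population until one exemplar frame shows at least one event with every key
residue ("representing all the key interactions" is evaluated on the
exemplar frame alone — the simplest reading; a cluster-fraction rule could
replace it). If none qualifies, the largest cluster's exemplar is returned
with a warning.

**Affinity propagation.** Preference defaults to the median off-diagonal
similarity and damping to 0.5 — the method's canonical defaults. The
implementation is deterministic: no random initialization, argmax ties
resolved toward the lower frame index. Near-tied similarities (frames
duplicated up to noise) are a known degenerate regime in which the
0.5-damped messages oscillate indefinitely; when the exemplar set has not
stabilized within the iteration budget, the pass is rerun once at damping
0.9, the canonical remedy, still deterministically. A run that still fails
returns `converged = FALSE` with a warning rather than an error.

## Geometry conventions

Superposition is least-squares (Kabsch via SVD) with the reflection branch
excluded. Ligand RMSD follows the "fit on protein backbone, measure ligand
un-refit" convention; `rmsd_trace(refit = TRUE)` provides the re-fitted
variant because either may be wanted when comparing to other tools. RMSF
uses the iterated mean structure (fit to the first frame, average, re-fit to
the average) as reference — vendor tools rarely state their reference, and
the two-pass mean is the stable choice — with `reference = "first"`
available. All indices are 1-based (R convention); residue numbers follow
author numbering as in the PDB input.

File formats: multi-model PDB (MODEL/ENDMDL, CONECT, CRYST1) and DCD are
read and written; XTC is not supported (no reader in the R stack this
package builds on) and raises a clear error. Ligand chemistry comes
preferentially from an explicit YAML sidecar — deterministic and
format-independent — with rule-based perception from the bond graph as a
fallback that cannot assign formal charges.

## The synthetic generator

`generator_config()` defaults encode the emulated study design: 20
independent replicas sampled at 1 ns (1000 frames each at desk scale),
planted hydrogen-bond occupancies 1.0 / 0.7 / 0.2 on Asp69 / Glu63 / His95,
water-site occupancy 0.8 with Markov persistence 0.95 (entry rate derived
from stationarity; with a 100-water pool this realizes roughly 30 distinct
site waters per replica per 1000 frames), and a 70% native Thr58 state with
persistence 0.95. Per-replica sub-seeds derive from the master seed by a
fixed splitting rule, so replicas are independent and the whole study is
reproducible bit for bit.

Two design rules make ledger comparisons exact rather than approximate:

1. **Far-from-boundary geometry.** Planted contacts are placed deep inside
   their criteria (H···A 1.9 Å, collinear donors, 160° acceptor angles) or
   far outside (≥ 6 Å); probabilistic realism lives in the Bernoulli/Markov
   schedules, not in borderline geometry.
2. **Audited noise.** Positional noise is Gaussian, clamped at 4σ
   (default σ = 0.02 Å). At build time every archetypal configuration
   (contact on/off × state × occupancy) is re-evaluated under criteria
   tightened and loosened by conservative worst-case bounds (2·4σ√3 on
   distances; arm-length-aware bounds on angles); any discrepancy is a
   configuration error. A σ that could flip any criterion is therefore
   rejected up front, and detector output equals the ledger exactly.

What the generator does **not** emulate: physical force fields, realistic
kinetics or solvent structure, conformational heterogeneity beyond the
planted two-state flip, overlapping/competing interactions, ions, or
box-wrapped coordinates. Passing the ledger-recovery tests demonstrates the
correctness of the detection and bookkeeping logic under known truth — it
does not validate scientific conclusions drawn from any particular force
field or sampling protocol, and real trajectories exercise borderline
geometries that the generator deliberately avoids (those are covered by the
brute-force oracle equivalence tests on random configurations instead).

## Pipeline and problem sizes

`run_pipeline()` executes load → per-replica fingerprints → pooled fractions
→ water occupancy/exchange → state traces → conditional occupancy →
clustering → representative frame, writing seven report files plus a
manifest (config hash, versions, seed, per-replica frame accounts) and a
log. A failing replica is isolated and recorded, never fatal to the others —
with 20 replicas, one corrupt file must not void the study.

Default problem sizes are chosen for a single CPU: the test suite runs the
full 20 × 1000-frame recovery study (~2 minutes), and the pipeline caps the
clustered frame count at 300 pooled frames (evenly subsampled by time; the
function-level cap is 2000) since the similarity matrix and message passing
scale as n². The affinity-propagation exemplars on well-separated basins are
insensitive to this subsampling; the cap is a config field
(`clustering$max_frames`) when more resolution is wanted.

## Known limitations

* Water bridges are single-water only; two-water chains are out of scope.
* Donor/acceptor typing comes from a fixed amino-acid template table plus
  the ligand sidecar; unusual protonation states must be declared in the
  sidecar.
* Halogen bonds, metal coordination and salt-bridge network graphs are not
  detected.
* Exchange statistics are stride-limited (see above), and masked-density
  points are returned unbinned rather than re-histogrammed.
* XTC input and mmCIF topologies are unsupported.
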