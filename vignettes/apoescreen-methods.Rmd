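---
title: "Consensus ranking and interaction analytics for ApoE4 structure-corrector screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus ranking and interaction analytics for ApoE4 structure-corrector screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apoescreen)
```

## The scientific problem

Apolipoprotein E4 (ApoE4) is the strongest genetic risk factor for
late-onset Alzheimer's disease. Relative to the benign E2/E3 isoforms,
the Cys112Arg substitution in ApoE4 propagates a long-range
conformational change in which the tryptophan-34 indole sidechain swings
from a "flip-in" orientation (perpendicular to the protein's long axis)
to a "flip-out" orientation (parallel to it), opening a small druggable
cavity. Small molecules that occupy this Trp34 pocket and push the
sidechain back to the E3-like flip-in state act as *structure
correctors*.

`apoescreen` implements the desk-side analytics of a virtual-screening
campaign for such correctors: every stage that turns docking scores,
shape-similarity scores, pose coordinates, binding tables and
trajectories into decisions. The docking, shape-overlay and
molecular-dynamics engines themselves are out of scope; a seeded
synthetic generator emulates their outputs so every stage is testable
offline.

## The consensus score

The core statistic exploits an asymmetry of the structural ensemble.
Holo-ApoE4 structures (crystallized with a bound stabilizer, Trp34
flip-in) present an open pocket, so docking ranks against them correlate
*positively* with experimental binding; free-ApoE4 structures (flip-out)
have the pocket closed, and ranks against them correlate *negatively*.
For ligand $i$ with per-structure docking ranks $r_{ij}$ (rank 1 = best
score), the consensus score is

$$ C_i \;=\; \frac{\tfrac12 \left( r_{i,\mathrm{holo1}} + r_{i,\mathrm{holo2}} \right)}
                 {\tfrac12 \left( r_{i,\mathrm{free1}} + r_{i,\mathrm{free2}} \right)} $$

and ligands are ranked by ascending $C_i$: a good corrector candidate
ranks *well* against the open holo pocket and *poorly* against the
closed free pocket. The score is dimensionless, invariant under any
uniform positive rescaling of ranks, strictly increasing in each holo
rank and strictly decreasing in each free rank — all of which are tested
as properties.

```{r consensus}
ct <- buildConsensusTable(knownLigandRanks())
ct[order(ct$consensus_rank), ]
```

On the published eight-ligand benchmark this reproduces the printed
consensus ordering exactly; the two weakest binders (Kd 900 and 230
micromolar) fall far down the list while all five ligands with Kd below
30 micromolar occupy the top five slots.

## Structure triage

Ensemble selection starts from eight high-resolution (at most 2 A),
non-mutant X-ray structures and removes those whose observed Trp34
orientation contradicts their class: apo-E3 is expected flip-in, apo-E4
flip-out, stabilizer-bound (holo) E4 flip-in. `triageStructures()`
applies the quality filters and the orientation rule, reporting every
removal with its reason; on the bundled metadata it removes 1OR3 (an E3
structure with an E4-like flip-out Trp34) and 1B68 (an E4 structure with
an E3-like flip-in Trp34), leaving two structures per category.

## Geometric detectors and the interaction checklist

The checklist that characterizes a corrector pose has four entries:
Trp34 orientation after binding, hydrogen bonds to Asp35 and Asp153, and
hydrophobic occupancy of the Trp34 pocket.

* **Hydrogen bonds** are detected as protein N/O to ligand N/O pairs at
  most 3.5 A apart (heavy-atom criterion; crystal and docked poses carry
  no hydrogens, so no donor/acceptor angle term is applied).
* **Pi-stacking** pairs rings perceived from covalent distance-based
  connectivity (heavy atoms within 1.8 A bonded; 5/6-membered,
  near-planar C/N cycles) and reports pairs with centroid distance at
  most 5.5 A and interplanar angle at most 30 degrees — parallel
  stacking only, since that is the contact the campaign reports;
  T-shaped contacts are deliberately not scored.
* **Pocket occupancy** counts ligand carbons and halogens within 4.5 A
  of the sidechain atoms of a configurable pocket residue list
  (default: the Trp34 sidechain of the toy pocket, since the campaign
  never enumerates the full pocket lining), and labels the connected
  ligand fragment with the most contacts. The descriptor reports raw
  counts and lets the caller threshold, because no minimum count
  defining "filling" is published.

`all_key_interactions` is the conjunction flip-in AND both H-bonds AND
non-zero occupancy. On the published checklist of the eight known
stabilizers, all eight are flip-in and six of eight show the full
profile — the two weakest each lack one aspartate H-bond.

All detectors are invariant under rigid-body isometries and monotone in
their cutoffs (property-tested with random rotations/translations at
1e-6 A tolerance).

## Flip classification and trajectory analytics

The "protein axis" is never formally defined in screening practice; this
package operationalizes it as the first principal axis of the CA
coordinates of the selected fragment (sign fixed along increasing
residue number), isolated behind `proteinAxis()` so an alternative
(e.g. a helix fit) can be substituted. The orientation vector of the
sidechain runs from CB to the centroid of the nine indole atoms — it
tracks where the sidechain points, which matches the visual flip-in /
flip-out contrast better than a ring-plane normal. The classification
angle is folded into $[0^\circ, 90^\circ]$ by the absolute-cosine
convention (axis sign irrelevant) and thresholded at 45 degrees, the
unique symmetric boundary between "parallel" (flip-out) and
"perpendicular" (flip-in). Both this axis-angle classification and raw
chi1/chi2 dihedrals (`chiAngles()`, with CD1 as the chi2 reference atom,
the standard Trp convention) are available, because published flip
assignments may rest on either.

Trajectory observables follow the common pocket-stability conventions:
each frame is superposed on the *backbone* selection onto the first
frame (proper Kabsch rotation via SVD, reflection-corrected), the
backbone RMSD is that of the fit, and the ligand RMSD is measured after
the same transform without re-fitting. Interaction persistence is the
mean per-frame indicator, and `flipFraction()` reports the fraction of
frames classified flip-in.

## The synthetic generators

The generators define the study conditions; they are deliberately simple
and their defaults are fixed.

**Screens** (`genScreen()`): the default library holds 1000 molecules,
10 of them genuine binders, mirroring the scale of the screened
natural-compound library (~1250 molecules) and its handful of known
actives. Latent activity is log10-Kd, drawn uniformly — actives below
the 30 micromolar activity cutoff, decoys above — within a 1–1000
micromolar range; Kd below the 5 micromolar detection floor is emitted
as a censored `"<5"` string to exercise the parser, exactly as bound
values appear in published binding tables. Coupling between activity and
each structure column goes through a Gaussian copula on the
library-wide activity ranks: +0.9 for the two holo-ApoE4 columns, −0.9
for the two free-ApoE4 columns (the sign pattern observed in the
published correlation row), and 0.75 × the holo coupling for the apoE3
columns, since the published apo-E3 correlations are positive but
weaker than holo-ApoE4. Scores sit on a docking-like kcal/mol scale
(mean −7, spread 1.5) with 0.25 kcal/mol of additional noise. What this
emulates is the *rank structure* of an ensemble docking campaign; it
does not emulate chemistry, score distributions of real docking
software, or correlated errors between structures, so passing tests
demonstrate the statistical machinery, not docking accuracy.

**Poses** (`buildPoseComplex()`): an idealized Trp-plus-two-Asp pocket
built from standard bond lengths and angles with exactly planar rings —
no real ApoE coordinates, hence no download dependency. Ligand atoms are
placed analytically so each requested interaction holds within 0.05 A /
2 degrees, and the construction is closed-loop verified against the
package's own detectors before the pose is returned. One caveat is
geometric necessity: a stacking ring parked 3.7 A over the indole is
itself within the 4.5 A occupancy cutoff, so when both a stack and an
occupancy count are requested the occupancy self-check is a lower bound
rather than an equality.

**Trajectories** (`genFlipTrajectory()`): a two-state chain over
flip-in/flip-out. The spec couples a per-state persistence with an
arbitrary stationary occupancy; a single shared stay-probability would
force a 50/50 stationary split, so the chain is regenerative instead —
with probability `pStay` it keeps its state, otherwise it redraws from
Bernoulli(`stationaryFlipIn`). The stationary distribution is then exact
by construction and the effective per-state stay probability is
`pStay + (1 - pStay) * pi(state)`. Each state maps to a chi1/chi2
rotamer center (chosen so the two CB-to-centroid directions are ~90
degrees apart) with 8 degrees of angular noise; frames are recorded at
0.1 ns intervals, matching the 100 ps cadence typical of production MD
analyses. All generators run under a fixed seed, restore the caller's
RNG state, and are byte-identical on reruns.

## Numerical choices and degenerate inputs

* Rank ties take average ranks everywhere (so each complete rank column
  sums to $n(n+1)/2$, a tested invariant); hit-list ties break by mean
  score then lexicographic id, and intersections order by position sum
  then id — all deterministic.
* Censored Kd values are kept as explicit censor flags, never sentinel
  numbers. The default correlation policy substitutes the bound value
  and records the flag (the published correlation row evidently used
  `"<5"` numerically); `drop` and `midpoint` (halve below-bounds,
  double above-bounds) are selectable. `"No binding"` records never
  enter numerics and never pass a Kd threshold.
* The default correlation method is Spearman, since docking rank versus
  Kd is an ordinal association. The published per-structure correlation
  row (0.839 … 0.996) is *not* reproducible from any of
  Pearson/Spearman/Kendall on the printed ranks and the method behind
  it is undisclosed, so the package exposes the method as a parameter
  and makes no attempt to match those printed coefficients; its own
  coefficients are verified against textbook formulas instead.
* Whether the printed library-wide consensus ranks were computed over
  1250 or 1258 molecules is not stated; only the *ordering* is used as
  a correctness surface, and fraction-type outputs use 1250.
* Degenerate inputs error early and descriptively: collinear points for
  dihedrals, fewer than three CA atoms for the axis, incomplete indole
  rings, mismatched trajectory atom sets, non-positive ranks, empty
  tables.
* The shape-combination rule is max-over-queries (ties by mean, then
  id): published practice says only that per-query scores were
  "combined", and max preserves any single strong query match. The rule
  is isolated behind `combineShapeQueries()`.

## Problem sizes used in the test suite

The bundled suites run the eight-ligand published benchmark exactly;
synthetic property suites use libraries of 1000 molecules (20 seeds for
the recovery comparison), 1000 seeded permutations for the
enrichment-factor null, and 20000-frame chains for stationary-occupancy
checks — sizes at which the Monte-Carlo tolerances (±0.02 occupancy,
3 standard errors on the null mean) are comfortably resolved on a single
CPU in a few minutes.

## Known limitations

* The toy pocket is idealized geometry; detector defaults (3.5 / 5.5 /
  4.5 A, 30 and 45 degrees) are standard literature values and are not
  calibrated against real ApoE crystal structures.
* Ring perception is distance-based and aromaticity-blind; saturated
  six-rings that happen to be planar would be treated as stackable.
* Only parallel pi-stacking is scored; cation-pi, halogen bonds, salt
  bridges and the Arg61–Glu255 domain interaction are out of scope (no
  full-length coordinates exist in scope).
* The synthetic screen's Gaussian-copula coupling is exchangeable across
  ligands; real docking errors are structured (size, charge,
  flexibility biases), so enrichment numbers on synthetic screens
  should be read as mechanism checks, not performance forecasts.

## Pipeline orchestration

`runPipeline()` chains triage, simulation, consensus ranking with
diagnostics and enrichment, shape-score combination, hit-list
intersection, pose checklist and trajectory analytics, writing TSV/JSON
stage outputs. Configuration is a list or YAML file; defaults are the
campaign conventions (Kd activity cutoff 30 micromolar, top-25 lists,
45-degree flip threshold). Config errors and stage errors carry distinct
condition classes, and identical config plus seed gives byte-identical
outputs.

```{r pipeline}
rep_ <- runPipeline(list(seed = 1,
                         screen = list(nDecoys = 180, nActives = 8,
                                       holoCoupling = 0.9,
                                       freeCoupling = -0.9),
                         trajectory = list(nFrames = 400)))
rep_$stage_names
rep_$stages$consensus$enrichment$enrichment_factor
```
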