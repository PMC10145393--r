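---
title: "Negative image-based rescoring: models, parameters and design notes"
author: "nibscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Negative image-based rescoring: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nibscreen)
```

This vignette is the package's own account of the science it implements:
the models, the parameters that matter, the numerical choices, and what
the synthetic fixtures do and do not demonstrate.

## The cavity negative image

A binding pocket is represented by the *negative image* of its solvent
volume: pseudo-atom points packed into the cavity, each neutral (kind
`C`), positive (`N`) or negative (`O`). The image serves as a rigid
scoring target — a docked pose that fills the pocket and matches its
polarity pattern resembles the image, and similarity to the image becomes
the pose score.

**Packing.** Points are placed on a face-centered-cubic lattice because
FCC is the densest sphere packing; the nearest-neighbour spacing is
exactly twice the *filler radius* (default 0.85 Å, giving a 1.7 Å point
spacing comparable to a carbon–carbon bond), restricted to a cube of
half-edge *box radius* (default 20 Å) around a seed point, typically a
co-crystallized ligand centroid. "Box" is read literally as a cube, not a
sphere.

**Carving.** A lattice point survives when

* it clashes with no protein heavy atom — its distance to every atom is at
  least that atom's Bondi van der Waals radius (scaled by
  `clash_vdw_scale`, default 1) plus the filler radius;
* it lies within `max_protein_distance` (default 4.5 Å) of some protein
  heavy atom, which removes free-floating outer shells;
* it belongs to the connected component (adjacency = lattice-contact
  distance) containing the surviving point nearest the seed.

The component rule is this package's replacement for the burial heuristics
of cavity-detection programs whose internals are unpublished: without it,
a 4.5 Å shell hugging the *outside* of the protein would survive the first
two rules. It is a design choice, not a reconstruction of any particular
tool. Carving is idempotent, and jointly rotating protein, seed and
lattice rotates the carved set — both properties are asserted in the test
suite.

**Charge typing.** Points within `hbond_distance` (default 3.5 Å, a
standard donor–acceptor heavy-atom separation) of a protein H-bond donor
become negative `O` points (they occupy the place of the acceptor the
donor would bind); points near an acceptor become positive `N`. When both
partner types are in range the nearer wins; an exact tie stays neutral.
Donors and acceptors are identified by a fixed residue/atom-name lookup
(backbone N/O, the usual side-chain donors and acceptors, water oxygen as
both); no protonation inference is attempted, matching the assumption
that input structures are already prepared.

## Shape and electrostatic similarity

Scoring is rigid: the pose is compared where the docking engine left it,
never translated or re-optimized.

**Shape.** Each body (pose heavy atoms with element vdW radii; model
points with a display radius) is a sum of atom Gaussians
$g_i(r) = p\,e^{-\alpha_i\lVert r-r_i\rVert^2}$ with amplitude $p = 2.70$
and $\alpha_i = \kappa/R_i^2$, $\kappa = \pi(3p/4\pi)^{2/3}$, the standard
first-order Gaussian model in which each atom Gaussian integrates to its
hard-sphere volume. Pairwise overlap volumes have the closed form
$V_{ij} = p^2(\pi/(\alpha_i+\alpha_j))^{3/2}
e^{-\alpha_i\alpha_j d_{ij}^2/(\alpha_i+\alpha_j)}$, and the similarity is
the Tanimoto $T = O_{AB}/(O_{AA}+O_{BB}-O_{AB}) \in [0,1]$. Higher-order
(triple) intersection corrections are deliberately omitted: the
first-order form is fast, symmetric, rigid-motion invariant, and
verifiable against grid quadrature, which the tests do to three
significant figures on two-atom bodies.

The model-point display radius is twice the filler radius, i.e. the FCC
nearest-neighbour spacing, so adjacent point spheres touch and the cloud
behaves as one contiguous body rather than a set of isolated beads. It is
configurable (`score_config(point_radius = )`).

**Electrostatics.** The pose's Coulomb field
$E(k) = \sum_a q_a/(\varepsilon\,\max(d_{ak}, d_{\min}))$ is sampled at
the model's own point centers and compared with the point charges by the
Hodgkin index $H = 2\sum E_A E_B / (\sum E_A^2 + \sum E_B^2) \in [-1,1]$.
Two choices matter here. First, the reference field *is* the charge
vector, not a Coulomb field computed among the points: the model is the
target pattern, and this keeps $H = \pm 1$ exactly at the
identity/anti-identity limits (asserted in the tests). Second, the
distance floor $d_{\min}$ (default 1 Å) caps the singularity when a
charged atom sits on an observer point. A pose with no partial charges
contributes a zero field and $H$ falls back to 0 — rescoring degrades
gracefully to shape-only.

**Blend.** `score = w_shape · T + (1 − w_shape) · H` with `w_shape = 0.5`
by default. The upstream literature does not state a blend; equal
weighting is the neutral choice and the weight is an explicit parameter.
Compound-level rankings always use the best-scoring duplicate (tautomer ×
enantiomer × pose), the convention for every selection step downstream.

## Enrichment metrics

Rankings are evaluated by ROC AUC (midrank Mann–Whitney; ties count one
half) and by BEDROC with $\alpha = 20$, which concentrates the weight on
roughly the top 8% of the ranking — the regime that matters when only the
top of a screen is taken forward. The implementation follows the standard
exponentially weighted formulation; tied scores share their mean rank so
the metric is independent of input order, and the all-active limit is
defined as 1. Records are collapsed to one best pose per compound before
metrics (disable with `collapse = FALSE`). Both metrics are
score-monotone-invariant and are tested against independent
direct-summation oracles on a thousand random permutations at 1e-10.

## Greedy model optimization (BR-NiB)

Out of the box a carved cavity image over-describes the pocket: points in
regions never reached by actives dilute the shape term and reward decoys.
BR-NiB trims them: per generation, every single-point-deletion variant of
the incumbent model is evaluated by training-set BEDROC20, the best
variant is accepted only on *strict* improvement (ties resolve to the
lowest point index for reproducibility), and the search stops when no
deletion improves the metric or one point remains. Strict improvement
guarantees termination and makes convergence a fixed point: re-running on
the output changes nothing.

One point is removed per generation; batch removal is not implemented.
The per-variant evaluation re-aggregates cached pose-vs-point
contributions (shape overlaps, field samples) instead of rescoring from
scratch — exact, not approximate, because both the Gaussian overlap and
the Hodgkin sums are linear aggregates over points; the cache is asserted
identical to full rescoring at 1e-12.

The second optimization round mirrors the screening reality that a model
trained on all actives over-fits the easy ones: actives ranking above the
top-1% decoy threshold are removed
(`subset_actives_by_decoy_rank`) and the original model is re-optimized
on the hard remainder.

## Pharmacophore point filter

Five binding-site regions, each one or more spheres anchored on residue
landmarks with an atom-class criterion:

| region | anchors | radius (Å) | criterion |
|---|---|---|---|
| 1 | His479, Tyr502 | 4.0 | H-bond-capable heavy atom (N, O, S, F, Cl, Br, I) |
| 2 | Leu324, Phe388 | 4.5 | aromatic atom |
| 3 | Phe378 | 5.2 | aromatic atom |
| 4 | His323, structural water | 4.0 | H-bond-capable heavy atom |
| 5 | Arg367 | 4.0 | H-bond acceptor (same element class, no attached H) |

A pose passes with regions 1∧2∧3∧4 or 2∧3∧4∧5, and must also place a
heavy atom within 4.0 Å of His479 or Tyr502; a compound passes if any of
its poses does. Radii are strict (≤).

Design notes. The source protocol measures distances "within X Å of a
residue" without naming atoms, so anchors follow a fixed, exportable
convention: His = ring-N centroid, Tyr = hydroxyl O, Phe = ring centroid,
Leu = CD1/CD2 midpoint, Arg = guanidinium C, water = O. Multi-anchor
regions are OR-combined — explicit in the "His323 or water" wording of
region 4 and adopted for region 1's His479/Tyr502 pair as well for
consistency; an AND reading remains expressible through the
`pass_logic` string of a custom `pha_model()`. The acceptor criterion is
a documented simplification (element class with no explicit hydrogen),
since docked pose files frequently omit hydrogens.

## Selection funnel

Per-model rankings are cut to the top fraction (`floor(f·N)`, minimum 1;
at the published library size of 169,100 compounds the 1% cut is 1,691
per model and 6,764 pooled entries over four models), pooled with
duplicates flagged, and filtered by strict thresholds: logP > 5.5
excluded (the pocket is lipophilic; the generous threshold reflects
that), predicted MM/GBSA binding energy > −95 kcal/mol excluded, and
compounds on a pattern-match list (e.g. PAINS) excluded. Energies and
pattern matches are *consumed*, never computed — they come from external
programs in practice — and boundary values survive, exactly as the
thresholds are worded. Exclusions are attributed to the first rule that
fires (pattern, logP, energy) and logged per record; filters commute as
set operations regardless of attribution order.

## Fingerprints

Hit novelty is judged by 64-bit linear fingerprints: all simple paths of
0–7 bonds over the heavy-atom graph, each path string built from
Daylight-style atom invariants (element, heavy degree, explicit-H count,
charge-sign proxy at |q| > 0.5 e, ring flag, aromatic flag) joined by bond
orders, canonicalized to the lexicographically smaller direction, and
hashed into the bit vector. The hash is fixed and documented — a
multiplier-31 polynomial string hash modulo 2^24 (exact in double
arithmetic), reduced modulo the width — so fingerprints are reproducible
across implementations. At 64 bits collisions are expected; that width is
kept for comparability with the published analysis, and `width` is a
parameter for anything beyond qualitative novelty (Tanimoto < 0.2 read as
"novel scaffold").

## Synthetic fixtures: what they show and what they cannot

The generators build a rectangular open-top pocket of dummy wall atoms
(1.5 Å spacing) carrying one donor and one acceptor wall atom and the
eight pharmacophore anchor residues just behind the walls; the two polar
atoms protrude slightly into the pocket so that carved points fall inside
H-bond range of them. Actives are plug-shaped atom grids filling the
pocket, jittered by `(1 − active_fit)` Å, with partial charges
complementary to the wall polarity and criterion atoms planted next to
each anchor; decoys are the same grids displaced and rotated out of the
pocket. Score-set fixtures draw actives from Normal(μ+Δ, 1) and decoys
from Normal(μ, 1), chosen for the closed-form expected AUC
$\Phi(\Delta/\sqrt 2)$ that the tests check. All generators are pure
functions of a seeded `fixture_spec`.

These fixtures make every algorithmic property testable — carving rules,
charge mirroring, ranking separation, greedy recovery of a planted noise
point, pharmacophore logic, funnel arithmetic — but they are emphatically
not realistic: walls are planar, poses are unphysical atom grids, charges
are planted, and the active/decoy separation is constructed. Passing
tests demonstrate algorithmic correctness, not prospective screening
performance on real targets.

**Problem sizes.** The test suite and the acceptance script run the full
protocol on pockets of ~200 protein atoms, cavity models of ~35 points
and 36–45 compounds, and verify metric identities on up to 1,000 random
permutations of ≤ 38-record rankings; these sizes exercise every code
path while keeping a complete run interactive. The funnel arithmetic is
exercised at the full published library size (169,100 records), which is
cheap because it is pure ranking.

## Degenerate inputs and numerical conventions

* Coordinates are Cartesian Å throughout; no unit conversion anywhere.
* An empty carve is an error naming the criterion that removed the last
  points, never an empty model passed onward.
* Score ties break deterministically (compound ID), greedy ties by lowest
  point index, altLoc ties by first encountered.
* `esp_min_distance` floors Coulomb distances; a zero-charge pose scores
  `H = 0`, and a zero-field/zero-model pair is defined as 0.
* BEDROC's all-active limit returns 1 exactly; `alpha` must be positive.
* The V2000 reader skips malformed records with a warning and counts
  them; zero-bond records (bare point sets) are legal poses.

## Known limitations

* The cavity burial rule (connected component) is a stand-in for
  unpublished heuristics; on shallow or multi-lobed pockets it may keep
  more or less than a specific upstream tool would.
* The shape/ESP blend weight is a free parameter defaulting to 1:1; no
  claim is made that this reproduces any particular program's blend.
* Pattern (PAINS) matching and binding-energy computation are out of
  scope by design; the funnel consumes their outputs.
* Fingerprints at 64 bits are collision-prone and suitable for novelty
  triage, not similarity searching.
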