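---
title: "Dual-channel lineage tracing: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-channel lineage tracing: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualTrace)
```

# The problem

Long-term light-sheet recordings of pre-implantation embryos are the raw
material for reconstructing the first cell-fate decisions, but a large
fraction of embryos rotate and translate so strongly between frames that
frame-to-frame nucleus tracking fails outright. When every nucleus carries a
green histone-fusion label and the progeny of a single cell photoconverted
at the 4-cell stage additionally carry the red form of the same protein, the
two colour channels provide exactly the information needed to fix this: the
green population defines a centre, the red population an orientation, and
the residual rotational degree of freedom can be found by matching
consecutive frames. This vignette explains the models implemented in
`dualTrace`, the meaning and defaults of every tunable parameter, and the
design decisions taken where the underlying method leaves freedom.

# Pipeline model

The pipeline operates on `SpotSeries` objects: per-frame, per-channel
collections of detected nuclei with positions in micrometres. All geometry
is done in physical units because the axial plane spacing (3 µm by default)
is much coarser than the lateral pixel pitch.

## Spot detection

`detectSpots()` is a multiscale Laplacian-of-Gaussian (LoG) blob detector.
Scales are given in micrometres and converted per axis into voxel units, so
the anisotropy is handled exactly. The scale-normalized response
$-s^2 \nabla^2 (G_s * I)$ is evaluated on a logarithmic grid of scales and
local maxima over space and scale above a threshold become spots; a spot's
radius adapts to its best scale $s$ as $\sqrt{3}\,s$. For a Gaussian nucleus
of scale $\sigma$ the response peaks at $s = \sigma/\sqrt{1.5}$, so the
reported radius is $\sqrt{2}\sigma$ — within the tolerance any downstream
consumer needs. Defaults (`sigmaMin = 2.5`, `sigmaMax = 8` µm, 5 scales,
`threshold = 2`) were tuned on the simulator and are deliberately
permissive: missing a dim nucleus at a late timepoint is costly, while
spurious extra detections are removed by the validation filters. Plateau and
cluster ties resolve deterministically (strongest response, then lowest
(z, y, x) index).

Two Gaussian blobs of scale $\sigma$ fuse into a single response maximum
when their separation falls below roughly $2.6\sigma$; the detector cannot
resolve nuclei packed more tightly than that, which sets the resolution
assumption for everything downstream.

## Validation filters

Four filters run per frame, in a fixed order:

1. **Embryo-extent filter.** The embryo extent is estimated as the median
   over spots of the maximal inter-spot distance, and spots farther than
   `radiusFactor` × extent from the green fluorescence centre of mass are
   discarded (closed ball: boundary spots are kept). The estimator
   approximates a diameter only when roughly antipodal spots exist — a
   4-cell tetrahedron has its blastomeres at 0.61 × extent from the centre,
   and the outermost genuine nuclei of a dense shell reach ~0.72 × extent —
   so the default factor is **0.78**: above the retention ratio of every
   clean configuration we generate, and strictly below the $1 - 1/5 = 0.8$
   bound at which the centre-of-mass drag of a single far outlier among
   four true cells would place it exactly on the threshold. The filter is
   **iterated to a fixed point** within each frame (outliers inflate the
   extent estimate, so survivors are re-filtered until nothing more is
   discarded); this is what makes the validation idempotent.
2. **Double-spot merge.** Spots of one channel closer than `mergeDistance`
   (default 4 µm, about one nuclear radius) are connected components of the
   proximity graph and merge — transitively — into one spot at the
   intensity-weighted centroid, with summed intensity and maximal radius.
   Merged spots get fresh ids; untouched spots are never moved.
3. **Red/green colocalization.** A red spot without a green spot within
   `colocDistance` (default 4 µm) is background: photoconversion is never
   exhaustive, so every true red nucleus retains a green partner.
4. **Temporal red recovery** (optional, on by default): a red spot
   discarded above is recovered if a valid red spot existed in the previous
   frame within `recoveryRadius` (default 6 µm). This compensates for
   residual green-channel mis-segmentation and is the only
   order-dependent step; it is applied sequentially in time, in the current
   coordinate system of the pass.

The per-frame report satisfies, exactly,
`nIn = nOut + outside + merged + noncoloc − recovered`.

**Limitations.** The extent estimator has breakdown problems that no
threshold choice can fully fix: a cluster of background spots at a similar
distance inflates the estimate enough to shelter itself, and with four true
cells plus several outliers the centre-of-mass drag can defeat the filter
entirely. Robust-centre variants (coordinate-wise or geometric medians) were
evaluated and rejected: they distort small post-division configurations and
peel genuine boundary nuclei. In practice the filter is reliable when
background is absent at the lowest cell counts — which matches its origin:
background detections appear when illumination is raised to follow the
red signal as it dilutes with division, i.e. only after the first division
round. The `radiusFactor` knob remains the user-level compensation exactly
as the method prescribes.

## Drift and rotation correction

`computeReferenceFrame()` builds, per frame, origin = green COM and axis =
ΔCOM = COMʳᵉᵈ − COMᵍʳᵉᵉⁿ. **Both COMs are intensity-weighted** (fluorescence
centres of mass). This matters: the histone-fusion signal is partitioned
between the daughters at division, so the weighted COM of either channel is
invariant across divisions, whereas a count-based COM steps by
$(c - \mathrm{COM})/(n+1)$ whenever one of $n$ cells divides. Those steps
tilt the orientation axis by 5–10° in a single frame — a jolt that the roll
search cannot correct (it only has the rotation *about* the axis) and that
was the single largest source of tracking errors in development. The
simulator dilutes both channels accordingly (green replenishment by fresh
protein synthesis is neglected on these timescales).

`buildBasis()` completes the axis into a right-handed orthonormal basis
(first row = axis; near-ties in the supporting world axis break toward
world-x with a 1e-6 tolerance so the basis varies continuously).
`optimizeRoll()` scans θ ∈ {0°, …, 359°} exactly — no sub-degree
refinement — and minimizes the **mean** nearest-neighbour distance of the
current frame's green spots to the previous aligned frame. The mean, not a
trimmed statistic, is deliberate: robust statistics allow the search to
"chase" a subset of the cloud after a small axis perturbation, visibly
mis-rotating the rest, while the mean is stiff. Ties break toward the
smallest angle. Frames whose red channel provides no usable orientation
reuse the previous frame's axis and are recorded.

Invariants after alignment: pairwise intra-frame distances are preserved to
1e-9 µm, the weighted green COM sits at the origin and the weighted red COM
on the +x ray of the basis, and every stored rotation satisfies
$R^\top R = I$, $\det R = 1$ to 1e-9. The second validation pass then
re-runs the filters on the re-aligned raw spots, which lets the temporal
red recovery operate in drift-free coordinates.

## Tracking and the two-channel split

`linkFrames()` computes an exact minimum-cost one-to-one assignment
(shortest augmenting paths; no assignment solver for R is available in this
stack, so the package carries its own, verified against brute-force
permutation search) subject to `maxLinkDistance` (default 15 µm). Unassigned
next-frame spots are then attached as second daughters: among assigned
mothers with out-degree 1 within `divisionDistance` (default 15 µm, two cell
radii — daughters are placed by the spindle about one cell radius from the
mother centre), the mother minimizing the **division-symmetry error**
$\lVert \mathrm{midpoint}(d_1, u) - m\rVert$ is chosen. Daughters straddle
the mother, so the midpoint of a true daughter pair falls onto the mother
while a false pairing lands half a cell spacing away; a plain nearest-mother
rule was observed to lose by under a micrometre in crowded frames. Ties
break by distance, then by the smallest mother id. Optional single-frame gap
closing (off by default) joins a track ending at *t* to one starting at
*t + 2* through a flagged synthetic midpoint node.

Tracking runs separately on the red subset and on the green-minus-red
subset (`subsetGreenMinusRed()`): each subproblem is sparser, and a division
in the red lineage can never steal a green daughter. For an acquisition
started at the 4-cell stage the expected result is one red and three green
trees rooted at frame 0.

## Condensed trees and the edit distance

`condenseTree()` keeps only division events: the root node stores the
number of timepoints until the first division (or track end) and each
division node stores, per daughter branch, the timepoints until the next
division or end. The root-origin node is included so that division-free
tracks are non-empty and pre-division track-length differences are visible.
Because biological daughters are unordered while the Zhang–Shasha distance
is defined on ordered trees, children are put into a canonical order
(branch length, then subtree node count, then subtree signature) before
comparison; exact unordered edit distance would be exponential and is
unnecessary at these sizes.

`zssDistance()` implements the keyroot/leftmost-leaf dynamic program and is
tested against a naive exponential edit-distance recursion on thousands of
random small trees, plus metric-property checks (identity, symmetry,
triangle inequality) under unit costs. The default update cost is binary
(equal branch-length tuples → 0, else 1); a length-difference-proportional
option exists. The condensation achieves the point it was introduced for: a
tracking slip near the start of a long branch changes the distance by a
bounded amount (≤ one update), not proportionally to the branch length.

Forests are matched by minimizing Σ(‖origin difference‖ + `timeWeight` ×
|frame difference|), with `timeWeight` defaulting to 1 µm/frame (an
embryo-scale heuristic). Trees rooted after the acquisition start or
tracked for fewer than `minTrackLength` timepoints are flagged spurious and
excluded from totals — they already penalize the tree they detached from.
Unmatched non-spurious trees pay their full per-node insertion/removal
cost.

# The synthetic embryo

`simulateEmbryo()` generates the study conditions; its defaults are the
conditions under which all quantitative claims in the test suite are made.

* **Geometry.** Embryo radius 45 µm (a ~90 µm embryo); nuclei confined to a
  peripheral shell (0.6–0.85 × radius — blastomeres appose the zona
  pellucida as the embryo compacts), with centre-to-centre spacing set by
  cell-size tiling of the shell (down to ~13 µm at the 32-cell stage) and
  never below 2.2 × the nuclear scale (4 µm).
* **Divisions.** Cell cycle 200 ± 35 min (synchrony loosens with rounds, as
  in real cleavage), three rounds by default (4 → 32 cells). Division
  orientation follows the free space around the mother (Hertwig-style:
  the candidate axis maximizing daughter clearance), daughters start one
  nuclear radius from the mother and the tiling relaxation — capped at
  2.5 µm/frame, the pace of physical cell rearrangement — spreads them over
  subsequent frames without shoving established neighbours (fresh
  daughters carry the mobility in the relaxation).
* **Motion.** Per-cell Brownian jitter (0.3–0.35 µm/frame), plus rigid
  drift and rotation of the whole embryo about an axis through its centre.
  The cloud's collective Brownian drift is removed (the zona confines the
  cell mass; collective motion enters through the explicit drift term).
* **Labels.** Every cell emits a green spot; descendants of the converted
  founder also a red spot. Intensities halve per generation in both
  channels (histone partitioning).
* **Presets.** `rotating` (15-min frames, 60 frames, 5°/frame rotation
  about a tilted axis plus (5, 4, 3) µm/frame drift), `stationary`
  (5-min frames, 160 frames, jitter only), `crowded` (smaller embryo,
  larger jitter, two rounds). Presets are clean acquisitions; background
  injection is a separate ingredient enabled via `spuriousRate`.
* **Background model.** Spurious detections ramp with the illumination:
  zero before the first division round (no dilution, no power increase),
  growing geometrically with the mean generation afterwards. Green
  background lands in a tight far-field band (2.9–3.0 × the cloud radius;
  a tight band keeps the self-referential extent filter effective), red
  background anywhere outside a 12 µm clearance of true nuclei (so it
  fails colocalization by construction). These regimes mirror where real
  background comes from and, equally, delimit where exact automatic
  cleanup can be guaranteed (see the filter limitations above).
* **Rendering.** Cells become anisotropy-aware Gaussian blobs in 80-plane
  stacks (3 µm plane spacing, 2 µm lateral pitch) with constant-plus-ramp
  background and optional Poisson noise.

Everything is deterministic given the seed (bitwise-identical outputs).

**What the simulator does not emulate:** optical point-spread functions
beyond an isotropic Gaussian, light-sheet stripe artefacts, photobleaching
kinetics, compaction and blastocyst morphology (no cavity; nuclei stay on a
sphere), fate-dependent behaviour, and segmentation errors other than
missed/extra/double detections. Tests passing on these simulations show
that the algorithms are correct under the stated motion, division and
background models — not that any particular real embryo will be tracked
error-free.

# Problem sizes and runtime choices

The test suite and the acceptance script run full-scale simulated
acquisitions: 60 frames × 32 cells (rotating), 160 frames × 32 cells
(stationary), 110 frames × 16 cells (crowded), five seeds for the paired
with/without-correction comparisons and three for the subsampling curves;
detection closure uses rendered 80 × 96 × 96 stacks at two stages. These
sizes keep a complete run in a few minutes on one core while exercising
every division round.

On these conditions the pipeline attains condensed-tree distance 0 to the
ground truth on every rotating and stationary run, while disabling the
alignment yields strictly positive distances; lineages survive subsampling
of the 5-min stationary series to at least 20-min intervals (and the
rotating series to 30-min), degrading monotonically beyond; and two-channel
tracing is never worse, sometimes strictly better, than tracing the
undivided green channel on the crowded preset.

# Known limitations

* The orientation axis is only as good as the red COM: if the red lineage
  is lost for many consecutive frames the axis freezes (previous-frame
  reuse) and rotational drift accumulates uncorrected.
* The roll search corrects rotation about the ΔCOM axis only; true axis
  tilt between consecutive frames (e.g. from asymmetric cell rearrangement)
  is invisible to it. The intensity-weighted COMs remove the dominant,
  division-driven part of this error but not all of it.
* The extent-based background filter is not robust to background clusters
  near the embryo or to any background at the 4-cell stage (see above).
* Tracking assumes nuclei move less than about a quarter of their spacing
  per frame; at 60-min effective intervals division assignment becomes
  genuinely ambiguous and errors appear, as the subsampling curves show.
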