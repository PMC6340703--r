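# dualTrace

Automated lineage tracing for volumetric time-lapse recordings of
pre-implantation embryos that carry a **dual nuclear label**: every nucleus
expresses a green histone-fusion fluorophore, and the progeny of one cell
photoconverted at the 4-cell stage additionally carry a red form of the same
protein. Light-sheet recordings of such embryos are frequently unusable for
automated tracking because the whole embryo translates and rotates between
frames; `dualTrace` uses the sparse red population as a fiducial to remove
that rigid motion and then reconstructs the cell lineage.

The package is aimed at developmental-biology labs doing long-term
light-sheet imaging of mouse (or comparable) embryos, and at method
developers who need a fully controlled synthetic benchmark for lineage
tracking: it ships a simulator that generates dividing, drifting, rotating
embryos with complete ground truth.

## Method

For every timepoint *t* the detected nuclei define a reference frame:

* origin **o**ₜ = fluorescence centre of mass (COM) of the green spots,
* orientation axis **a**ₜ = ΔCOM = COMʳᵉᵈ − COMᵍʳᵉᵉⁿ, normalized,
* the residual degree of freedom — the roll angle θₜ about **a**ₜ — is chosen
  from the 360 one-degree candidates that minimize the mean
  nearest-neighbour distance between the aligned green spots of frames *t*
  and *t − 1*.

Every spot **x** is mapped to R(θₜ) B(**a**ₜ) (**x** − **o**ₜ), which places
the green COM at the origin and the red COM on a fixed axis in every frame.
Before alignment, a validation pass removes background detections (spots
outside radiusFactor × the embryo extent, where the extent is the median of
all maximal inter-spot distances), merges double detections of one nucleus,
discards red spots with no green partner (photoconversion always leaves a
residual green population, so a true red nucleus is always green too) and
optionally recovers red spots seen near a valid red spot in the previous
frame. The validation is re-run on the re-aligned embryo, the green spots
colocalizing with red are subtracted from the green channel, and the red and
green-minus-red subsets are tracked **separately** (optimal one-to-one
assignment per frame pair plus division attachment, at most two daughters).

Reconstructed forests are compared through **condensed trees**: each lineage
tree reduced to its division events, every node storing how many timepoints
each daughter branch was tracked. Condensed trees are compared with the
Zhang–Shasha ordered-tree edit distance (user-defined insert/remove/update
costs), forests are assigned to each other by the spatial + temporal
distance of their root origins, spurious trees are excluded, and the summed
pairwise distance is the total lineage difference.

## Worked example

```r
library(dualTrace)

sim <- simulateEmbryo(simulationPreset("rotating", seed = 1))
sim$series
#> SpotSeries with 60 frame(s), 1221 spot(s)
#>   frame interval: 15 min; voxel size (z,y,x): 3 x 2 x 2 um
#>   per channel: green=969, red=252

res <- traceSeries(sim$series)          # validate -> align -> re-validate -> trace
res$forest
#> LineageForest: 4 tree(s), 969 node(s)
#>   channels: green=3, red=1

ev <- evaluateAgainstTruth(res$forest, truthForest(sim$truth),
                           transforms = res$alignment)
ev$totalDistance
#> [1] 0
```

The simulated embryo rotates 5°/frame and drifts ~7 µm/frame, divides from 4
to 32 cells, and is still reconstructed perfectly (condensed-tree distance 0
to the ground truth, link precision and recall 1.0). Running the identical
pipeline with `align = FALSE` yields a strictly positive distance (19 for
this seed): the drift correction is what makes the lineage recoverable.

File-based processing is available through `runPipeline()` (YAML
configuration, all intermediates written to a run directory) and the thin
command-line front end `inst/scripts/dualtrace` with subcommands
`simulate`, `detect`, `validate`, `align`, `trace`, `treedist`, `pipeline`
and `evaluate`.

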