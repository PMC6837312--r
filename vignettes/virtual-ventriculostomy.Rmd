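---
title: "Virtual ventriculostomy lesions in structural connectomes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual ventriculostomy lesions in structural connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vlconn)
```

## The question

A frontal ventriculostomy follows the Kocher-Monro (KM) trajectory: a
catheter enters at Kocher's point — classically 10 cm posterior to the
nasion and 3 cm lateral to the midline — and is advanced to the foramen of
Monro.  The pass inevitably transects white-matter fibers, yet the
procedure is considered neurologically silent.  `vlconn` implements an
in-silico version of that experiment on whole-brain tractograms: place a
virtual cylindrical instrument along the KM trajectory, delete every
streamline it transects, rebuild the structural connectome, and ask at
which scale of description the network notices — global graph indices,
nodal strength, or edge-level subnetworks (the network-based statistic,
NBS).

Because the package must be testable without any imaging download, a
synthetic cohort generator stands in for real diffusion data.  The
generator is first-class, seeded, and deliberately simple enough that every
downstream stage has an analytic or brute-force oracle.

## Geometry

**Head model.** The scalp is a sphere (default radius 80 mm) carrying the
nasion on its anterior midline and the two foramina of Monro in its
interior.  Real scalp geometry is irrelevant to the statistics being
tested; the sphere keeps Kocher's point closed-form and checkable.
Coordinates are a right-handed RAS-like millimetre frame (+x subject
right, +y anterior, +z superior).

**Kocher's point.** The 10 cm / 3 cm offsets are interpreted as geodesic
arc lengths along the scalp — the surgical tape-measure convention — first
along the midsagittal great circle, then along the orthogonal great circle
toward the operated side.  (Chord-length offsets would differ by a few
millimetres on an 80 mm sphere; the convention is a genuine open choice and
the geodesic one matches how the entry point is found on a patient.)  On a
sphere both walks have closed forms, which the tests exploit.

**Instrument.** A finite capped cylinder from Kocher's point to the
ipsilateral foramen of Monro, default radius 2 mm (a conservative 4 mm
diameter).  A streamline is *transected* when the exact minimum distance
between its polyline and the axis segment is strictly below the radius:
boundary contact at exactly the radius does not count (a zero-measure tie
needs a fixed convention), distances are measured to the finite segment
(no end caps beyond the segment metric), and the decision is computed by a
vectorized exact segment-segment distance, not by sampling.  Tests compare
it against a dense-sampling oracle (points every 0.05 mm) and check
reversal symmetry, rigid-motion invariance and radius monotonicity.

## Synthetic cohorts

`default_cohort_spec()` encodes the desk-scale study design: 12 cortical
nodes (6 per hemisphere), 8 subjects per group in three groups (control,
left KM, right KM), and ~1,800 streamlines per subject in ~34 bundles.
A full-scale design (84 nodes, 44 subjects per group, millions of
streamlines) runs through the same code path — supply a larger
`parcellation()` and subject count, or `experiment_config(profile =
"full")` for the 44-per-group permutation settings; the desk profile
exists so that the full experiment, its calibration runs and its recovery
replicates fit in minutes of CPU.

Bundles are Catmull-Rom splines through node centroids and waypoints, with
independent per-axis Gaussian offsets of every control point per streamline
(`spread_sd`, 0.8–2 mm), sampled densely enough that point spacing never
exceeds 1 mm.  Per-point FA is clipped Gaussian (defaults 0.35–0.60 mean,
0.05 SD, matching typical white-matter values; clipping at the stated
defaults affects well under 1% of samples).  Inter-subject anatomy is
emulated by jittering landmarks and waypoints with `jitter_sd` (default
0.5 mm).  The jitter is deliberately modest: both the bundle and the
trajectory are defined in the same subject's native anatomy and therefore
covary — what matters statistically is the *relative* geometry of bundle
and instrument, and a relative SD much beyond a millimetre would make the
per-subject transected fraction bimodal rather than merely variable.

Seeds: one master seed; every subject, stage and permutation stream draws
its own seed through a counter-based multiplicative split (`split_seed`),
so a cohort or a full experiment is a pure function of `(spec, seed)`.

**The planted asymmetry.** The right anterior medial complex — six bundles
forming the complete graph on the four right medial nodes, emulating a
dense cingulum-like anteroposterior system whose width is comparable to
the instrument's — is routed through the right KM axis.  Its left mirror
image is routed through a paramedian corridor roughly 10 mm clear of the
left axis, and all other bundles (broad callosal-fan-like commissures,
lateral association bundles) stay clear of both trajectories.  This plants,
by construction, the asymmetric result structure the virtual experiment is
meant to exhibit: a right-lateralized strength decrease at the complex's
nodes and a right decrease subnetwork, with the left comparison null.
Streamline counts are deliberately distinct across bundles (16–170) so
that each subject's weight ranking is stable; that choice, plus the
strong transected fraction (~85–90% of the complex at 2 mm radius), gives
per-edge standardized differences large enough that 8-vs-8 groups suffice
— at desk scale a subtle effect would be undetectable by design, which
would test nothing.

Two low-count "minor" bundles have wide endpoint spread so their capture
varies across subjects; they exercise the majority edge mask and make
per-subject adjacency non-constant.  They can be disabled
(`minor_bundles = FALSE`), in which case the deterministic redundant
architecture makes every subject's adjacency identical — the clean setting
for showing that the lesion leaves the binary network connected and the
global indices untouched.

**What the generator does not emulate:** diffusion signal formation,
fiber-orientation distributions, probabilistic tracking and its
false-positive structure, gyral geometry, and label-volume parcellation
(endpoints are captured by nearest centroid within 4 mm).  Passing tests
therefore demonstrate the correctness and calibration of the *pipeline* —
geometry, connectome algebra, and error control — not fidelity to any
particular acquisition.

## Connectome construction

Streamlines longer than 200 mm are removed (standard false-positive
control in whole-brain tracking; the cap is a parameter).  Each surviving
streamline whose endpoints land on two distinct nodes contributes 1 to the
NOS (number-of-streamlines) edge and its mean per-point FA to the TW-FA
(track-weighted FA) edge.  The TW-FA edge weight is the *sum* of
per-streamline mean FA: summation keeps NOS and FA information in one
weight (a mean-over-streamlines variant would discard bundle size, and the
aggregation is configurable at the matrix level since the choice is a
genuinely open one).

Edges enter a comparison only when present in a strict majority (> 1/2) of
the control sample *and* of the patient sample; presence in exactly half
excludes, which is the conservative reading of "more than half".

Raw TW-FA weights are not normally distributed, so each subject's masked
matrix is resampled into a Gaussian: the N nonzero upper-triangle weights
are replaced rank-for-rank by the sorted values of N fresh unit-normal
draws (smallest for smallest).  Structural zeros stay zero, ties are broken
by stable input order, and symmetry is restored.  The transform is an exact
rank replacement (Spearman correlation 1 with the input) whose output is
exactly Gaussian over included edges.  One consequence worth knowing when
reading nodal results: the transform is a per-subject rank renormalization,
so deleting streamlines from some edges *raises* the resampled values of
untouched edges in the same subject.  Lesions therefore produce genuine
decreases at transected nodes and compensatory apparent increases
elsewhere; the pipeline reports effect direction so decrease and increase
findings are never conflated.

## Graph indices and inference

Global indices follow the standard complex-network definitions on *binary*
adjacency matrices: mean local clustering (degree < 2 contributes 0),
characteristic path length over mutually reachable ordered pairs
(disconnected pairs excluded, per "between connected nodes" — not an
infinite penalty), global efficiency (mean inverse shortest path, 1/Inf =
0), and degree assortativity (Pearson over edge endpoints, both
orientations; undefined on regular graphs, returned as NaN with a
warning).  A weighted-efficiency variant was considered and rejected: the
quantity compared across groups is computed on adjacency matrices, and
mixing weighted distances into one index of four would break the shared
"binary backbone" interpretation.  Nodal strength is the row sum of the
gaussianized weighted matrix and may be negative.

Stage 1 compares each index between controls and one patient group with a
relabeling permutation test on the difference of means (default 10K
permutations at full scale, 1K at desk scale), add-one p-value estimator
(p is never 0 and never below 1/(n_perm+1)), FDR over the four indices.

Stage 2 runs a per-node two-sample t-test gated by Shapiro-Wilk normality
on each group and an F test of variance homogeneity (both at 0.05): pooled
variance when both gates pass, Welch otherwise — a gate failure downgrades
the test rather than aborting, and the node is flagged.  Benjamini-Hochberg
FDR across nodes ("FDR" is read as BH).  Constant values in both groups
make a node degenerate: p = 1, flagged.

Stage 3 is the four-step NBS: pooled t per masked edge; primary threshold
at the t-value of the two-sided uncorrected alpha 0.001 (the "principal
component threshold" is read as this primary threshold, matching the
canonical NBS procedure, not as a PCA step); connected components of the
suprathreshold graph scored by extent, extracted separately for decrease
and increase edges since effect direction is the finding of interest; and
a permutation null of the maximum component extent (default 5K, desk 500),
giving component-level FWER control at 0.05.  The NBS runs on the
gaussianized TW-FA matrices by default — the matrices every other stage
uses — with a switch for raw NOS matrices, since the weighting choice for
edge tests is ambiguous between the matrix-construction and the
statistical descriptions of the procedure.

The dual-acquisition strategy (two fields with complementary strengths) is
emulated as two generator profiles differing in streamline count, jitter
and FA noise; the intersection report keeps only edges and nodes
significant in both runs, intersected at the edge/node level.

## Numerical choices and degenerate inputs

* Segment-segment distance: two-pass clamped (Lumelsky) solution of the
  quadratic; exact to floating point, validated against dense sampling.
* Permutation p-values: add-one estimator everywhere; degenerate inputs
  (identical groups) give p = 1 without special-casing.
* Rank ties in resampling: stable input order; Gaussian draws are almost
  surely tie-free.
* The probability map counts voxel centers strictly inside each cylinder,
  matching the transection convention.
* Degenerate heads (jitter pushing a foramen outside the scalp, arcs
  longer than the hemisphere) raise errors rather than producing silent
  nonsense.
* Desk-scale problem sizes used by the test suite and the acceptance
  script: 12 nodes, 8 subjects/group, ~1,800 streamlines/subject, 1K/500
  permutations, 20 recovery replicates, 2,000 calibration replicates for
  the permutation test and 200 null cohorts for the NBS family error.

## Known limitations

* The spherical head and centroid parcellation are caricatures; distances
  to the trajectory are realistic in scale but not in shape.
* The planted effect is strong by design; desk-scale power for subtle
  effects is not claimed, and the full-scale configuration has not been
  run against real data by this package.
* Tissue deformation, catheter bending and multiple punctures are out of
  scope; the instrument is a rigid cylinder.
* The rank-renormalization side effect described above means nodal
  *increases* near a lesion should be interpreted as compensatory
  artifacts of the per-subject transform, not as biology.
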