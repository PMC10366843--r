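---
title: "Methods: path-finding based labeling of circle-of-Willis centerlines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: path-finding based labeling of circle-of-Willis centerlines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cowpath)
```

## The problem

The circle of Willis (CoW) is the ring of communicating arteries at the
base of the brain that joins the anterior (internal carotid) and posterior
(basilar) circulations. Quantitative vessel analysis — tortuosity metrics,
diameter distributions, segment lengths — needs each artery's centerline,
labeled by name. Fully manual tracing is slow; deep-learning segmentation
needs training data that is itself manually traced. This package
implements the middle road: segment the bright arteries, thin them to
centerlines, and let a path-finding algorithm connect two manually
annotated endpoints per segment into a labeled centerline.

The scientific crux is that the CoW contains *loops* (the anterior and
posterior communicating arteries exist to provide alternative routes), and
loops are exactly where naive path finding fails. A depth-first search
returns the first path it completes, which on a loop may be the long way
around; a shortest-path algorithm always returns the minimal route, which
is wrong whenever noise, touching vessels, or skeletonization artifacts
create a spurious shortcut across a tortuous vessel. The package makes
both failure modes reproducible on synthetic phantoms.

## Pipeline and assumptions

**Isotropic resampling.** TOF-MRA is typically acquired with finer
in-plane spacing (0.4–0.6 mm) than slice spacing (≈0.8 mm). Axes whose
spacing differs from the target (default 0.6 mm) are interpolated with
cubic splines (`stats::splinefun`, "fmm" end conditions — exact on
polynomials up to degree three). The output grid preserves the physical
extent: `n_out = round((n_in − 1)·s_in/s_out) + 1` samples at `k·s_out`,
with clamping at the boundary. Only axis-aligned spacing is honored;
oblique affines are out of scope.

**Coordinate convention.** All modules use 0-based integer voxel indices
in `(x, y, z)` order matching the NIfTI array layout. Annotated endpoint
coordinates are interpreted on the resampled grid, since annotation
happens after skeletonization of the interpolated data.

**Segmentation.** Arteries are bright on a dark background (flow-related
enhancement), so a global Otsu threshold (256-bin histogram, maximizing
between-class variance; deterministic) separates the two intensity
classes. Rather than thresholding globally — which would admit veins and
extracranial vessels — the mask is grown from three user seeds (right ICA,
left ICA, basilar artery) by 3D seeded region growing: a candidate voxel
is accepted when its intensity is within `t` of the running mean of the
region accepted so far, with the mean updated after every acceptance and a
fixed FIFO visiting order for determinism. The default tolerance links the
two stages: `t = seed intensity − Otsu threshold`, floored at 10% of the
seed intensity. Growing uses 6-connectivity by default (less leakage
across thin gaps; 26 is available). The three per-seed masks are combined
by voxelwise union. Under-segmentation is legal output: segments absent
from the mask surface downstream as "undetected", which in real cohorts
happens mostly to the PComms (hypoplasia or non-enhancement).

**Skeletonization.** The mask is thinned to one-voxel-wide centerlines by
sequential deletion of *simple points* (Bertrand/Malandain
characterization: exactly one 26-connected foreground component in the
26-neighborhood and one 6-connected background component in the
18-neighborhood touching a face) in six directional subiterations,
preserving endpoints (voxels with at most one foreground 26-neighbor).
Sequential re-testing at deletion time guarantees exactly that (i) the
skeleton is a subset of the mask and (ii) 26-connected component counts
are preserved — the two contracts downstream stages rely on. The
directional sweep keeps the result close to the medial axis; a solid
cylinder thins to its exact axis in the test suite.

**Graph construction.** Every skeleton voxel is a vertex (dense graph, not
a junction summary — path reconstruction needs every voxel); edges join
all 26-adjacent voxel pairs; weights are Euclidean distances between voxel
centers in mm. 26-connectivity is required for 1-voxel-wide diagonal
skeletons to stay connected, and yields the weight set `{s, s√2, s√3}` at
isotropic spacing `s`.

**Path finding.** Three methods share the graph and a common validator:

* *DFS* visits neighbors in a fixed lexicographic `(dz, dy, dx)` offset
  order, pushing onto a stack and backtracking when stuck; the stack at
  termination is the path. Valid and simple, but not shortest.
* *Dijkstra* returns the globally minimal-cost path; frontier ties are
  broken by the lexicographically smallest node coordinate, so results are
  platform-independent.
* *A\** expands by `f = g + h` with `h` the Euclidean distance (mm) to the
  goal. Because every edge weight is itself a Euclidean length, the
  triangle inequality makes `h` admissible and consistent, so A\* matches
  the Dijkstra cost on every query; `h` deliberately uses the same mm
  units as `g`.
* A brute-force exhaustive enumerator (with an expansion guard) serves as
  the independent oracle in tests and in the acceptance script, never in
  the pipeline.

`start == goal` returns a zero-length single-node path rather than an
error: adjacent segments share branch points (ICA top; BA top), so
degenerate queries are plausible.

**Endpoint handling.** Manual annotations routinely miss the one-voxel
skeleton, so both endpoints are snapped to the nearest skeleton voxel
(ties broken lexicographically) within a default radius of 3 voxels —
small enough not to jump to a neighboring vessel. A failed snap on a
non-sentinel segment is classified *undetected* (the vessel is absent from
the mask); a no-path result between two successfully snapped endpoints is
a distinct *failed* state, surfaced per segment without aborting the
subject. The sentinel `0 0 0` for both endpoints marks a segment the
annotator could not find.

**Evaluation.** Accuracy is `100·correct/(correct + incorrect)` with
undetected segments excluded from the denominator. Between-method
association per segment uses a two-sided Fisher's exact test on the 2×2
correct/incorrect table, with the minimum-likelihood convention: the
p-value sums the hypergeometric point probabilities of all tables with the
observed margins whose probability does not exceed the observed one,
within a relative slack of 1e-7 to absorb floating-point noise. Point
probabilities come from `stats::dhyper`, which works on a log scale
internally and is stable at the table sizes involved (N = 120). Reported
p-values are rendered to three decimals, with `<0.001` below 0.0005.
Correctness judgments are an explicit input, never computed from real
images: on phantoms a found path is "correct" when its mean distance to
the ground-truth centerline is below one voxel; on real data they must be
supplied by a reviewer file. Wall-clock timings are reported (graph
construction separated from path finding, since construction dominates)
but never asserted — they are hardware-dependent.

## The phantom generator

The phantom emulates what the algorithms actually consume: bright tubes
(default intensity 300) on a dark background (50) with additive Gaussian
noise (sd 10), wired with CoW topology on a 128³ grid at 0.6 mm — the
working resolution of the pipeline. Each vessel is a piecewise-linear
curve rasterized at radius 2 voxels; ground truth is the densely sampled
curve rounded to voxels. The defaults keep the vessel/background
separation at 25 noise standard deviations, comfortably inside the regime
where Otsu thresholding and region growing are exact; the end-to-end
recovery property is stated for noise up to 5% of the vessel intensity.

Variants realize the two documented failure substrates: `looped` adds an
A2-to-A2 arc over the AComm, giving DFS a long alternative route around
the anterior loop; `bridged` makes the right ICA strongly tortuous and
adds a short spurious bridge between its bends, so the shortest path
undercuts the true course (the shortcut is ~5.9 mm shorter in the default
geometry); `missing_pcomms` omits both PComms and writes sentinel
annotation lines. Geometry is schematic — circles and arcs, not
patient-derived shapes — because the path finders see only the skeleton
graph, i.e. topology and edge lengths. What the phantom does *not*
emulate: MRA physics (inflow saturation, flow artifacts), partial-volume
boundaries, veins and other confounding bright structures, and true
anatomical variability. Passing phantom tests therefore demonstrates
algorithmic correctness on CoW-like topology, not segmentation robustness
on clinical images; the published 60-subject counts shipped with the
package are the bridge to real-data behavior.

## Numerical and design choices

* Histogram bins for Otsu: 256; the threshold is the bin edge maximizing
  between-class variance, first maximizer on ties.
* Region-growing candidates are tested once, at dequeue time, against the
  current running mean; rejected voxels are not revisited. Monotonicity in
  the tolerance holds in the two-level intensity regime the phantoms
  exercise.
* Path-cost comparisons use 1e-12 slack; validator and oracle agreement
  use 1e-9; Fisher point-probability comparison uses 1e-7 relative slack.
* DFS neighbor order, Dijkstra/A* tie-breaks, FIFO growing order and a
  restored RNG state after phantom generation make every stage
  bit-reproducible from (inputs, seed).
* Degenerate inputs: constant volumes are a degenerate-input error for
  Otsu; empty masks skeletonize to empty skeletons; `start == goal` is a
  legal zero-length query; structured condition classes separate input,
  parse, snap, no-path, degenerate and oracle-refused errors.
* Test problem sizes are chosen to keep the suite fast while staying
  exhaustive where it matters: brute-force path enumeration on graphs of
  ≤ 12 nodes (200 seeded trials), exhaustive Fisher agreement for all
  tables with totals up to 30 plus 400–500 seeded tables with totals up to
  200, full-pipeline checks on 128³ phantoms, and component/weight
  contracts on every variant.

## Known limitations

* Only the 14 canonical CoW segments are labeled; A2/M2 and more distal
  segments are out of scope, as are disconnected-vessel detection
  (occlusions) and automatic seed or landmark localization.
* The region-growing rule is a running-mean criterion with a single
  tolerance; contrast-enhanced CT, where bone abuts arteries, would need a
  different segmentation front end.
* Skeleton-graph cycle structure includes small triangles wherever the
  thinned centerline mixes straight and diagonal steps; path lengths are
  therefore measured along the voxel chain, which can slightly undercut
  the smooth-curve length.
* The DFS result depends on the (documented) neighbor ordering; other
  orderings reproduce the same qualitative detour behavior but not the
  same voxel sequence.
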