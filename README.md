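# cowpath

Semi-automatic labeling of the arterial centerlines of the **circle of
Willis (CoW)** from 3D time-of-flight MR angiography (TOF-MRA), for
neuroimaging researchers who need named vessel segments (AComm, A1, M1,
ICA, PComm, P1, P2, BA, left/right) as a precursor to morphometry —
tortuosity, diameters, lengths — without training a segmentation network.

## What it does

The pipeline reduces vessel labeling to shortest-path search on a voxel
graph:

1. **Resample** the volume to isotropic resolution (cubic interpolation,
   default 0.6 mm).
2. **Segment** the arteries: Otsu threshold to calibrate an intensity
   tolerance, then 3D seeded region growing from three user seeds (right
   ICA, left ICA, basilar artery), united into one binary mask.
3. **Skeletonize** the mask to one-voxel-wide centerlines by
   topology-preserving thinning.
4. **Build a graph** `G = (V, E)`: every skeleton voxel is a vertex, every
   26-adjacent voxel pair an edge, with weight `w(u, v) = ‖u − v‖₂` in mm
   (so weights lie in `{s, s√2, s√3}` for isotropic spacing `s`).
5. **Connect annotated endpoint pairs** of the 14 canonical CoW segments
   with one of three methods:
   - **DFS** (Method 1): a stack-based maze solver — fast to set up, but on
     looped anatomy (the communicating arteries) it can return a long
     detour, since it accepts the first path found;
   - **Dijkstra** (Method 2): the globally shortest path by accumulated
     cost `g`;
   - **A\*** (Method 3): best-first search on `f = g + h` with the
     Euclidean heuristic `h(v) = ‖v − goal‖₂`, admissible because edge
     weights are themselves Euclidean lengths, hence cost-identical to
     Dijkstra.
6. **Evaluate**: per-segment correct/incorrect/undetected tallies,
   accuracy `100·c/(c+i)`, and two-sided **Fisher's exact tests** between
   methods (hypergeometric, minimum-likelihood convention).

A synthetic phantom generator builds CoW-topology volumes (with loops,
absent PComms, tortuous ICAs, and optional spurious bridges) together with
ground-truth centerlines, so the whole pipeline is testable without any
imaging data.

## Worked example

```r
library(cowpath)
ph   <- make_cow_phantom(seed = 1, variant = "complete")
mask <- segment_vessels(ph$volume, ph$seeds)     # Otsu + 3x region growing
skel <- skeletonize_3d(mask)
g    <- skeleton_to_graph(skel)
label_segments(g, ph$endpoints, method = "dijkstra")
#> <cow_labels> method dijkstra: 14 found, 0 undetected, 0 failed
#>   AComm    found         7.84 mm
#>   R-A1     found        14.34 mm
#>   ...
#>   BA       found        22.83 mm
```

All 14 segments are recovered; each `length_mm` is the summed Euclidean
edge weight of the returned centerline path.

The evaluation module, fed a published 60-subject method-comparison tally
shipped with the package, reproduces that study's statistics:

```r
evaluation_table(cow_reference_counts())
#> segment   m1_c  m1_i  m2_c  m2_i  m3_c  m3_i     p12     p13     p23  undet  total
#> AComm       19    25    44     0    36     8  <0.001  <0.001   0.006     16     60
#> ...
#> Total      614   121   714    21   706    29                            105    840
#> accuracy: dfs 83.5%, dijkstra 97.1%, astar 96.1%
```

The DFS accuracy collapses on the anterior communicating artery (43.2%)
because the anterior CoW loop offers an alternative route; the shortest-path
methods avoid that failure but can instead be fooled by spurious short
routes (see the `bridged` phantom variant).

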