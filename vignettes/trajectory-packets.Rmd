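---
title: "Methods: trajectory models, transforms and packet construction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trajectory models, transforms and packet construction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trajpacket)
```

This vignette is the package's own account of the models and procedures
it implements, the parameters that matter, the design choices made where
the design was genuinely open, and the known limitations.

## The data model

A `trajectory_set` mirrors the flat buffer layout a GPU line renderer
consumes: an $N \times 3$ coordinate matrix, per-vertex attribute
columns of length $N$ *in vertex order*, an $M \times 2$ segment index
list, a per-vertex track map, and one or more named geometry states
(alternative coordinates for the same topology; state 1 is always the
original). Consequences of this choice:

- Tracks are implicit (via the track map), so the flat buffers remain
  the single source of truth and serialization is a direct dump.
- Vertices *may* be shared between segments; the importers never
  duplicate vertices (each emits simple per-track chains), but the
  validator and renderer accept shared vertices, since the buffer
  format permits reuse.
- Attribute min/max are recorded at construction because the UI schema
  needs slider bounds without rescanning data; a recorded range may be
  deliberately wider than the data (`shared` ranges across datasets).
- Indices are 1-based inside R — the natural convention for R
  subsetting — and converted to 0-based only in the serialized packet,
  where the consumer is a JavaScript/GPU viewer. Keeping R code 1-based
  avoids a permanent off-by-one hazard in every subset operation.

Validation is report-based (`validate_trajectory_set()` returns all
violations rather than stopping at the first), because importers want
to show users everything wrong with a file at once.

## Import formats

- **CSV**: one row per vertex; rows grouped by id, ordered by the time
  column if the dialect names one (ties broken by file order, with a
  warning), else by file order. Defaults: comma delimiter, `.` decimal,
  case-insensitive header matching, every remaining numeric column
  becomes an attribute. Tracks are ordered by *natural id order*
  (numeric if all ids parse as numbers, else locale-independent
  lexicographic), which makes reader output invariant to row shuffles.
- **biotracks**: frictionless data package; each link becomes one
  track, objects ordered by frame, frame stored as `time`. Gaps inside
  a link are bridged by a straight segment.
- **TGMM XML**: one document per timepoint; tracks are maximal
  parent-chains. At a division the default `split-at-division` policy
  ends the parent track and starts a new track per child, keeping every
  track a simple polyline; `duplicate-history` instead copies the
  shared ancestry into each daughter track (the buffer format allows
  point reuse). Parent id −1 or a missing parent denotes a root; a
  dangling parent reference degrades to a track start with a warning
  rather than an error, since truncated exports are common.
- **SVF**: treated as a CSV linkage table with columns
  `cell_id,x,y,z,t,parent_id`; binary/pickled variants are out of
  scope. Cyclic linkage is an error.
- 2D inputs (no z column) are accepted and padded with $z = 0$, so
  planar trail data needs no preprocessing.

## Derived attributes

- `time`: input time verbatim (`raw`), shifted per track to start at 0
  (`zero`), or rescaled per track to $[0,1]$ (`unit`); without input
  time, the per-track vertex rank. Unit mode exists because tracks of
  different lifespans should be comparable on one slider.
- `angle`: the local turning angle, measured in 3D (not projected to a
  view plane) as the angle between consecutive segment directions, in
  degrees for slider readability. Endpoints default to 0 so straight
  tracks read uniformly 0; zero-length segments contribute angle 0.
- `dir_x/dir_y/dir_z`: the unit direction of each vertex's *outgoing*
  segment (incoming for the last vertex), so colour is constant along a
  straight segment. Degenerate vertices get $(0,0,0)$.

All enrichments are idempotent.

## Edge bundling

No specific bundling algorithm is mandated by the workflow this package
implements, so the choice was open. The implementation is a
kernel-density-style iterative centroid attraction: it is mesh-free,
has few parameters, preserves topology trivially, and produces the
"highways" effect on parallel structure. Per iteration, each
non-anchored vertex $p_i$ moves by
$s\,(c_i - p_i)$ with
$c_i = \sum_j w_{ij} p_j / \sum_j w_{ij}$,
$w_{ij} = \exp(-\lVert p_i - p_j\rVert^2 / 2\sigma^2)$ over all
vertices within radius $r$ (the vertex itself included at weight 1),
$\sigma = r/2$; then `smoothing_passes` synchronous Laplacian passes
pull each interior vertex half-way to the mean of its polyline
neighbours. Parameters, with defaults:

| parameter | default | meaning |
|---|---|---|
| `radius` | 0.05 | neighbourhood radius, fraction of bbox diagonal |
| `iterations` | 10 | attraction iterations |
| `strength` | 0.5 | step toward the centroid per iteration |
| `anchor_endpoints` | TRUE | keep track endpoints fixed |
| `smoothing_passes` | 1 | Laplacian passes per iteration |

Properties relied on by tests: strength 0 (or 0 iterations + 0
smoothing) is the identity; coincident geometry is a fixed point;
anchored endpoints never move; on the two-bundle fixture the mean
within-bundle nearest-neighbour track distance decreases strictly on
iteration 1 and never increases afterwards. The neighbourhood query
uses a uniform grid (cell size $r$, 27-cell stencil); a quadratic
brute-force search is kept as the independent oracle and must agree to
$10^{-9}$.

One boundary case worth recording: for two isolated parallel lines at
separation $d$ (strength 1, one iteration, no smoothing) the centroid
rule sends interior vertices to $d\,w/(1+w)$ and $d/(1+w)$ with
$w = e^{-2d^2/r^2}$ — i.e. *exactly* onto the midline only in the limit
$d \ll \sigma$. The tests assert the closed form exactly and
near-midline behaviour at small $d$, rather than pretending the
midline is reached exactly.

## Projections and axes

Planar projection is the standard orthogonal map
$p \mapsto p - ((p-q)\cdot n)n$; idempotence and residual direction are
tested to $10^{-9}$.

The Mercator state assumes a sphere (no ellipsoid model): radius
information is discarded, making the map invariant to distance from the
center — two points at the same angular position project identically.
The latitude clamp defaults to 85° to avoid the pole singularity of
$\ln\tan(\pi/4+\varphi/2)$. Output is embedded in 3D with $z = 0$ so
blending between the 3D view and the map is plain componentwise
interpolation. Segments whose wrapped endpoint longitudes differ by
more than $\pi$ cross the antimeridian seam; they are flagged in a
per-vertex `seam` attribute (1 on both endpoints) so a renderer can
hide them instead of drawing a line across the whole map. Longitudes
wrap into $(-\pi, \pi]$.

Automatic axes are the three bounding-box edges from the minimum
corner, with `tick_count` evenly spaced ticks labelled from the data
range; a zero-extent dimension collapses to a single tick without
error. Custom axes (e.g. continent outlines for geographic tracks) are
arbitrary polylines; `transform_axes()` applies the same point mapping
as the data, so axes follow every projection.

## Selections

Filters use closed intervals on both ends (boundary values pass) and
combine by AND, so filter evaluation is order-independent. Points
exactly on a cutting plane pass, which makes a plane and its flipped
copy complementary rather than jointly dropping the boundary. ROI
steps are order-dependent set algebra starting from the empty focus:
each sphere or box either unions, intersects, or subtracts its hits.
Selection is volumetric (3D containment), not screen-space: it needs
no camera and is reproducible from the data alone. At the default
track granularity a track is hit when *any* of its vertices is inside
— the behaviour needed to pick out, say, one hemisphere of a
tractography dataset by a half-space box; vertex granularity is
available for surgical cuts. Focus combines with visibility by AND: an
invisible vertex is never focus-rendered.

## Tours

Actions start `delay` seconds after the *end* of the previous action
(so edits to one action's duration shift everything after it, which is
the editing model users expect from a storyline timeline), and numeric
transitions interpolate linearly over `duration`; duration 0 is a step.
Camera transitions interpolate eye/look-at/up componentwise — a
documented simplification (no quaternion slerp); for the short moves
typical of tours the difference is negligible and the arithmetic stays
exactly reproducible.

Serialization is compact JSON (17 significant digits, so doubles round
trip bit-exactly) behind a `TP1.` version header, base64url-encoded.
The payload is capped at 2,953 bytes — the largest binary payload of a
version-40, error-correction-L QR code — since URL/QR sharing is only
sensible for tours with a limited number of actions; larger tours are
embedded in the packet's `tours.json` as plain JSON. QR *image*
rendering is not implemented (no suitable R dependency is declared);
the capacity contract is enforced so payloads are QR-ready.

## Headless renderer

The renderer exists to make visual semantics testable and to export
tour frames; it is deliberately simple and bit-deterministic:

- Segment depth = midpoint distance along the view axis; compositing
  is painter's algorithm back-to-front with the "over" operator, ties
  broken by segment index. This is not per-pixel depth-correct
  transparency — it is a *defined* order, which is what
  reproducibility needs.
- Integer Bresenham-style rasterization, no antialiasing; line width
  ≥ 1 px via orthogonal dilation.
- Colour modes: uniform; attribute through a 256-entry viridis-like
  table shipped as a plain-text packaged asset (so output never
  depends on platform palette code); orientation XYZ maps
  $(|d_x|, |d_y|, |d_z|)$ to RGB. Absolute values make the colouring
  invariant to segment direction reversal — the sign convention for
  negative components was open, and reversal invariance is the
  physically meaningful choice for undirected streamlines.
- Opacity: constant, or a linear ramp over an attribute's recorded
  range (e.g. time to opacity).

Frame export samples the tour at `fps`, giving
$\lfloor \mathrm{duration}\cdot\mathrm{fps}\rfloor + 1$ frames; each
frame equals a direct render at the tour-resolved parameters, which the
tests cross-check at transition midpoints.

## The packet

`build_packet()` writes `data.json` (flat coordinate list, 0-based
segment indices, attribute arrays in vertex order, each extra state's
coordinates, track map), `manifest.json` (counts, bounding box,
attribute/state descriptors, UI schema, format version "1"),
`tours.json`, `axes.json`, and an `index.html` stub. JSON was chosen
over a binary buffer for inspectability; numbers are limited to 9
significant digits and keys have a fixed order, so rebuilding from
equal inputs is byte-identical (tested by hashing). The UI schema
contains one range slider per attribute (bounds = recorded min/max)
plus one blend slider per extra state. Loaders reject unknown format
versions and any buffer whose length disagrees with the manifest. The
HTML stub is a replaceable packaged asset: the interactive WebGL viewer
itself is outside this package's scope, and the stub documents exactly
what a viewer must read.

## Synthetic study data

The fixture generators define the conditions every property is tested
under; all are driven by one integer seed through a private RNG stream
(byte-identical reruns, no global RNG pollution):

- `parallel_bundles`: two groups of near-parallel lines along x
  (length 10, group separation 5, per-track offset ±0.2, per-vertex
  jitter σ = 0.05) — bundling contraction, with group membership
  emitted as a `bundle` attribute so tests read ground truth instead
  of recomputing it.
- `helix`: unit-radius helices with constant parameter step — constant
  interior turning angle, closed-form checkable.
- `random_walk`: isotropic Gaussian walks — filters and ROI algebra.
- `grid2d_trails`: z = 0 lattice walks, standing in for planar trail
  data.
- `two_hemispheres`: walks confined strictly to the x > 0 or x < 0
  half-space (margin 0.1), labelled by a `hemisphere` attribute —
  half-space selections with exact expected counts.

Default test sizes are 10 tracks × 20 vertices (bundling), 50 × 20 =
1,000 vertices with 100 random selection states (selection oracle), and
4–6 tracks × 6–10 vertices elsewhere; the acceptance script uses the
same sizes. These fixtures emulate the *structural* features the
algorithms key on (parallelism, curvature, spatial separation), not the
geometry statistics of real embryos, brains, or migration routes — so
passing tests demonstrate algorithmic correctness, not biological
realism of any particular rendering.

## Known limitations

- No interactive viewer: the packet's `index.html` is a stub; the
  package's contract ends at correct, deterministic buffers.
- Transparency compositing is per-segment painter's order, not
  per-pixel depth sorting.
- No force-directed bundling with segment-compatibility measures; the
  kernel method trades some bundling quality for simplicity and
  testability.
- Mercator assumes a sphere; no other map projections.
- QR codes: capacity is enforced, images are not generated.
- No video container export (numbered PNG frames only).
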