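---
title: "Batch registration and gauge-based similarity of 3D facial shells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Batch registration and gauge-based similarity of 3D facial shells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Biological anthropologists and forensic analysts increasingly work with
stereophotogrammetric 3D facial scans: open triangular shell meshes in
millimetre units, with ragged trimmed borders and occasional holes where
preprocessing removed unreliable surface (beards, nose folds). Two
questions recur: how to place a whole collection of such scans into one
common coordinate frame without landmark annotations, and how to
quantify the mutual (dis)similarity of every pair. Done naively both are
quadratic in the number of faces — every pair must be registered and
measured — which is prohibitive beyond a few dozen scans. `facegauge`
implements a nearly-linear-time alternative: landmark-free generalized
Procrustes alignment driven by one-directional ICP, followed by indirect
pairwise measurement through the population's average face.

## Distance model

All similarity values rest on exact point-to-surface nearest neighbors:
for a vertex $v$ of face $f_i$, the closest point $\mathrm{near}(v,
f_j)$ may lie anywhere on the polygonal surface of $f_j$ — triangle
interiors, edges or vertices. Vertices with more than one nearest
neighbor (an event measured in fractions of a percent on real scans) are
excluded so that the mapping is a deterministic partial function.

The **directional mean distance** (`d_avg()`) is the average of
$\lVert v - \mathrm{near}(v, f_j)\rVert$ over the retained vertices, and
the symmetric **mutual distance** (`mesh_distance()`) is

$$\mathrm{dist}(f_i, f_j) = \max\bigl(d_{avg}(f_i, f_j),\,
d_{avg}(f_j, f_i)\bigr),$$

a modified Hausdorff distance: replacing the supremum with the mean
makes it robust to noise and outliers while keeping symmetry.

**Auto-cropping.** An open mesh knows where it ends: an edge incident to
exactly one triangle is a boundary edge. When the nearest neighbor of
$v$ lies on a boundary edge (or at a boundary vertex) of $f_j$, $v$
hovers over surface that $f_j$ simply does not cover — a ragged border
strip or a hole — and its distance is an artefact of trimming, not of
facial shape. Such vertices are excluded wherever `crop = TRUE` (the
default in measurement). Cropping is what makes one-directional ICP
usable inside a Procrustes loop: the dominant source of direction
asymmetry is non-overlapping border surface, and removing it makes
registering A onto B and B onto A nearly equivalent (the package's
asymmetry tests quantify exactly this on ragged synthetic pairs).

## Registration

`icp_register()` is plain point-to-point ICP: pair the (sub-sampled)
moving vertices with their closest points on the fixed surface, drop
ambiguous pairs and — from the second iteration on — cropped pairs, fit
the least-squares rigid transform in closed form (orthogonal Procrustes
with reflections excluded; an optional uniform scale is off by default
because distances are reported in millimetres), compose, repeat. The
first iteration is never cropped, so that poorly overlapping starts can
still pull the surfaces together. Iteration stops when the mean pairing
distance changes by less than `delta_threshold` or at `max_iterations`.

Sub-sampling is drawn once per registration, not per iteration, which
keeps the stopping criterion stable. Three strategies are provided:
uniform random sampling (the recommended default, `n_samples = 1000`),
one random vertex per cell of a 3D grid sized by bisection, and the
top-$n$ vertices by discrete Gaussian curvature (angle deficit over one
third of the incident area; boundary vertices use a half-disc angle).

### Convergence behaviour and the stopping threshold

Point-to-point ICP converges linearly, and its rate is governed by how
strongly the surface constrains tangential sliding: closest-point
pairings only "see" the component of a misalignment along the local
surface normals. On feature-rich, wrapped surfaces the contraction is
brisk; on smooth shallow shells the tangential modes contract by only a
fraction of a percent per iteration. Two practical consequences are
built into the package's defaults and tests:

* The default `delta_threshold = 0.05` mm stops iteration when the
  *improvement* stalls, which is the right operating point for routine
  batch work on real scans — a handful of iterations per face. It is
  not a guarantee that the *error* is below 0.05 mm.
* When an experiment needs exact pose recovery (for example the
  known-transform recovery checks in the test suite), ICP is run to
  convergence with `delta_threshold = 1e-6` and a few hundred
  iterations, and auto-cropping is disabled: a noise-free displaced copy
  has no non-overlapping surface to crop, and discarding the rim would
  discard precisely the tilted normals that pin down lateral motion.

## Batch registration (GPA with ICP)

`gpa_register()` replaces landmark-based Procrustes superimposition with
surface registration:

1. clone one face (the analyst's choice) as the template;
2. register every face onto the current template with one-directional
   ICP;
3. transmute the template toward the population: every template vertex
   moves to the centroid of its nearest neighbors across the registered
   faces, $v \leftarrow v + \frac{1}{|F|}\sum_f (\mathrm{near}(v,f) -
   v)$, skipping faces where the neighbor is ambiguous or cropped;
4. repeat until consecutive average faces differ by less than
   `psm_threshold = 0.3` (measured with `mesh_distance`, used here as a
   Procrustes-style surface metric between iterates), or after
   `max_gpa_iterations`.

The orientation of the averaging step matters: moving vertices *toward*
the neighbor centroid makes a single-face population a fixed point and
makes symmetric populations average to their centre, both of which the
test suite asserts; the opposite orientation is unstable. Each iteration
costs one registration and one averaging pass per face — linear in the
population — and two to three iterations suffice in practice. Faces
whose registration fails for lack of overlap are excluded permanently
with a warning.

## Batch measurement through the average-face gauge

With all faces in the average face's frame, pairwise distances are
approximated without comparing pairs directly. One nearest-neighbor
pass per face fills a cache over the average face's vertices
(`build_cache()`, linear in the number of faces); the pairwise matrix is
then assembled from cached values only (`indirect_matrix()`, quadratic
but with trivially cheap, independent cells).

Two cached representations are offered. The *euclidean* method stores
the closest point itself and measures
$\lVert \mathrm{near}(v,f_i) - \mathrm{near}(v,f_j) \rVert$; the
*relative* method stores a single signed scalar per record — the
nearest distance, positive if the neighbor lies in the half-space of
the average face's vertex normal (ties at zero dot product count as
positive), negative otherwise — and measures the absolute difference of
two scalars. The relative method needs a third of the memory and no
arithmetic beyond subtraction, at the price of requiring consistently
oriented normals, which the package recomputes after every averaging
step. On smooth populations the two agree to within a few percent.

Cell $(i,j)$ averages only the gauge vertices valid for *both* faces
(unique neighbor, and under cropping not on either face's boundary);
vertices invalid for one face are dropped from that pair only. Pairs
with no jointly valid vertex are flagged missing and serialized as
empty CSV cells, never as 0.

For validation the package also ships the two quadratic baselines:
`direct_matrix(mode = "FR")` measures all pairs directly after batch
registration, optionally restricted to the surface covered by the
average face so that direct and indirect measurements cover the same
region; `mode = "BL"` additionally registers every pair from scratch in
both directions and keeps the better one.

## Synthetic study conditions

No real scan database ships with the package; `generate_shell()` and
`generate_population()` create fully self-contained stand-ins. A shell
is an angular patch of an ellipsoid with semi-axes 75/85/95 mm spanned
by ±75° of azimuth and ±55° of elevation — the wrap of an ear-to-ear
facial scan — displaced along the outward normal by a dozen smooth
Gaussian features of up to 5 mm (the relief scale of noses, sockets and
lips), with optional punched holes, tangentially jittered ragged
borders, and i.i.d. vertex noise. The wrap is deliberate: a flat cap
leaves surface normals nearly parallel, tangential misalignments almost
invisible to ICP, and registration ill-conditioned; the wrapped patch
with three distinct semi-axes has no rotational near-symmetry. Feature
centres are drawn in a fixed angular reference frame, so shells
generated from one seed but trimmed to different wraps share their
geometry the way two trims of one scan do.

Populations share a base shell; each member adds its own smooth
variation features (default amplitude 4 mm at eight random surface
points) and a recorded rigid jitter (up to 10° and 10 mm by default).
These defaults put post-registration pairwise distances at roughly 1–2.5
mm, the low-millimetre similarity scale observed between real facial
scans, and pre-registration distances a few times larger.

Default problem sizes in the tests and the acceptance script are grids
of 32–40 vertices per side (≈1000–2300 vertices, ≈2000–4400 triangles)
and populations of 10–12 faces; real scans are one to two orders of
magnitude denser, and the algorithms are linear (registration,
caching) or quadratic (matrix assembly) in exactly the same way at
either scale.

What the generator does *not* emulate: anatomically structured shape
covariance (it uses independent random features, not a morphable face
model), scanner-specific noise spectra, texture, expression or pose
variation, and strongly non-uniform vertex densities. Passing tests
demonstrate the correctness and internal consistency of the geometry
pipeline under realistic scales, not recognition performance on real
faces.

## Numerical choices

* **Exact nearest queries.** The spatial index examines triangles in
  ascending order of the provable bound (distance to centroid minus
  circumradius) and stops when no remaining triangle can beat or tie
  the best hit, so accelerated results equal an exhaustive scan
  bit-for-bit; the test suite checks this against an independent
  brute-force oracle.
* **Tie tolerance.** Exact equality of two nearest distances is
  meaningless in floating point; a hit is ambiguous when another
  triangle attains the minimum within a relative `1e-9` *and* its
  closest point lies more than `1e-6` mm away — the separation test
  prevents the shared edges and vertices of adjacent triangles from
  masquerading as ties.
* **Boundary classification.** The closest-point routine produces exact
  0/1 barycentric coordinates in clamped regions, so "lies on a
  boundary edge" is a test of a barycentric coordinate below `1e-9`
  against the precomputed boundary-edge table.
* **Degenerate input.** Zero-area triangles are dropped at load with a
  warning; isolated vertices get flagged `NA` normals and are excluded
  from the relative measure; transform estimation refuses fewer than
  three or (nearly) collinear pairs.
* **Determinism.** Every stochastic step (sampling, synthetic
  generation) derives from explicit integer seeds; repeated runs are
  bit-identical, which the suite asserts for ICP, caches and the CLI
  pipeline.

## Limitations

The method assumes reasonably dense, roughly uniform meshes and rough
pre-alignment (an optional centroid initializer is provided, global
pre-alignment is out of scope). Shells whose geometry approaches a
surface of revolution registration cannot pin down — spheres, shallow
caps — converge slowly or not at all, a property of point-to-point ICP
itself. The average face depends mildly on the template choice, which
is left to the analyst. Bidirectional/symmetric ICP cost functions,
point-to-plane variants, landmarking, texture and mesh repair are
deliberately outside the package's scope.
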