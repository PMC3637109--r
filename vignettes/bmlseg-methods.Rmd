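---
title: "Methods: semi-automated BML segmentation and volumetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: semi-automated BML segmentation and volumetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

Bone marrow lesions (BMLs) appear on sagittal fat-suppressed knee MRI as
ill-defined areas of high signal intensity inside the tibia and femur. Their
volume, and especially its longitudinal change, tracks osteoarthritis
progression, but fully manual volumetry is slow and reader-dependent.
`bmlseg` implements a semi-automated measurement: the reader only marks
coarse bone boundaries; everything downstream — bone refinement, lesion
detection, false-positive elimination, regional volumetry — is automatic
and deterministic.

This vignette documents the three processing stages, the tunable
parameters, the numerical choices behind the implementation, what the
synthetic phantom does and does not emulate, and the known limitations.

## Stage 1: bone segmentation

The reader marks a handful of points per sagittal slice along each bone's
boundary, flagging the points on the articular (joint-facing) surface. The
points are interpolated by a closed periodic cubic spline (chord-length
parameterization, `stats::spline`) and the interior is rasterized by an
even-odd fill over voxel centers. This coarse region is then refined by
edge-based curve evolution: a geodesic active contour with edge-stopping
function

$$ g = \frac{1}{1 + |\nabla (G_\sigma * I)|^2 }, $$

computed per slice after rescaling intensities to $[0,1]$, with the
Gaussian scale $\sigma$ expressed in millimetres and converted per axis to
pixels (the in-plane grid is anisotropic, e.g. $0.357 \times 0.511$ mm).
Bone has well-defined cortical boundaries, so an edge-driven evolver is the
right tool, and the initial curve does not need to hug the boundary — the
contour advects along $\nabla g$ into the nearest edge minimum.

Numerically we use the morphological discretization of the geodesic
active contour flow (binary state, curvature smoothing by alternating
sup–inf/inf–sup line filters, advection by the sign of
$\nabla g \cdot \nabla u$, balloon force off). It is unconditionally
stable, parameter-free apart from the smoothing count, and converges to
within one voxel of an ideal step edge. Convergence is declared when the
per-iteration mask change stays below 0.1% of the mask area for 5
consecutive iterations, when the state repeats (morphological schemes can
enter short limit cycles; we hash the last 8 states), or at 500 iterations.
Each refined slice is reduced to the single connected component best
overlapping its initialization, holes filled; slices are stacked into the
3D bone mask. Refinement is run slice-wise in 2D because marking, display
and quality control are all per-slice; the 3D mask is assembled afterwards.

Each boundary voxel inherits an articular flag from the nearest segment of
the marked polygon (a segment is articular when both endpoints are
flagged; distance ties break toward articular). The articular surface
anchors the proximity filter of stage 3.

The central sagittal slices — by default 9 slices, 2.7 cm at 3 mm slice
thickness — are excluded from the analysis before lesion detection: bone
borders there (tibial spines, trochlea) are unreliable to segment and the
marrow signal is heterogeneous. The window is centered on the volume
midpoint, left-biased when parities differ, since no anatomical landmark
is available in the data files.

Before lesion detection the bone mask is eroded by one in-plane voxel.
The refined boundary is accurate to about one voxel, and a one-voxel halo
of bright soft tissue inside the nominal mask would otherwise be
indistinguishable from lesion signal adjacent to the articular surface.

## Stage 2: BML candidate segmentation

Detection inside each bone is fully automatic and uses only the mean and
standard deviation of the marrow intensity:

1. **Gaussian null.** Sample mean and SD of all bone-interior voxels
   (sample SD, $n-1$; at least 30 voxels; a constant region is a
   degenerate null and aborts the pass).
2. **Upper-tail p-values.** $p = 1 - \Phi((I - \hat\mu)/\hat\sigma)$ per
   voxel — BMLs are hyperintense.
3. **FDR thresholding.** Benjamini–Hochberg step-up at level
   $q = 0.05$. The implied intensity threshold is the minimum intensity
   over rejected voxels; a larger $q$ gives a lower threshold and more
   candidate voxels. p-values are pooled per bone per volume.
4. **Initial curves.** The rejected voxel set is consolidated by an
   in-plane morphological closing (radius 2): the supra-threshold voxels
   of a genuine lesion are dense but not contiguous, and curve evolution
   needs contiguous seed regions to evolve. Isolated noise rejections stay
   isolated and are eliminated by the length penalty.
5. **Region-based curve evolution.** Two-phase piecewise-constant
   (Chan–Vese-type) refinement restricted to the bone domain, minimizing
   $$ E(u) = \sum_{u=1} (I - c_1)^2 + \sum_{u=0} (I - c_2)^2 + \mu\, L(u), $$
   where $L$ counts in-plane 4-neighbour label-discordant voxel pairs and
   intensities are rescaled to $[0,1]$ within the domain, making
   $\mu \in [0,1]$ dimensionless. The default is $\mu = 0.28$.

The evolution is a narrow-band scheme: each iteration solves the banded
problem *exactly* as a minimum s–t cut (our own Dinic max-flow) over a
shell of half-width 2 voxels around the current front, with the eroded
region interior frozen as foreground and the far exterior as background,
then refits $c_1, c_2$. Three properties follow by construction:

* the previous labelling is feasible in every banded problem, so the
  energy never increases from initialization to convergence;
* the front moves at most 2 voxels per iteration, so evolution is local:
  a homogeneous region far from any seed is never relabelled, and a
  lesion wider than the band can only be reshaped at its boundary, never
  deleted wholesale — the defining behaviour of curve evolution, which a
  global minimizer of the same energy does not share;
* an isolated bright voxel is always removed at $\mu = 0.28$ (its four
  boundary edges cost $4\mu > 1$, the largest possible data gain on
  $[0,1]$ intensities), which is exactly the intended suppression of
  small discrete bright specks; at $\mu = 0$ specks survive.

The whole procedure is run **twice**: the second pass refits the null and
the p-values on the bone voxels excluding the first-pass lesions, which
recovers dimmer lesions whose contrast was diluted when bright lesions
inflated the null SD. We refit both the null and the threshold in pass 2
(the alternative — recomputing only the threshold — is noted as an open
reading; refitting is the more complete interpretation). The final
candidate mask is the union of the two passes, with per-voxel pass
provenance retained. Exactly two passes are run; the pass loop is not
iterated to convergence.

## Stage 3: refinement and quantification

Candidates are stacked into 3D and decomposed into connected components
(26-connectivity by default). Two rules eliminate false positives
(connective tissue, artifacts, isolated specks that survived):

1. the minimum 3D Euclidean distance from the component to the articular
   surface, computed in world millimetres with the anisotropic spacing,
   must be at most 10 mm (measured from the component's nearest voxel —
   the conservative reading of "distance to the articular surface");
2. the component must span at least 2 distinct slices ("more than one MR
   image").

Retained components are assigned to the four tibiofemoral regions (medial
and lateral femur and tibia). Medial versus lateral is decided by the
component centroid's slice index against a configurable sagittal divider
slice — supplied with the contour file (e.g. the slice through the tibial
spines) or defaulting to the volume midpoint; ties go medial, and which
side of the divider is medial is configurable (knee laterality is not
recorded in the image files). Component volume is voxel count times voxel
volume ($0.357 \times 0.511 \times 3.0 = 0.547$ mm³ at the default
spacing); regional volumes are exact sums of member components.
Longitudinal change is the per-region difference of two independent,
deterministic runs, so identical inputs give exactly zero change.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `q` | 0.05 | — | FDR level; larger = lower intensity threshold |
| `mu` | 0.28 | — | boundary-length penalty; larger = smoother, fewer specks |
| `max_articular_dist_mm` | 10 | mm | articular-proximity filter |
| `min_slice_span` | 2 | slices | multi-slice filter |
| `n_central_excluded` | 9 | slices | central exclusion window (2.7 cm) |
| `connectivity` | 26 | — | 3D component neighbourhood |
| `smoothing_sigma` | 1.0 | mm | edge-map Gaussian scale |
| `max_iters` / `convergence_tol` | 500 / 0.001 | — | evolution controls |

`q` and `mu` are the two method-level tunables; the defaults are the
values used for every experiment in the package's tests.

## The synthetic phantom

No clinical MR data ships with the package; the generator
(`phantom_spec()`, `generate_phantom()`) builds the entire validation
bench. It emulates, at the target acquisition geometry
($0.357 \times 0.511 \times 3$ mm, 24 sagittal slices):

* two convex super-ellipsoidal bone bodies (femur above tibia across a
  joint gap), darker than the surrounding soft tissue, with the
  joint-facing half of each bone's boundary tagged as ground-truth
  articular surface;
* planted ellipsoidal BMLs adjacent to the articular surfaces, with
  contrast expressed in multiples of an intensity unit equal to the
  default noise SD (so contrast 5 means SNR 5), placed clear of the
  central exclusion window and on opposite sides of the medial/lateral
  divider;
* three decoys, one per false-positive rule: a deep lesion more than
  10 mm from the articular surface, a single-slice lesion, and a bright
  extra-osseous blob that tests bone-mask confinement;
* additive Gaussian noise (matching the method's Gaussian null; a Rician
  option exists but is off by default) and seeded jitter of the simulated
  manual marking (default 2 voxels).

Everything is seeded and bit-reproducible. The truth table records each
blob's exact voxel count and volume, so the construction is its own
oracle: end-to-end tests compare recovered volumes against it across
cohorts of 20 phantoms with lesion volumes spanning roughly 200–3000 mm³,
the scale of tibial BML volumes reported in knee-OA cohorts.

The phantom deliberately does *not* emulate: anatomically realistic bone
shapes (convexity suffices to exercise every stated rule), bias fields,
chemical-shift or motion artifacts, partial-volume boundaries, subchondral
cysts, or inter-scanner intensity variation. Passing the phantom suite
therefore demonstrates algorithmic correctness — geometry, thresholds,
filters, determinism, volume arithmetic — not clinical performance on
real MRI, which the original validation addressed against semiquantitative
scores and cartilage morphometry.

Problem sizes used by the test-suite and the acceptance script (phantom
grids of $240 \times 120 \times 24$, cohorts of 12–20 phantoms, 50 small
energy-check phantoms) were chosen so the full bench runs comfortably on a
single CPU while still spanning the reported lesion-volume range.

## Reliability statistics

`icc()` implements the two single-measure intraclass correlations of the
Shrout–Fleiss taxonomy used in reader studies: ICC(3,1) (two-way mixed,
consistency) for intra-reader agreement — invariant to a reader's additive
bias — and ICC(2,1) (two-way random, absolute agreement) for inter-reader
agreement, which penalizes systematic offsets. Both come from the exact
two-way ANOVA mean squares; a zero between-subject variance leaves the
coefficients undefined and raises an error. Average-measure ICCs and
confidence intervals are out of scope.

## Design decisions on genuinely open points

* **Edge-based evolver.** The specific edge-based technique is not pinned
  down by the method description; we use the canonical geodesic active
  contour with the $1/(1+|\nabla G_\sigma * I|^2)$ stopping function, in
  its morphological discretization, with the balloon term off.
* **Region-based evolver.** Implemented as the exact banded minimization
  described above rather than a level-set PDE: it preserves the energy,
  the locality and the $\mu$ semantics while being deterministic and free
  of CFL/reinitialization tuning.
* **Contour file format.** The original workflow used an interactive GUI;
  here marked points travel as JSON (per-slice ordered `[x, y,
  articular]` triples, 0-based continuous voxel coordinates) so the
  pipeline is scriptable and testable.
* **Medial/lateral divider and central window centering.** Neither is
  anatomically defined in the inputs; both are configurable with
  documented defaults (volume midpoint; ties medial).
* **Spline initialization.** A periodic cubic spline through sparse
  marked points overshoots at sharp corners (a 4-point "square" marking
  bulges outward). This is immaterial in practice — bone cross-sections
  are smooth and refinement corrects the initialization — but worth
  knowing when marking very sparse, highly angular contours.

## Known limitations

* BMLs and subchondral cysts are segmented as one class; no location
  priors or intensity-distribution features are used beyond mean and SD.
* The central (patellofemoral) region is excluded by design.
* Lesions thinner than the evolution band on every slice and dimmer than
  the FDR threshold can be missed; very small lesions lose their
  single-voxel-thick end slices to the length penalty, so volumes of
  sub-300 mm³ lesions are biased slightly low.
* The medial/lateral split is purely sagittal-slice-based, not an
  anatomical compartment boundary.
* Distances use voxel centers; sub-voxel surface geometry is not modelled.
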