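---
title: "Two-view 3D coronary vessel reconstruction: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-view 3D coronary vessel reconstruction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(angiorecon)
```

This vignette is the package's account of its science: what is modelled,
which parameters matter and why their defaults are what they are, what the
synthetic phantoms do and do not emulate, and where the design was genuinely
open and a choice had to be made.

## The problem and the model

A coronary angiogram is a cone-beam projection: X-rays diverge from a focal
spot, pass through the contrast-filled lumen, and land on a detector at
source-to-intensifier distance (SID). A single projection cannot measure
depth, foreshortening, curvature or torsion. With **two** projections at
different gantry angles and known geometry, a space curve is recoverable:
each image point back-projects to a ray, and corresponding rays intersect
(epipolar constraint). Two views are *not* enough for arbitrary
cross-sections, so the lumen is modelled as locally circular — every
quantity downstream (radius profile, stenosis severity, tube mesh) inherits
this assumption.

The pipeline is: vessel enhancement → centreline between user-chosen
points → wall delineation → two-view 3D reconstruction → Frenet tube mesh.

## Geometry conventions

World frame: isocenter at the origin; x = patient left, y = posterior,
z = superior. At zero gantry angles the source sits at `(0, SOD, 0)` and
the beam runs along −y; the primary angle (LAO positive) rotates the gantry
about +z, the secondary (cranial positive) about +x, composed in that
order. Image rows grow toward the patient's feet, columns toward the
patient's left; the principal point is the raster centre.

The source-to-isocenter distance SOD is not always archived with the image;
it fixes the magnification `M = SID / depth`. The constructor defaults to
`SOD = SID/2` (a generic C-arm); supply the real value when known, since
radii scale with `1/M`.

## Stage parameters

**Vesselness** (`vesselness_filter`). 2D Hessian-eigenvalue vesselness with
blobness sensitivity `b = 0.5` and structureness sensitivity auto-set to
half the maximal structureness per scale — the standard calibration.
Scales default to {1, 2, 3, 5, 8} px, spanning septal branches to proximal
segments at typical angiographic resolution (~0.2–0.4 mm/px). The Hessian is
scale-normalized with exponent γ = 0.75, the ridge exponent: a Gaussian
ridge of width σ then peaks at scale s = σ, which is the property the test
suite checks. Polarity defaults to dark-on-bright (iodine contrast).

**Hysteresis** (`hysteresis_threshold`). Defaults are quantiles (q80/q95)
of the *whole* vesselness map, floored at 2 %/5 % of the maximum. The floor
matters: on clean synthetic images the background response is exactly zero,
and quantiles of the nonzero support alone would discard most of the vessel.

**Skeleton points** (`skeletonize_and_label`). Bifurcations are skeleton
pixels whose 8-neighbourhood crossing number is ≥ 3 (transition count
around the ring); a plain ≥ 3-neighbour rule misfires on diagonal
staircases. Adjacent bifurcation pixels are merged; the merged point is the
cluster pixel nearest the centroid, so it always lies on the skeleton.

**Centreline** (`smooth_centreline`, `refine_centreline_ridge`). Pixels
within 2 px of a bifurcation are excluded from the spline support (thinning
pulls branch-point pixels off the vessel axis); their coordinates are kept
as correspondence anchors for the two-view matching. The spline uses one
degree of freedom per ~3 support pixels — near-interpolation that still
damps single-pixel staircase noise; exact interpolation of a binary
skeleton would contradict the smoothness the spline is there to provide.
The curve is then refined onto the vesselness ridge by a parabolic
sub-pixel fit along each normal. This refinement halves the residual 2D
error (to under 0.1 px on phantoms) and is the main reason the 3D
centreline reaches ~0.1 mm RMS: lateral centreline error in one view maps
to depth error amplified by `1/sin(view separation)`.

**Wall delineation** (`extract_vessel_walls`). Ten candidate nodes per
normal at 1 px spacing cover walls out to 10 px from the centreline. The
path merit combines a node reward `e_m` with two coherence penalties: the
gradient/second-derivative ratio difference (weight β) and the squared edge
orientation difference (weight 1 − β). β defaults to 0.75, weighting edge
magnitude over direction smoothness. Three choices here were genuinely
open:

* *The node reward.* `e_m` is not pinned down by the cost function's
  source; we define it as the gradient magnitude, rescaled to \[0, 1\] over
  the grid and gated by `cos²` of the angle between edge orientation and
  the local normal. The gate encodes what a vessel-wall edge *is* — an edge
  running along the vessel — and is what makes the delineation insensitive
  to branch ostia and other crossing structures: a perpendicular branch
  edge earns no reward, so the path has no incentive to detour onto it.
* *The stabilizer ε.* The ratio `e_gm/(e_hm+ε)` degenerates exactly at an
  ideal edge, where the second derivative crosses zero: with a tiny ε the
  ratio explodes there and its stage-to-stage difference dominates the
  merit by orders of magnitude, measurably repelling the path from true
  walls (on the stenosed phantom the apex radius error went from ~50 % to
  ~2 % when ε was raised). We default ε = 0.5 — half the normalized
  feature range — which bounds the ratio and lets it act as the intended
  mild coherence term. Any positive ε can be supplied.
* *Direction wrapping.* Gradient direction is taken modulo π (an edge has
  no sign) and differences are wrapped to (−π/2, π/2\]; otherwise a
  consistent wall produces spurious π jumps.

The optimizer is exact (stage recursion over K² transitions; ties break
toward the node nearer the centreline, and the first/last stage are pinned
to the max-gradient node). Two post-passes refine the discrete solution:
parabolic sub-node interpolation of the gradient peak (removing the
half-spacing quantization, which otherwise dominates the radius error at a
tight stenosis), and a model-based correction of the systematic inward bias
of gradient-maximum edges on cylindrical density profiles
(`chord_edge_radius`: the offset is a smooth monotone function of `R/σ`,
computed numerically once and inverted). Stages where no wall-aligned edge
exists anywhere on the normal — a branch ostium interrupts the wall — are
bridged by interpolating the wall offset from flanking supported stages,
as quantitative coronary analysis systems do; "no support" means the best
gated edge response is below half the per-curve median.

**Two-view reconstruction** (`correspond_and_reconstruct`). Midpoint-of-
common-perpendicular triangulation; monotone epipolar matching seeded by
arc length with bifurcation anchors; per iteration the 3D curve is
resampled to uniform *3D* arc length and re-projected, which is what
removes foreshortening (foreshortened stretches receive more samples);
stop at max update < 1e−3 mm or 20 iterations. Orientation of the second
curve is auto-checked by endpoint epipolar consistency. Matching degrades
where the epipolar line is tangent to the vessel; an error is raised if
more than 20 % of epipolar lines miss the second curve entirely.

**Curvature and torsion** (`add_frenet_frames`). κ and τ are second- and
third-derivative quantities; differentiating a measured curve amplifies
noise at wavelength λ by (2π/λ)³. Derivatives are therefore taken on a
spline-smoothed copy with ~one df per 7 mm of arc — enough to resolve
bending at the coronary scale, chosen once from that physical argument.
The model's stored centreline is *not* replaced by the smoothed copy.
Straight runs leave the Frenet normal undefined; the frame is continued by
parallel transport (rotation-minimizing) so it never flips.

**Tube mesh** (`build_tube`). Rings of `s` vertices (default 16) at
`X + r(N cos θ + B sin θ)`, with θ spaced by 2π/s over \[0, 2π) — no
duplicated seam vertex — stitched with 2s triangles per ring pair and
optional end caps (watertight when capped). Branch tubes are exported as
separate meshes; merging them into one watertight tree is out of scope.

**Annotator consensus** (`ml_consensus`). Two-class confusion-matrix EM
(Dawid–Skene): majority-vote initialization, tol 1e−6 on posteriors, 100
iterations max. Regularization (pseudocount 0.5) is applied only where the
MLE degenerates — a truth class with no posterior mass, a constant-label
annotator, or zero cells that make an observed item impossible under both
classes — so the clean cases (e.g. unanimous annotators) recover exact
identity confusion matrices. The per-annotator quality score is the
prior-weighted off-diagonal mass.

## The phantom world

`make_phantom` + `render_views` define the package's test world: a
parametric 3D curve (line / arc / helix / perpendicular-branch), radius
1.2–1.5 mm (typical proximal coronary calibre), optional Gaussian-profile
stenosis whose minimum radius is exactly `(1 − severity)·r0`; rendered with
chord-length attenuation (the projection of a cylinder is proportional to
the X-ray chord through it), dark-on-bright, plus additive Gaussian read
noise of sd 0.02 on a 0.9 background with 0.5 vessel contrast — moderate
fluoroscopic noise. The canonical geometry is SID 1000 mm, SOD 750 mm,
0.4 mm pixels, 256² rasters, views 0° and 30° primary.

Orientation choices are part of the stated world and matter: the helix axis
lies along z so that the epipolar coordinate of a primary-rotated view pair
grows monotonically along the vessel (each epipolar line meets the second
curve once), and its default pitch (a = 10 mm, b = 6 mm, 0.75 turns) keeps
the projected bend wider than the lumen half-width. Both degeneracies the
defaults avoid are real: a vessel segment running inside an epipolar plane
cannot be reconstructed from that view pair, and a projected bend tighter
than the vessel width fills into a blob whose skeleton cuts the corner.
Clinically both are avoided by view selection; here they are avoided by
phantom design, and the package raises errors rather than guessing when it
detects the first.

What the phantom does *not* emulate: scatter, detector MTF and spectral
beam hardening; ECG-gated motion; overlapping vasculature and catheters;
non-circular (eccentric) lumina. A green test therefore establishes the
correctness of the geometry and optimization chain under the stated imaging
model — not robustness to every clinical artifact. In the same spirit, the
chord-profile edge-bias correction assumes the only blur is the package's
own Gaussian feature scale; on real images with system blur it will
under-correct, and radius calibration against a catheter of known size
remains the practice.

## Numerical choices and degenerate inputs

* Derivative kernels are truncated at 3σ and DC-corrected so constant
  image offsets are exactly invisible — the vesselness of a constant image
  is exactly zero, and vesselness is invariant to additive offsets.
* Hausdorff distances use the expanded-form distance matrix for speed but
  recompute the selected nearest pairs stably, so `δ_H(X, X) = 0` exactly
  and the result matches the brute-force double loop to machine precision.
* Curves are compared as dense resampled point sets (0.25 px step) so the
  set Hausdorff approximates the curve distance; references are cropped to
  the span the extraction actually covers (thinning erodes vessel ends by
  a few pixels; the uncovered ends are not delineation errors).
* Ties: skeleton snapping breaks by smallest (row, col); DP argmax by
  smallest offset index; both rules are honored by the test oracles.
* Degenerate inputs error early and specifically: empty masks/skeletons,
  disconnected endpoints (named in the message), near-parallel
  triangulation rays (< 1e−6 rad), normals fully outside the image, `s < 3`
  mesh subdivisions, empty meshes (no file written).

## Known limitations

Single vessel segment per run (trees are reconstructed segment by segment
and exported as separate tubes); circular cross-sections; no table-motion
estimation (a translation vector is accepted but not solved for); epipolar-
tangent stretches rely on the monotone matching to interpolate through;
radius accuracy on real images is limited by the unmodelled system MTF.
The printed-table discrepancy values of the originating study depend on its
patient images and radiologist annotations and are not reproducible here;
the acceptance machinery instead checks the pipeline's properties on the
phantom world at stated tolerances.
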