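# angiorecon

Patient-specific 3D coronary vessel surface models from two monoplane X-ray
angiogram projections.

Conventional coronary angiography remains the reference examination for
coronary artery disease, but it produces 2D projections: vessel curvature,
torsion and the true severity of a stenosis are hard to judge from single
views, and computational hemodynamics needs a 3D lumen surface to run on.
`angiorecon` rebuilds that surface from two projections acquired at
different gantry angles (a routine monoplane acquisition), for researchers
working on quantitative coronary analysis, 3D/2D vascular geometry, or
CFD-ready vessel models. The only manual input is a start and an end point
per vessel segment; everything downstream is automatic.

## Method

Four stages, per vessel segment and per view:

1. **Vessel enhancement and skeletonization.** Multiscale Hessian-eigenvalue
   vesselness (blobness ratio `R_b = λ₁/λ₂`, structureness
   `S = √(λ₁²+λ₂²)`, dark-on-bright polarity), hysteresis thresholding,
   topology-preserving thinning, and bifurcation/end-point detection by the
   crossing number of each skeleton pixel's 8-neighbourhood.
2. **Centreline.** User points are snapped to the skeleton, the
   √2-weighted shortest skeleton path between them is extracted, and a
   cubic smoothing spline — excluding pixels near bifurcations, which
   thinning places off the vessel axis — yields a sub-pixel centreline,
   refined onto the vesselness ridge and resampled at 1 px arc-length steps.
3. **Wall delineation by dynamic programming.** On each side of the
   centreline a grid of K = 10 candidate nodes per normal is built, with
   Gaussian-derivative features: gradient magnitude `e_gm`, second
   directional derivative magnitude `e_hm`, edge orientation `e_gd`.
   The wall is the path maximizing

       C = Σᵢ e_m(oᵢ) − β Σᵢ |e_gm(oᵢ)/(e_hm(oᵢ)+ε) − e_gm(oᵢ₋₁)/(e_hm(oᵢ₋₁)+ε)|
                      − (1−β) Σᵢ (e_gd(oᵢ) − e_gd(oᵢ₋₁))²

   solved exactly by the standard stage recursion with endpoints pinned to
   the max-gradient nodes; β = 0.75 by default. Wall nodes are refined
   sub-pixel and corrected for the systematic inward bias of
   gradient-maximum edges on cylindrical density profiles.
4. **3D reconstruction and meshing.** The two 2D centrelines are matched
   with the epipolar constraint (monotone matching, bifurcation anchors) and
   triangulated; foreshortening is removed iteratively by resampling the 3D
   curve to uniform arc length and re-matching, until the update falls below
   1e−3 mm. Per-point radii come from back-projecting the four wall points
   to the centreline depth and averaging the distances (circular
   cross-section assumption). Frenet frames (T, N, B), curvature κ and
   torsion τ are estimated by central differences, and the tube surface
   `X + r(N cos θ + B sin θ)` is triangulated and exported as STL or OBJ.

Validation machinery: exact Hausdorff distance between curves, and a
two-class EM (Dawid–Skene) fusion of multiple annotators' edge labels with
per-annotator confusion matrices, error rates and ROC points.

A built-in phantom generator (`make_phantom()`, `render_views()`) renders
parametric vessels — straight, arc, helix, branched, with analytic
curvature/torsion and optional stenosis — into cone-beam projection pairs
with full ground truth, so the entire pipeline is testable with no patient
data.

## Worked example

A stenosed helical vessel (radius 1.5 mm, 50 % stenosis at midpoint, helix
a = 10 mm, b = 6 mm) is rendered into two views 30° apart and reconstructed
end-to-end:

```r
library(angiorecon)

geomA <- projection_geometry(sid = 1000, pixel_size_mm = 0.4,
                             primary_deg = 0,  sod = 750, image_size = c(256, 256))
geomB <- projection_geometry(sid = 1000, pixel_size_mm = 0.4,
                             primary_deg = 30, sod = 750, image_size = c(256, 256))
phantom <- make_phantom("helix", r0_mm = 1.5,
                        stenosis = list(location = 0.5, severity = 0.5))
views <- render_views(phantom, geomA, geomB, seed = 1)
views$imageA
#> angio_image: 256 x 256 px, spacing 0.4 x 0.4 mm/px, range [0.351, 0.976]

cfg <- list(seed = 1,
            phantom = list(kind = "helix", r0_mm = 1.5,
                           stenosis = list(location = 0.5, severity = 0.5),
                           geometryA = list(sid = 1000, pixel_size_mm = 0.4,
                                            primary_deg = 0, sod = 750,
                                            image_size = c(256, 256)),
                           geometryB = list(sid = 1000, pixel_size_mm = 0.4,
                                            primary_deg = 30, sod = 750,
                                            image_size = c(256, 256))))
res <- run_pipeline(cfg, outdir = "run1")
res$model
#> vessel_model_3d: 153 centreline points, length 53.3 mm, radii 0.76-1.49 mm, mesh 4896 faces
```

The run writes `vessel.stl` (the tube mesh), `vessel_centreline.csv`
(per-point x/y/z, radius, κ, τ) and `manifest.json` (every parameter of the
run). Because this config renders its own phantom, a ground-truth comparison
is included:

```r
res$validation$centreline_rms_mm   # 0.121  (mm, vs the true 3D centreline)
min(res$model$radii_mm)            # 0.76   (mm; true apex radius 0.75)
mean(res$model$kappa[16:138])      # 0.0721 (1/mm; closed form a/(a²+b²) = 0.0735)
```

The reconstructed minimum radius localizes the 50 % stenosis to within
about 1 %, and the centreline is recovered to ~0.12 mm RMS — a third of a
detector pixel at this magnification.

Real images are supplied per view as PNG/PGM/CSV plus a JSON geometry block
(SID, pixel size, gantry angles, source-to-isocenter distance) and
start/end points; see `?read_config`.

## Command line

```sh
Rscript inst/cli/angiorecon.R run     --config cfg.json --out results/
Rscript inst/cli/angiorecon.R phantom --config cfg.json --out phantom/
```

Subcommands: `run`, `phantom`, `enhance`, `centreline`, `walls`, `recon`,
`mesh`, `validate`. All take `--config` (JSON), `--out`, `--seed`,
`--log-level`.

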