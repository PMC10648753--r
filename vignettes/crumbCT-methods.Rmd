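---
title: "Quantifying porous crumb microstructure from micro-CT volumes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying porous crumb microstructure from micro-CT volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Steamed bread and other baked foods age during storage: moisture migrates
from the center through the crumb to the skin, the cell walls contract, and
small gas cells merge into large ones. These structural changes track the
quality indexes a producer actually cares about — hardness, flexibility,
moisture content — so a non-destructive readout of the internal pore
structure is a practical proxy for freshness. X-ray computed tomography
provides that readout: each voxel's grayscale value (GSV) is proportional to
local X-ray attenuation, hence local density, so the solid crumb matrix and
the air-filled pores occupy separable grayscale bands.

crumbCT implements the full analysis pipeline for such volumes:
segmentation of the solid matrix, recovery of the interior pore phase,
pore separation and per-pore morphometry, extraction of a pore-throat
network, local region-of-interest analysis, and the statistics linking
microstructure to physicochemical covariates across a storage series.
Because bench CT scans of food samples are rarely deposited publicly, the
package ships a seeded voxel phantom generator with exact ground truth;
every quantitative claim the package makes about itself is validated
against that ground truth in the test suite.

## Grayscale model and segmentation chain

Volumes are signed 16-bit grids (GSV in $[-32768, 32767]$), by default at
160 µm isotropic spacing. For steamed-bread crumb the matrix band is
$[-750, -250]$ and the pore/air band is $[-1250, -1000]$; both are config
defaults (`matrix_band`, `pore_band`), never literals inside the stages,
because they are sample-specific choices. Band thresholds are closed
intervals — the field convention writes bands as "−750~−250" without
endpoint semantics, so the inclusive reading is fixed and documented here.

The pore-recovery chain mirrors standard closed-cell-foam practice:

1. **Band (or balanced-histogram) threshold** marks the solid matrix.
2. **Fill holes** recovers the whole sample: background components not
   connected to any volume face are enclosed cavities, i.e. pores.
3. **Mask arithmetic** (`filled AND NOT matrix`) isolates the interior
   pore phase. This chain is necessary, not decorative: exterior air and
   pore air share the same grayscale distribution (physically both are
   air), so no threshold alone can separate them.
4. **Ball opening** (erosion then dilation with a digitized Euclidean
   ball, default radius 3 voxels) cuts the necks between coalesced pores.
   The radius convention is a *radius*, not a diameter; vendor tools are
   ambiguous here, so the config documents it explicitly.
5. **Connected-component labeling** (26-connectivity for pores, with the
   standard dual 6-connectivity for the hole-filling background flood)
   yields the separated pores; labels are assigned in raster order of each
   component's first voxel so runs are deterministic.

Porosity is defined on the *pre-opening* pore phase: 100 × pore voxels ÷
filled-sample voxels. Opening is a separation device for per-pore
statistics, not part of the porosity definition — it strictly removes
voxels and would bias porosity low. Because the published day-wise tables
do not say whether their per-pore means were taken before or after
separation, both label sets are available (`segment_volume()` returns the
pore phase and the opened mask); the pipeline's summaries use the
post-opening labels.

The balanced histogram threshold offered as the automatic alternative uses
the endpoint-removal formulation: the working range starts at the
outermost nonempty bins and the heavier side's outer bin is removed until
the range collapses; weights are taken about the real-valued range center,
with a bin sitting exactly on the center contributing half to each side.
On an exact tie both outer bins are removed (a tied two-bin range drops
the right bin). This variant is symmetric — a symmetric bimodal histogram
thresholds at its central bin — which single-sided tie rules cannot
achieve; the method family is named in the literature without fixing a
variant, so symmetry was the deciding criterion.

## Morphometry

Per-pore measurements follow the conventional parameter set:

* **Volume**: voxel count × voxel volume — exact for voxel sets.
* **Surface area**: triangulated isosurface at the 0.5 level. The scalar
  field is sampled at voxel-grid *corners* as the mean of the eight
  incident voxels and triangulated by marching tetrahedra with linear
  interpolation. This box reconstruction matters: extracting the surface
  directly between binary voxel centers inflates sphere areas by 25–30%
  (staircase bias), while the corner-averaged field is within ±3% of
  $4\pi r^2$ for digitized spheres of radius ≥ 5 voxels. Labels too thin
  to support the smoothed surface (single voxels, 1-voxel plates) fall
  back to exposed-face counting, which is exact for axis-aligned boxes;
  face counting is also available globally as a debug alternative
  (`area_method = "faces"`), with the caveat that it runs ~1.5× high for
  smooth blobs.
* **Length and width**: maximum and minimum directional (Feret) extents
  over a fixed, deterministic direction set — the three coordinate axes
  plus a 128-point Fibonacci hemisphere. Extents are computed on voxel
  *corner* points so a single voxel has nonzero extent. The set size is a
  config knob (`feret_n_directions`); 128 directions bound the
  discretization error of sphere diameters by about 2%.
* **EqDiameter**: $(6V/\pi)^{1/3}$, the diameter of the equal-volume
  sphere, used for the pore-size distribution with half-open bins
  (default edges 0, 2, 4, 6, 8, 10 mm) and a reported overflow bin.
  Half-open binning is a convention choice; printed ranges like "0–2 mm"
  do not state edge membership.
* Border-touching pores are measured and flagged, and included in
  summaries by default (`drop_border_pores` switches them off); nothing
  in the standard workflow indicates they were excluded.

Local structure is probed with cubic ROIs (default 45 voxels per side)
band-thresholded in the pore band — the fraction of in-band voxels is a
fast local porosity proxy that distinguishes the dense center from the
porous skin region without running the full chain.

## Pore-throat network

The pore phase is reduced to a centered curve skeleton by
distance-ordered homotopic thinning: voxels are deleted in increasing
order of their exact Euclidean distance to the background; a voxel is
deleted only if it is a *simple point* (its removal provably preserves
the topology of object and background, checked by the standard
two-condition neighborhood characterization), and curve endpoints are
kept. Any published topology-preserving thinning would satisfy the
contract (component preservation, centered paths); the distance ordering
was chosen because it keeps the skeleton on the distance ridge, which is
what makes throat radii meaningful.

The voxel skeleton becomes a spatial graph: voxels with a 26-neighbor
count ≠ 2 are nodes, maximal paths between nodes are segments, and
isolated cycles become one closed segment anchored at their raster-first
voxel. Each segment carries its polyline, its length (sum of inter-voxel
center distances) and the minimum and mean distance-map values along it;
the minimum is the **throat radius**, the physical bottleneck between two
pore bodies. Terminal branches shorter than `prune_factor` (default 1.0)
times the distance-map radius at their junction are pruned as thinning
artifacts — a branch that does not even escape the inscribed sphere of
its junction carries no connectivity information; pruning is logged and
can be disabled. Calibration on digitized cylinders of radius 3–8 voxels
recovers the throat radius within half a voxel; the residual error is the
digitization offset (the nearest background center of a radius-$r$
digitized disk sits at distance slightly above $r$).

The distance transform measures to the nearest background voxel *center*
(a single isolated voxel has distance one spacing), honors anisotropic
spacing exactly, and does not treat the outside of the grid as
background.

## The phantom generator

The generator is the package's stand-in for undeposited bench scans, and
its defaults are the study conditions the pipeline targets:

* an ellipsoidal bun (default semi-axes 42 × 42 × 22.3 mm ≈ 165 mL, the
  fresh-sample volume) at 160 µm voxels;
* matrix GSVs drawn at −500 ± 80 so ≥ 99.7% fall inside the matrix band,
  pore *and exterior* air at −1100 ± 40 so ≥ 99% fall inside the pore
  band (air is radiologically homogeneous, so its spread is narrower
  than the heterogeneous starch–gluten–water matrix); the two bands must
  not overlap at ±3σ, or `phantom_spec()` refuses the setting;
* spherical pores with log-normal radii (median 0.55 mm, log-sd 0.35 —
  nearly all equivalent diameters in the 0–4 mm bins, as observed for
  fresh crumb), centers uniform in the body, rejection-sampled so each
  sphere lies fully inside, overlaps allowed — overlapping spheres are
  how the generator emulates small pores merging into larger ones;
* a pore-free skin shell (default 0.4 mm) under the body surface: steamed
  bread forms a denser closed skin, and the shell is also what makes the
  interior pore phase *enclosed*, so the fill-holes chain is actually
  exercised rather than bypassed;
* an optional radial weighting of pore placement (`pore_radial_power`):
  positive values concentrate pores toward the periphery, emulating the
  tighter, moisture-rich center of real crumb for local-ROI contrasts;
  the default is uniform placement;
* an optional planar delamination slab clipped under the skin, emulating
  the skin–crumb separation gap of aged samples (the gap is shown but
  never parameterized in the literature, so position and thickness are
  free parameters);
* exact ground truth: the per-voxel phase grid, the sphere list, porosity
  as the phase-grid count ratio (it *is* the definition), and the body
  volume.

Pore placement can target a porosity: spheres are added until the running
phase-grid porosity reaches the target, which hits the requested value to
within a fraction of a percentage point.

The storage series interpolates linearly over days between trend
endpoints: porosity 23.5 → 28.8%, body volume 165.33 → 126.37 mL (applied
to phantoms as relative shrinkage, so the series scales to any phantom
size), hardness 10.1 → 40.4 N, flexibility 6.5 → 6.0 mm, median pore
radius × 1 → 1.3 (pore coarsening), and region-wise moisture ordered
center > crumb > skin throughout. Since day-wise moisture values are not
published numerically, the moisture trajectories (42→38, 40→34, 36→26%)
are free parameters chosen to respect the reported ordering and the
faster skin drying; they are set once here and not calibrated against any
output. Hardness is generated as an affine function of center moisture
plus Gaussian noise (default sd 1.5 N, a realistic texture-analyzer
repeatability); with zero noise, hardness–moisture correlation is exactly
−1 by construction, which the statistics tests exploit. For the
moisture–porosity fit, `porosity_noise_sd_for_r2()` returns the Gaussian
noise level at which the population coefficient of determination equals a
requested value, using the sample variance of the day-wise trend porosity
as signal variance; at a target of 0.94 the mean fitted $R^2$ over
replicate series sits slightly above the population value (≈ 0.95–0.96
with n = 5 days), the familiar small-sample optimism of $R^2$.

What the phantom does **not** emulate: X-ray physics (beam hardening,
ring artifacts, noise spectra), dough rheology, non-spherical pore
geometry, and spatial porosity gradients within a day's sample. Passing
the recovery suites therefore demonstrates the correctness of the
measurement chain on known geometry, not robustness to scanner
artifacts; on real scans the band thresholds remain per-sample choices.

## Statistics

Correlations are Pearson product-moment coefficients computed over the
day-wise means of a storage series (n = 5 days), mirroring how
per-storage-period averages are used in practice; per-sample tables work
through the same functions. Complete-case handling drops and reports
incomplete rows; constant columns are an error (r is undefined), never a
silent zero. Unadjusted p-values are attached but clearly labeled — with
n = 5 daily means they are descriptive at best, and the published
matrices report raw r without adjustment. The moisture–porosity
relationship is summarized by an ordinary least-squares line; for a
single regressor $R^2$ equals the squared Pearson correlation, an
identity the tests verify to 1e-10.

## Numerical and design choices

* **Indexing**: 0-based voxel coordinates and half-open `[lo, hi)` boxes
  in all user-facing geometry (crop boxes, ROI centers); voxel *i* has
  its center at $(i + 0.5) \times$ spacing. Arrays are `[x, y, z]` with x
  fastest, matching both R's column-major storage and the on-disk RAW
  order.
* **RAW byte order** is little-endian by default and recorded in the
  plain-text sidecar, since headerless vendor formats do not state it.
* **Opening at borders**: outside the grid counts as background for
  erosion, so structures touching the volume border erode there — the
  conservative choice for masks that should be surrounded by air.
* **Determinism**: every stochastic step (phantom geometry, GSV draws,
  covariate noise) derives from an integer seed; identical spec + seed
  gives bit-identical volumes, and identical config + seed gives
  byte-identical pipeline outputs, which the tests check literally.
* **Problem sizes in the validation suite**: phantom tests run at
  desk-scale geometries (bodies of roughly 1–16 mL, grids of about
  100³–200³ voxels) rather than the full 900 × 900 × 1100 scanner grid;
  porosity is scale-free and the recovery bounds hold at these sizes, so
  larger grids add runtime, not information. The statistics replicates
  (200 seeded series) run on covariate simulations without voxel data.

## Limitations

Pore separation by ball opening under-segments pores connected by necks
wider than the ball and removes pores smaller than it; at 23–29% porosity
a system-spanning pore cluster typically survives opening, which inflates
the mean per-pore volume relative to a watershed-style separation (not
implemented; out of scope). Surface areas of labels at the 1–2 voxel
scale fall back to face counting and are correspondingly coarse. The
skeleton graph describes connectivity, not transport: no permeability or
percolation modeling is attempted. DICOM ingestion and scanner-side
reconstruction are out of scope; volumes enter as RAW + sidecar or slice
stacks.
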