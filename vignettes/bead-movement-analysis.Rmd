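---
title: "Analyzing bead movement in 4D biofilm assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analyzing bead movement in 4D biofilm assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beadtrack4d)
```

## The measurement problem

Bacterial biofilms differ enormously in their material properties: matrices
rigidified by amyloid fibers (such as curli in *Enterobacteriaceae*) hold
micron-scale particles nearly immobile, while fluid matrices (as in
*Enterococcus faecalis*) let them wander tens of micrometres. A direct way to
probe this microrheology is to seed one-micrometre fluorescent beads into a
biofilm and follow them by time-lapse 3D confocal microscopy: a stack of
0.5 µm z-slices through 18–20 µm of biofilm, captured about once per minute
for ~20 frames, at 0.48 µm lateral pixel size. Two channels are acquired —
the beads, and the nucleoid-stained bacteria — and split into separate TIFF
stacks.

`beadtrack4d` implements the full analysis chain for such an assay:

1. **tracking** — feature-point detection and Brownian-motion linking of the
   bead channel into trajectories (an emulation of the Mosaic ImageJ
   plugin's detection/linking stage, with its published settings as
   defaults);
2. **ingest** — reading/writing trajectory CSVs (Mosaic or plain dialect)
   and calibrated 4D TIFF stacks;
3. **metrics** — per-trajectory life span, path length, bounding box,
   velocity mean/variance, population summaries and percent-of-total
   histograms;
4. **msd** — origin-anchored mean-squared-displacement curves, pooled
   quadratic trend fits, diffusive-motion classification, and diffusion
   coefficient estimation;
5. **density** — local cellular density from the bacterial channel,
   density-weighted velocities, and velocity-versus-density regressions at
   segment and trajectory scales;
6. **synthetic** — a seeded ground-truth scene generator so every stage is
   testable without any microscope data.

## Units, coordinates and calibration

Trajectory files and detections are kept in 0-based pixel/slice units,
exactly as trackers emit them. Every physical quantity is computed after
scaling by a `calibration(dx, dy, dz, dt)` object (µm, µm, µm, s). There is
no default calibration: forgetting it is an error, never a silent assumption
of unit voxels. Voxel centers sit at integer pixel coordinates, so position
`(x, y, z)` maps to `(x·dx, y·dy, z·dz)` µm.

## Trajectory metrics and their conventions

A **trajectory** is one bead's ordered positions across frames; a
**segment** is the displacement between two consecutive observations.
Choices a user should know:

* **Life span = number of recorded observations**, not `last − first + 1`.
  A track followed through 20 frames has life span 20 and 19 segments. When
  the linker bridges a missing frame, the bridged frame is not counted.
  Because broken tracks are never stitched (deliberately out of scope —
  identity across large jumps is not decidable), life spans under-count
  total bead–biofilm association time.
* **Segment duration = frame gap × dt**, so a bridged gap lowers the
  segment velocity rather than inflating it.
* **Velocity variance is the population (divide-by-n) variance** over the
  complete set of observed segments; a sample-variance mirror is a one-line
  change.
* **Bounding boxes are raw min/max boxes**; degenerate axes keep zero
  extent and volume 0 (observed volumes genuinely run down to ~0 µm³).
  Padding is applied only where a box serves as an integration region
  (density, below).
* **Histogram bins** are configuration-driven; defaults are 1-frame
  life-span bins and log-spaced volume bins over 1–6000 µm³, mirroring the
  ranges seen in fluid biofilms. Out-of-range values go to explicit
  under/overflow bins, never dropped.

## The origin-anchored MSD

The package deliberately reproduces the origin-anchored statistic

$$\mathrm{MSD}(m) = \frac{1}{m}\sum_{i=1}^{m}\lVert x_i - x_0\rVert^2,$$

where $x_i$ is the 3D physical position at the $i$-th observation — *not*
the sliding-window time-lag MSD of standard microrheology. It measures how
displacement from the starting point evolves over the course of each
trajectory. Useful closed forms (which double as test oracles):

* stationary bead: $\mathrm{MSD}(m) \equiv 0$;
* straight-line motion at constant step $d$:
  $\mathrm{MSD}(m) = d^2(m+1)(2m+1)/6$ — quadratic in $m$;
* 3D Brownian motion with diffusion coefficient $D$:
  $\mathbb{E}\,\mathrm{MSD}(m) = 3D\,\Delta t\,(m+1)$ — linear in $m$ with
  slope $3D\Delta t$.

A quadratic least-squares trend is fitted to all $(m, \mathrm{MSD})$ points
pooled across trajectories (unweighted raw pooling, so long trajectories
contribute more points). Motion is classified **diffusive** when the
curvature ratio $r = |a_2| m_{\max} / |a_1|$ is below 0.25 — a package
convention standing in for the visual linearity judgement usually made on
such plots; the threshold is exposed in the configuration. The linear
sub-model inverts the Brownian closed form to estimate
$\hat D = a_1 / (3\Delta t)$; a negative slope (sub-resolution movement) is
reported as-is with a warning flag. Group summaries reduce each trajectory
to its mean MSD and use a two-sided 95% t-interval across trajectories
(single-trajectory groups report the mean with the interval flagged
undefined).

The index $i$ runs over observations, so bridged gaps collapse —
consistent with the life-span convention. A time-indexed variant would be a
small extension.

## Cellular density and weighted kinematics

Local cellular density is the **raw mean voxel intensity of the
bacterial channel** inside a bounding box — a relative-intensity proxy for
cell crowding (no background subtraction or binarization by default; a
fixed floor is available). Voxel membership is by voxel-center-in-box,
half-open at the upper edge so adjacent boxes never double-count; boxes are
clipped to the stack. Axes narrower than the padding margin (default
0.5 µm ≈ the bead radius) are symmetrically inflated so a degenerate box
still integrates over a physical region. Segment densities average the
segment's two frames — the narrowest window covering the displacement.

"Weighting a velocity by its local density" admits several readings; the
package computes the normalized product
$\tilde v_i = v_i\,\rho_i/\bar\rho$ (unit-preserving, reduces exactly to
$v_i$ under uniform density) and also reports the classical weighted mean
$\sum\rho_i v_i / \sum\rho_i$, labeled, at the trajectory scale.

Velocity-versus-density scatter is fitted with both a linear model (OLS)
and an exponential $v = A e^{b\rho}$ (Levenberg–Marquardt nonlinear least
squares seeded from a log-linear fit on the $v>0$ points — a plain
log-linear fit would silently drop the zero-velocity segments that dominate
rigid biofilms). The two-scale report compares segment-scale fits against
trajectory-scale fits (mean velocity vs whole-box density). Raw slopes are
**not** comparable across scales: box-averaging compresses the density
spread, which mechanically steepens a fitted slope. The report therefore
includes a standardized effect, $|\beta_1|\cdot\mathrm{sd}(\rho)$ — the
velocity variation actually resolvable across the density spread observed
at that scale — which is the quantity that shrinks when whole-trajectory
averaging is too coarse to resolve a local effect.

## Tracking: detection and linking

Detection is a Crocker–Grier-style feature-point pipeline: normalize
intensities, Gaussian-smooth at the noise scale, subtract a boxcar
background at twice the particle radius, find local maxima within the
radius, keep the top-percentile candidates, apply non-particle
discrimination, and refine to sub-voxel positions by intensity-weighted
centroid. The discrimination score is the product of the normalized
zeroth-order moment (mean filtered intensity over the neighborhood, so
boundary-clipped spots are not penalized) and the normalized peak
intensity; genuine spots score O(1) and noise maxima orders of magnitude
lower, so the default cutoff separates them cleanly. A flat volume yields
an empty detection list.

Linking uses the Brownian-dynamics cost (squared displacement) solved
frame-by-frame as an **exact** linear assignment problem (a
Jonker–Volgenant/Hungarian solver written for this package and verified
against brute-force enumeration), with a rejection cost of
`max_displacement²` so links longer than the limit are excluded and tracks
may end or begin at any frame. Gaps up to `link_range` frames are bridged.
Defaults pin the published tracker settings: radius 3 px, cutoff 0.003,
percentile 0.12, link range 2, maximum displacement 10 px. Distances are
computed in pixel/slice index units during tracking (as the original
plugin does), with physical calibration applied downstream. Single-point
tracks are discarded with a logged count — trajectory counts legitimately
exceed bead counts, and surfacing those counts matters.

## The synthetic scene generator

`scene_config()` defaults encode the acquisition this toolchain targets:
0.48 µm pixels, 0.5 µm z-steps, 36 z-slices (~18 µm of biofilm), 20 frames
of 60 s, 50 beads (within the 40–140 working range of the assay), baseline
diffusivity $D_0 = 0.005$ µm²/s (which yields mean bead velocities
~0.02 µm/s, within the 0.01–0.15 µm/s range seen in fluid biofilms). The
lateral field defaults to 128 × 128 px (~61 µm), a sub-region of a full
512 × 512 acquisition: the bead count, geometry and timing are the
scientifically pinned quantities, and a sub-region keeps every stage —
including rendering and tracking — runnable in seconds on one CPU.

The density field is a uniform background plus seeded random 3D Gaussian
blobs (scales 3–9 µm), normalized to [0, 1] — emulating thicker and
thinner biofilm regions. Beads take Gaussian steps with per-axis variance
$2 D_{\mathrm{local}}\Delta t$, where
$D_{\mathrm{local}} = D_0 e^{-k\rho}$ couples mobility to local density
($k = 0$, the default, gives homogeneous Brownian motion). The exponential
coupling mirrors the exponential regression family fitted downstream and
gives a cleanly recoverable parameter. Boundaries are **reflecting**: real
beads can leave and re-enter focus, but reflection keeps the ground truth
fully observable — a documented simplification. Rendering draws beads as
anisotropic Gaussian spots plus seeded Gaussian noise (default peak SNR
50), and the bacteria channel is the field scaled to intensity; an
optional mode stretches the axial PSF of fast-moving beads, mimicking the
elliptical bead images caused by movement during sequential z-slice
capture. Everything is deterministic per seed.

What passing tests on synthetic scenes do **not** show: the generator has
no bacterial growth or bulk biofilm flow, no viscoelastic memory (steps
are independent), no uneven cell distribution within a box beyond the
blob scale, and no matrix-material density — so agreement on synthetic
data validates the *computation*, not the biological interpretation of any
particular biofilm.

## Validation conditions and problem sizes

The test suite and the acceptance script re-derive every quantity from
scratch at these scales, chosen to run comfortably on one CPU:

* definitional checks (life span 20 ⇒ 19 segments; minimal life span 2)
  and the MSD closed forms: exact, instantaneous;
* brute-force oracle equivalence (bounding boxes, path lengths, box
  densities, weighted moments, least-squares fits): ≥ 100 random small
  instances each, tolerances 1e-12 (geometry) to 1e-8 (fits);
* Brownian parameter recovery: 500 tracks × 20 frames at
  $D_0 = 0.005$ µm²/s, $\Delta t = 60$ s — mean per-trajectory MSD slope
  within 3 SE of $3D_0\Delta t$, pooled $\hat D$ within 15%, classified
  diffusive. The small systematic shortfall (a few percent) is the
  reflecting z-boundary: an 18 µm slab genuinely truncates vertical
  excursions at these diffusivities;
* end-to-end: the default rendered scene tracked and analyzed — detection
  recall ≥ 0.9, link identity agreement ≥ 0.9, per-scene $\hat D$ within
  25%. At ~50 beads the per-scene estimate carries ±10–15% sampling
  scatter, so this is a loose, single-scene bound, not the
  parameter-recovery surface;
* density machinery: uniform density ⇒ weighted statistics equal
  unweighted ones exactly; 20 coupled scenes ($k = 2$,
  $D_0 = 0.02$ µm²/s — a fluid-biofilm mobility, so that bead excursions
  are commensurate with the 3–9 µm density features and sub-trajectory
  heterogeneity is actually sampled) ⇒ negative exponential rate at the
  segment scale in ≥ 95% of seeds, and a larger standardized effect at the
  segment scale than at the trajectory scale in ≥ 80%.

## Worked example

```{r example, eval = FALSE}
library(beadtrack4d)

# a complete synthetic assay: ground truth + two rendered channels
cfg <- scene_config(seed = 42)
scene <- simulate_scene(cfg)

# track the bead channel and compare with ground truth
res <- track_stack(scene$stacks$bead)
rec <- tracking_recovery(ground_truth_trajectories(scene$truth),
                         res$trajectories, res$detections, linker_config())

# the full metrics bundle, with density weighting from the bacteria channel
cal <- scene_calibration(cfg)
bundle <- analyze_trajectories(res$trajectories, cal,
                               bacteria = scene$stacks$bacteria)
print(bundle)
write_results(bundle$tables, "results")
```

The same chain is available from a shell via the `inst/cli/beadtrack`
script (`simulate`, `track`, `analyze`, `plot` subcommands); every run
writes a YAML config echo next to its outputs so any result can be
re-derived exactly.

## Known limitations

* Trajectory stitching across broken tracks is deliberately absent;
  life spans and trajectory counts inherit the corresponding biases (which
  the analysis surfaces rather than hides).
* The MSD is origin-anchored by design; no viscoelastic modulus extraction
  is attempted.
* Density is relative stain intensity: it sees nucleoids, not whole cells
  or matrix material, and ignores uneven cell distribution within a box.
* The tracker is a behavioral emulation of the published feature-point
  method, not a code port; its discrimination score is one monotone
  spot-quality choice among several admissible ones.
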