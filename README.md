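# beadtrack4d

Bead-trajectory analysis for 4D (3D time-lapse) confocal assays of bacterial
biofilms.

## What it is for

Seeding one-micrometre fluorescent beads into a biofilm and imaging them
through ~18–20 µm of biofilm (0.5 µm z-slices, ~60 s frames, ~20 frames)
probes the biofilm's material properties at the microscale: rigid,
amyloid-containing matrices pin beads in place, fluid matrices let them
diffuse. `beadtrack4d` turns such two-channel image stacks (beads +
nucleoid-stained bacteria) into quantitative movement statistics:

* **tracking** — feature-point detection and Brownian linking of the bead
  channel into trajectories (functional emulation of the Mosaic ImageJ
  plugin stage, defaults pinned to its published settings: radius 3 px,
  cutoff 0.003, percentile 0.12, link range 2, max displacement 10 px),
  with the assignment step solved exactly;
* **per-trajectory metrics** — life span (frames observed), 3D path length,
  minimal bounding box and volume, velocity mean/variance, population
  summaries and percent-of-total histograms;
* **MSD analysis** — the origin-anchored statistic
  MSD(m) = (1/m) Σᵢ₌₁..m ‖xᵢ − x₀‖², pooled quadratic least-squares trend,
  diffusive/non-diffusive classification, and diffusion-coefficient
  estimation via the Brownian closed form E MSD(m) = 3DΔt(m+1);
* **density weighting** — local cellular density as mean bacterial-channel
  intensity per voxel inside (padded) bounding boxes, density-weighted
  velocities ṽᵢ = vᵢρᵢ/ρ̄, and linear + exponential velocity-versus-density
  regressions at segment and trajectory scales;
* **synthetic scenes** — a seeded generator of ground-truth Brownian beads
  (optionally with density-coupled mobility D(ρ) = D₀e^(−kρ)) inside
  heterogeneous density fields, rendered to realistic two-channel stacks,
  so the whole chain is testable without a microscope.

## Worked example

```r
library(beadtrack4d)

cfg <- scene_config(seed = 42)          # 50 beads, 128x128x36 voxels, 20 frames
scene <- simulate_scene(cfg)            # ground truth + rendered channels

res <- track_stack(scene$stacks$bead)   # detect + link
rec <- tracking_recovery(ground_truth_trajectories(scene$truth),
                         res$trajectories, res$detections, linker_config())
#> detection recall 0.974, link agreement 0.985

cal <- scene_calibration(cfg)
bundle <- analyze_trajectories(res$trajectories, cal,
                               bacteria = scene$stacks$bacteria)
print(bundle)
#> bead_analysis: 53 trajectories
#>   life spans 3-20 frames; mean velocity 0.02012 um/s
#>   motion: diffusive (curvature ratio 0.0749), D = 0.004237 um^2/s
#>   segment-scale velocity ~ density regression (n = 921)
#>   linear:      v = 0.02038 + -0.003463 rho   (RSS 0.06807)
#>   exponential: v = 0.02038 exp(-0.1715 rho)   (RSS 0.06807)
```

Reading the output: 50 simulated beads yield 53 trajectories (tracks break
and are never stitched, so trajectory counts exceed bead counts); the pooled
MSD trend is essentially linear (curvature ratio 0.07 < 0.25 ⇒ diffusive),
and the recovered diffusion coefficient 0.0042 µm²/s sits within the
single-scene sampling scatter of the true 0.005 µm²/s. Because this scene
was simulated with k = 0 (no density coupling), the fitted density
dependence is within noise of flat.

`write_results(bundle$tables, "out/")` writes every table (per-trajectory
metrics, per-segment metrics, MSD curves and fit coefficients, histograms,
density/regression tables) as full-precision CSVs. The same pipeline is
scriptable from a shell:

```sh
Rscript inst/cli/beadtrack simulate --out scene --seed 42
Rscript inst/cli/beadtrack track --stack scene/bead.tif --config run.yaml \
    --out tracked --truth scene/truth_trajectories.csv
Rscript inst/cli/beadtrack analyze --trajectories tracked/trajectories.csv \
    --config run.yaml --out results --bacteria scene/bacteria.tif
Rscript inst/cli/beadtrack plot --trajectories tracked/trajectories.csv \
    --config run.yaml --style msd --out msd.png
```

where `run.yaml` holds the calibration and tracker settings (`dx`, `dy`,
`dz`, `dt`, `n_z`, …). Every command writes a YAML config echo next to its
outputs.

Real Mosaic trajectory exports are read directly with
`read_trajectories(path, dialect = "mosaic")`; a plain lower-case dialect
(`trajectory, frame, x, y, z`, pixel units) is the interchange format.

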