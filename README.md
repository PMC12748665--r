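# velflow

Time-varying velocity-field modeling of developmental atlas trajectories
in R.

Developmental brain atlases (e.g. mouse templates spanning E11.5 to P56)
sample a continuous growth process at a few discrete ages.  `velflow` fits a
single time-parameterized velocity field v(x, t) to corresponding point sets
sampled at those stages, so that integrating the flow

    dφ/dt = v(φ(t), t)

between *any* two normalized times t0, t1 ∈ [0, 1] yields a diffeomorphic
displacement field — between sampled stages, between a stage and an
unsampled age, or between two unsampled ages.  On top of the fitted field
the package synthesizes "virtual" templates at intermediate ages by warping
the bracketing stage templates to the target time and averaging.

The pieces, each usable on its own:

- **geometry**: physical-space raster containers (`image_grid`,
  `scalar_image`, `label_image`, `displacement_field`) with trilinear /
  nearest-neighbour warping and Dice overlap, NIfTI-1 I/O via RNifti;
- **time axis**: log min–max normalization of stage ages with an optional
  late-age cap (`normalize_stage_times`), so early development gets finer
  temporal resolution;
- **point sampling**: stratified contour (boundary) and region (interior)
  point extraction from label images at configurable fractions, boundary
  points double-weighted (`extract_label_points`,
  `assemble_trajectories`);
- **optimizer**: `fit_time_varying_velocity` — iterative symmetric updates
  at M time slices, each update regularized by weighted multilevel
  B-spline scattered-data approximation (`fit_bspline_scattered`);
- **runtime**: classical RK4 integration (`integrate_velocity_field`,
  `integrate_velocity_field_at_points`), fixed-point displacement
  inversion (`invert_displacement_field`), virtual-template synthesis
  (`synthesize_template`);
- **synthetic data**: `flow_scene` — nested-ellipsoid label scenes deformed
  by analytic flows (translation, affine, radial growth, drifting affine)
  whose closed-form maps are exact oracles for every other module.

## Worked example

Fit a velocity field to a synthetic three-stage growth scene and check that
it transports first-stage points onto last-stage points:

```r
library(velflow)

scene <- flow_scene("radial_growth", n_stages = 3, seed = 42)
traj  <- generate_trajectories(scene)     # contour/region points + exact flow
traj
#> point_trajectory_set: 334 points x 3 stages ( 259 contour / 75 region )

timeline <- normalize_stage_times(exp(c(0, 0.5, 1)))   # uniform on [0,1]
vgrid <- image_grid(c(16, 16, 16), spacing = rep(23.5 / 15, 3))
fit <- fit_time_varying_velocity(traj, timeline, vgrid,
  fit_config(n_integration_points = 6, max_iterations = 40, step_size = 0.2))
fit
#> velocity_fit: 6 slices on 16x16x16 grid; 40 iterations
#>   mean mismatch: 0.5429 mm -> 7.236e-06 mm

phi <- integrate_velocity_field_at_points(fit$field, traj$coords[, 1, ], 0, 1)
median(sqrt(rowSums((phi - traj$coords[, 3, ])^2)))
#> 1.315e-05   # mm; the domain diagonal is ~40.7 mm
```

The mean point mismatch (the optimizer's objective) falls from 0.54 mm to
under 1e-5 mm in 40 iterations, and integrating the fitted field across the
full interval reproduces the ground-truth correspondence to ~1e-5 mm —
about 3e-8 of the domain diagonal.

## Command line

A thin CLI wraps the same functions (`exec/velflow`):

```sh
velflow simulate --flow radial_growth --n-stages 3 --grid-size 48 \
        --spacing 0.5 --out-dir scene
velflow fit --points scene/points.tsv --times 0,0.5,1 \
        --grid-size 16 --spacing 1.5667 --integration-points 6 \
        --step-size 0.2 --max-iters 60 --out model.nii.gz
velflow integrate --model model.nii.gz --t0 1 --t1 0 \
        --grid-like scene/labels_stage00.nii.gz --out disp.nii.gz
velflow apply --input scene/labels_stage00.nii.gz --disp disp.nii.gz \
        --label --out warped.nii.gz
velflow virtual-template --model model.nii.gz \
        --inputs t0.nii.gz:0,t1.nii.gz:1 --target-time 0.5 --out virt.nii.gz
velflow evaluate --model model.nii.gz --labels s0.nii.gz,s1.nii.gz,s2.nii.gz \
        --times 0,0.5,1 --manifest scene/manifest.json --out dice.csv
```

Stage ages (days, or E/P names with `--ages`) are accepted wherever
normalized times are; every model carries a JSON sidecar with the timeline,
fit configuration and convergence summary, sufficient to re-run the fit
identically.

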