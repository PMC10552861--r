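# dishmetry

Markerless estimation of **plate and bowl dimensions** from a single
egocentric image taken by an eyeglass-mounted wearable sensor, for use
in image-based dietary assessment. Instead of placing a fiducial marker
in the scene, the method combines three things the wearable already
measures:

* the **image** itself, with pixel points annotated on container rims;
* a **time-of-flight (ToF) distance** between the device and the eating
  surface;
* the **device pitch** ω, derived from the gravity component of a
  128 Hz accelerometer (plus the fixed 21° offset at which the camera
  is mounted).

Because every measured point lies on a known horizontal plane — the
tabletop *Z* = 0, or the raised bowl-mouth plane *Z* = *H* — the
perspective projection can be inverted point by point. With the camera
at height *h* = d_tof·tan ω above the plane and pitched down by θ, a
rim point observed at ideal image coordinates (u, v) sits at depth

    W = h / (sin θ + (v / f_c) cos θ),

then (U, V) = (W/f_c)(u, v), and the world point follows from the
inverse rigid transform. Radial lens distortion
(u, v) = (ū, v̄)[1 + K_c(ū² + v̄²)] is removed before backprojection.
Bowl heights use the projected wall extent *H′* on the tabletop:
*H* = tan(ω)·*H′*. Diameters come from a Pratt circle fit of the
backprojected rim; box sides from rotating-caliper extents; percent
errors are summarised per object as mean ± sample sd, the layout of the
device's published bench tables.

The package is tidyverse-native (tibbles in, tibbles out, `tidy()` /
`glance()` / `autoplot()` methods) and ships a **synthetic scene
renderer** that forward-projects containers of known size into pixel
annotations and sensor logs — every inverse stage is validated by
round-trip recovery, including the full 3-height × 3-pitch ×
8-container test bench.

## Worked example

Render a 15 cm × 6 cm cylindrical bowl seen from 350 mm at 55° pitch,
recover the device pose from the synthetic sensor log, and measure it:

```r
library(dishmetry)

cfg   <- geometry_config(bowl_plane_model = "geometric")
spec  <- container_spec("cylinder_bowl", 150, height_mm = 60)
scene <- render_scene(spec, camera_height_mm = 350, pitch_deg = 55,
                      config = cfg, seed = 42)

(pose <- pose_at(scene$log, scene$t_image))
#> <device_pose> pitch 55.00 deg, dtof 245.1 mm (roll = yaw = 0)

measure_containers(scene$annotation, pose, config = cfg) |>
  dplyr::select(type, diameter_cm, height_cm, pitch_deg, dtof_mm)
#> # A tibble: 1 × 5
#>   type  diameter_cm height_cm pitch_deg dtof_mm
#>   <chr>       <dbl>     <dbl>     <dbl>   <dbl>
#> 1 bowl         15.0      6.00      55.0    245.
```

The mouth diameter (15.0 cm) and height (6.00 cm) match the rendered
container exactly: with zero noise and the self-consistent geometry
mode the whole pipeline is a numerical identity. The same holds across
the full bench grid:

```r
bench <- run_bench(config = cfg, seed = 1)
glance(bench)
#> # A tibble: 3 × 5
#>   class               mean_pct   sd_pct max_abs_rel     n
#>   <chr>                  <dbl>    <dbl>       <dbl> <int>
#> 1 container_diameter -7.68e-11 6.80e-11    1.89e-12    27
#> 2 container_height   -2.29e-10 1.82e-10    4.41e-12    27
#> 3 plate_dimension    -9.30e-11 8.08e-11    2.01e-12    45
```

Under realistic perturbations — the bench protractor's calibration
error (−2.43° ± 1.36°) on the pitch and 2 px of annotation jitter —
plate dimensions stay within a few percent while bowl heights and
diameters disperse much more, the characteristic weakness of the
planar height relation:

```r
noise <- noise_config(pixel_sigma_px = 2, pitch_sigma_deg = 1.36,
                      pitch_bias_deg = -2.43)
run_bench(noise = noise, replicates = 10, seed = 7) |> glance()
#> # A tibble: 3 × 5
#>   class              mean_pct sd_pct max_abs_rel     n
#>   <chr>                 <dbl>  <dbl>       <dbl> <int>
#> 1 container_diameter   -20.6   17.9        0.996   269
#> 2 container_height     -12.5    9.13       0.411   269
#> 3 plate_dimension       -4.11   4.51       0.189   450
```

(The bowl rows above use the faithful `paper_sec` mouth-plane
adjustment, whose secant term adds a systematic diameter bias; see the
methods vignette, `vignettes/container-metrology.Rmd`.)

## Command line

A thin CLI wraps the same functions:

```sh
exec/dishmetry simulate --shape circular_plate --size 180 \
    --camera-height 350 --pitch 55 --out scene/ --seed 3
exec/dishmetry measure --annotation scene/annotation.json \
    --sensorlog scene/sensorlog.csv --out results.csv
exec/dishmetry bench  --out bench.csv --replicates 10 --pitch-sigma 1.36
exec/dishmetry report --results bench.csv --out report.csv
```

`measure` writes one row per annotated container (2-decimal table
convention, full precision in a `*_full.csv` sidecar); per-container
geometry failures become error rows and the run continues.

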