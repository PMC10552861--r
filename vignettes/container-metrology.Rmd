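---
title: "Single-view metrology for eating containers: model, assumptions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-view metrology for eating containers: model, assumptions and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dishmetry)
```

## The problem

Image-based dietary assessment needs a metric scale reference: a single
photograph of a meal carries no absolute size information. Instead of
placing fiducial markers in the scene, the approach implemented here
estimates the dimensions of the eating containers themselves — plates,
bowls, boxes — from one egocentric image taken by an eyeglass-mounted
wearable sensor. Two auxiliary sensor readings replace the marker: a
time-of-flight (ToF) distance between the device and the eating surface,
and the device pitch derived from a 3-axis accelerometer. Once the
container size is known it can serve as the in-image scale reference for
portion size estimation.

## The geometric model

The camera is a pinhole with focal length $f_c$ over a small sensor,
with one radial distortion coefficient $K_c$:

* world $\to$ camera: $(U, V, W)^t = R\,(X, Y, Z)^t + T$, with a
  pitch-only rotation (roll and yaw are assumed zero while eating);
* perspective division: $(\bar u, \bar v) = \frac{f_c}{W}(U, V)$ in mm
  on the image plane;
* radial distortion: $(u, v) = (\bar u, \bar v)\,[1 + K_c(\bar u^2 + \bar v^2)]$;
* pixel mapping: $x = s_{cx}\,u + c_{cx}$, $y = s_{cy}\,v + c_{cy}$
  (px/mm scale factors and principal point).

The tabletop is the plane $Z = 0$. Because every measured point lies on
a known horizontal plane, the projection is invertible: with the camera
at height $h$ above the plane and pitched down by $\theta$, the depth of
the point observed at ideal image coordinates $(u, v)$ is

$$W = \frac{h}{\sin\theta + (v/f_c)\cos\theta},$$

after which $(U, V) = \frac{W}{f_c}(u, v)$ and the world point follows
from the inverse rigid transform. The camera height comes from the ToF
reading, by default $h = d_{\mathrm{tof}}\tan\omega$ where $\omega$ is
the device pitch; the pitch comes from the gravity direction measured by
the accelerometer plus the fixed 21° offset at which the camera is
mounted in the enclosure.

### Sign convention

One convention is used everywhere, and the synthetic renderer is its
source of truth: world $Z$ up, tabletop at $Z = 0$, camera centre at
$(0, 0, h)$ looking along $+Y$ and pitched down by $\theta$; image $v$
and pixel $y$ grow downward together; visible points have $W > 0$. Under
this convention the denominator above vanishes exactly at the horizon,
which is guarded at $10^{-9}$; rays that meet the plane behind the
camera are rejected. The closed form is verified against a generic
ray–plane intersection oracle (an independent implementation used only
in tests) to below $10^{-6}$ mm on $10^4$ random poses.

### Bowls: a raised measurement plane

Bowl mouths lie on $Z = H$, not $Z = 0$, and $H$ itself must be
estimated. The annotator marks a rim point and the point of the inner
wall/base vertically beneath it. Both pixels are backprojected onto the
*tabletop* plane, where the wall appears as a stretch of length $H'$
along the world $y$-axis, and the height is recovered as

$$H = \tan(\omega)\, H'.$$

This planar relation is exact only for wall points seen along a ray
whose depression angle equals the device pitch — equivalently, points on
the image's horizontal midline through the principal point. Away from
that line it is an approximation, and this is an inherent property of
the method, consistent with bowl heights being by far its noisiest
output. The synthetic renderer therefore places the height pair at the
perimeter point that crosses the midline (the side wall of the bowl)
whenever the mouth crosses it, so that noiseless round trips are exact
and any residual is attributable to the stage under test; when the mouth
does not cross the midline the renderer falls back to the nearest
perimeter point and the relation is only approximate.

Given $H$, measurements continue on the raised plane with an adjusted
camera height. Two variants are implemented behind
`geometry_config(bowl_plane_model = ...)`:

* `"paper_sec"` (default, faithful to the printed model):
  $h' = h - H\sec\omega$;
* `"geometric"`: $h' = h - H$, which is exact for a camera $h$ above
  $Z = 0$ — the vertical offset of the plane is simply $H$.

The secant variant introduces a systematic size bias that grows with
$H\,\sec\omega / h$ (it can even drive $h' \le 0$ for a tall bowl seen
steeply from a low camera, which is reported as an error, not silently
clipped). The package reports this deviation rather than hiding it;
round-trip exactness claims are made in the `"geometric"` mode. The same
duality exists for the ToF conversion
(`height_model`): `"paper_tan"` ($h = d_{\mathrm{tof}}\tan\omega$,
default) versus `"slant_sin"` ($h = d_{\mathrm{tof}}\sin\omega$, the
reading taken as a slant range along the optical axis). The renderer
always generates $d_{\mathrm{tof}}$ consistently with the selected
model, so round trips are valid in either mode.

## Sensor stream

The accelerometer streams at 128 Hz. Pitch needs the *gravity*
component of the signal, so the stream is split at 0.1 Hz into a
gravity band and a complementary motion band; pitch is computed on the
gravity band as $\operatorname{atan2}(a_y, \sqrt{a_x^2 + a_z^2})$ with
$a_y$ the forward axis. The split is a causal order-2 Butterworth
low-pass initialised at the steady state of the first sample: a static
recording passes through bit-near-exactly, with no edge transient. (A
zero-phase forward–backward filter was rejected: at a 0.1 Hz cutoff its
edge transients span several seconds and corrupt even the middle of a
10 s window.)

Images arrive every 10 s; the pose attached to an image is the *median*
device pitch and median valid ToF distance over ±1 s around the image
timestamp. The median is robust to isolated ToF outliers and invariant
to sample order. ToF readings outside the sensor's working range
(30–2000 mm) are retained but flagged invalid and excluded from the
median.

## Measurement rules

All rim pixels are undistorted and backprojected before any metric is
taken; backprojection is what metricises the plane, so no further
perspective rectification is applied.

* **Circular containers** — with ≥ 5 rim points, diameter by the Pratt
  algebraic circle fit (stable on partial arcs, no iteration, no
  initial guess); with exactly 2 points, the endpoint distance of a
  marked diameter. The reported x/y widths are the extents of the
  *fitted circle* (equal to its diameter), not of the finite point
  sample: sample extents would depend on where along the rim the
  annotator happened to click, and would not be invariant to an
  in-plane rotation of the container.
* **Square plates and boxes** — side lengths as the two orthogonal
  extents measured in the shape's own frame, found by rotating calipers
  over the convex hull; the headline size is their mean. Again this is
  rotation invariant, and identical to plain x/y extents for an
  axis-aligned container.
* **Plates** are assumed flat and part of $Z = 0$; their thickness is
  approximated to zero, and `height_cm` is reported as 0.
* Percent errors are $100\,(\hat d - d)/d$, summarised per object group
  as mean ± **sample** (N−1) standard deviation. (The sample convention
  was chosen because it is the one the published bench tables actually
  follow; the package verifies this arithmetic against those tables.)

## Numerical choices

* Undistortion inverts the radial profile $r_d = r\,(1 + K_c r^2)$ by
  per-point Newton iteration started at $r_d$, tolerance $10^{-9}$ mm
  (three orders below the pixel pitch), maximum 50 iterations. A damped
  fixed-point scheme was tried first and abandoned: its contraction
  factor approaches 1 near the monotonicity limit of a barrel lens
  ($3|K_c| r^2 \to 1$), where it cannot reach the tolerance within the
  iteration budget, while Newton converges in under 10 iterations
  everywhere the map is invertible. For $K_c < 0$ the radial map is
  only invertible for $r < 1/\sqrt{3|K_c|}$; with $K_c = -0.1$ mm⁻²
  that limit lies inside the sensor corner radius, so invertibility
  claims are made (and tested) on the invertible region.
* Circle fitting solves Pratt's constrained algebraic minimisation as a
  4×4 generalized eigenproblem after centring and scaling the data;
  collinear or coincident points raise a degeneracy error.
* The horizon guard is $|\sin\theta + (v/f_c)\cos\theta| < 10^{-9}$.
* Default camera parameters are the device's factory values (2.4 mm
  lens, 3.67 × 2.74 mm sensor, 3378 × 2347 px distortion-corrected
  frame); $K_c$ is not part of the published calibration, so the
  default configuration uses $K_c = 0$ and tests exercise the
  distortion path with nonzero values.

## The synthetic bench

The renderer forward-projects containers of known size into pixel
annotations and static sensor logs, reproducing the physical test-bench
grid: camera heights of 200/350/500 mm × pitches of 40°/55°/70°, with
eight containers (circular plates of 180/220/260 mm, square plates of
180/230 mm, cylindrical bowls of 30×70, 70×110 and 60×150 mm
height × mouth diameter). Containers are placed with the mouth centred
on the principal axis — where a wearer naturally looks — and pushed
away from the camera by the minimal 1 mm step needed to fit the frame
with a 2% sensor margin (the 26 cm plate at the lowest, steepest pose
needs ~25 mm). Noise, when enabled, perturbs only what a sensor or
annotator actually observes: pixel coordinates, the logged pitch, the
logged distance; world geometry stays exact. All stochastic paths run
through one seeded RNG, so scenes and benches are reproducible
byte-for-byte.

What the renderer does *not* emulate: real lens blur and demosaicing,
rim occlusion by food, curved bowl walls (the model itself assumes flat
walls), human variability in clicking rim points beyond isotropic
Gaussian jitter, and head motion during capture. Passing round-trip
tests therefore validate the geometry and its implementation, not the
end-to-end accuracy on real meal images, which is additionally limited
by annotation quality and by the flat-wall and zero-thickness
assumptions.

Problem sizes used by the validation suite and the acceptance script:
$10^4$ random poses for the oracle-equivalence check, the full
8-container × 9-condition grid (zero noise) for exactness, and a
Monte-Carlo bench of 100 replicates of that grid with the bench's
protractor calibration error (−2.43° ± 1.36°) plus 2 px annotation
noise for the dispersion ordering (plate dimensions tightest, bowl
heights widest relative to their size).

## Known limitations

* Bowl-height accuracy degrades away from the image midline; real
  annotations cannot always be placed there.
* The `paper_sec` bowl-plane adjustment and the `paper_tan` ToF model
  are kept as defaults for fidelity, although the geometric/slant
  variants are the self-consistent ones; mixed-model use (render in one
  mode, measure in another) produces systematic bias by design.
* Roll and yaw are assumed zero; a tilted head violates the model.
* Plate thickness and curvature are ignored.
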