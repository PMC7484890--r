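---
title: "Beam's-eye-view contour monitoring: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Beam's-eye-view contour monitoring: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cinemv)
```

## The problem

During external-beam radiotherapy the target can move between the setup
image and the end of the delivery. A linac's electronic portal imaging
device (EPID) sits opposite the treatment beam, so continuous megavoltage
imaging (cine-MV) observes the patient in exactly the beam's-eye view, at
no extra dose. `cinemv` implements the computational chain that makes those
images interpretable at a glance: the planning ROIs (target, fiducial
markers, tolerance margins) are projected onto a virtual EPID for every
gantry angle before the first fraction, and during (or after) delivery each
frame receives a time-corrected gantry angle so that the matching contour
can be superimposed. A therapist can then see whether the imaged anatomy
stays inside its contour and interrupt the beam if it does not.

The package also contains a full synthetic acquisition simulator, because
the accuracy claims of such a chain can only be tested end to end: frames
of a ball-bearing (BB) phantom are rendered with the same rolling-shutter
physics the angle-assignment code corrects, and the closed loop
(simulate, preprocess, assign, look up, compare) is measured.

## Geometry

Room coordinates are centimeters with the isocenter at the origin: X
lateral, Y longitudinal (gun-target), Z vertical. At gantry angle
$\theta$ the source sits at $S_\theta = (SAD\sin\theta,\, SAD\cos\theta)$
in the X-Z plane. A point $O$ projects onto the plane through the
isocenter perpendicular to the beam axis by intersecting the ray
$S_\theta \to O$ with that plane; the signed lateral coordinate along the
in-plane axis $\hat u = (\cos\theta, 0, -\sin\theta)$ is the AB position
of the projection, and for a point $(O_x, 0, 0)$ it reduces to

$$u(\theta) = \frac{SAD\, O_x \cos\theta}{SAD - O_x \sin\theta}.$$

A gantry-angle error $\varepsilon$ displaces the projection by
$P(\theta+\varepsilon) - P(\theta)$; for an object 12.5 cm off-axis
(the panel-edge region) a 1-degree error reaches 2.5 mm at isocenter
scale, which is why the per-frame angle assignment below is worth the
trouble:

```{r sweep}
sw <- error_sweep(room_point(12.5, 0, 0), epsilon_deg = 1)
max(abs(sw$error_mm))
```

The detector constants are a 1024 x 1024 panel at 160 cm from the source
with a 25.6 cm field of view at the isocenter plane, hence 0.25 mm per
native pixel at isocenter scale and 0.5 mm after the 2 x 2 binning used
throughout the display chain. The source-to-axis distance is not printed
on the hardware datasheet values above; it is fixed at 100 cm, the value
forced by the 1.6 magnification implied by those constants. All projected
quantities in this package are reported at isocenter scale; multiply by
1.6 for physical panel-plane millimeters.

## ROI projection

Projection follows a deliberately discrete recipe, chosen to be exactly
reproducible rather than anti-aliased:

1. contours are voxelized on the planning-CT lattice (even-odd polygon
   fill at voxel centers; points exactly on an edge count as inside, a
   convention that is brute-force testable);
2. for each 2 x 2 detector group, the ray from the source through the
   pixel is intersected with every lattice plane that contains occupied
   voxels; each intersection is rounded to the nearest voxel index (half
   away from zero) and tested against the occupancy grid, stopping at the
   first hit. Planes are visited in order of increasing distance from the
   source so the early exit is a true first hit; the binary result is
   order-independent. Only intersections on the source-to-panel segment
   count (the geometry makes intersections behind the source or beyond
   the panel physically meaningless; this choice is documented because
   the recipe itself does not pin it down);
3. contour pixels are the map pixels with value 1 that have at least one
   zero 8-neighbor or lie on the map border; the centroid stored with
   each contour is the area centroid of the full filled projection, since
   the readout-time correction needs the projection's mass center, not
   the boundary's;
4. steps 2-3 run at 0.5-degree intervals over 360 degrees (720 overlays
   per ROI), once, offline. Lookup at display time is nearest-grid-angle,
   wrap-aware, with exact midpoints resolving toward the lower angle.

Fiducial-marker ROIs are typically expanded into tolerance margins with
`dilate_isotropic()`, a physical-distance spherical dilation that honors
anisotropic voxel spacing.

Because treatments whose primary field can spill past the imaging area
must not be monitored this way, `field_within_epid()` checks every plan
control point: the per-leaf-pair open rectangles (clipped by the jaws)
are rotated by the collimator angle and their vertices, grown by a
security margin, are tested against the 25.6 cm field of view. The margin
is configurable and defaults to 5 mm at isocenter scale; the requirement
is only that it be "small" relative to the field of view, and 5 mm keeps
a standard 24 x 24 cm validation field eligible (120 + 5 <= 128 mm).

## Frame timing: the rolling shutter

The panel is split laterally into two halves with independent readout
electronics, both read column by column from the outside in over one
integration time $T$ = 433 ms. With $TS$ the frame timestamp (readout
completion), column $c$ was read at

$$t(c) = TS - T + \alpha_c \frac{T}{511}, \qquad
\alpha_c = \begin{cases} c & c \in [0, 511] \\ 1023 - c & c \in [512, 1023].\end{cases}$$

Machine messages carry the gantry angle at about 4 Hz; angles are
interpolated linearly on the unwrapped angle (continuous across 0/360,
assuming less than 180 degrees traveled between samples — safe by a
factor of 150 at the 4.8 deg/s clinical maximum). The per-ROI assignment
is iterative because the relevant column depends on the angle: interpolate
at $TS$, read the centroid column of the overlay at that angle, evaluate
$t(c)$, re-interpolate. One refinement step is the default, which follows
the procedure as described; a fixed-point mode (up to 5 iterations,
stop at 0.05 degrees) exists behind `max_iter` but changes assignments by
well under the 0.5-degree grid step, because the column moves only a few
native pixels between iterations and a full column is worth only
0.85 ms of readout time.

The binned centroid column is converted to a native column as
`round(2 * col_binned)`; the readout-time model is defined on native
columns, and the half-pixel of the binning is absorbed by the rounding.

## Image pipeline

Preprocessing applies, in order: dark-frame subtraction, flood-field gain
correction, panel-position translation, median filtering, 2 x 2 binning.
Choices the recipe leaves open, and what this package does:

* **Gain correction** divides by (flood - dark) at the nearest available
  dose rate and rescales to preserve the mean. Nonpositive gain pixels
  (dead detector elements) are replaced by the local 3 x 3 median of the
  gain map.
* **Translation** uses the gantry-angle-indexed correction table
  (interpolated wrap-aware) rounded to integer native pixels — consistent
  with the roughly one-pixel reproducibility of the panel position that
  the table corrects in the first place.
* **Median kernel**: 3 x 3, the smallest effective size; implemented as a
  vectorized 19-operation min/max sorting network, verified against a
  brute-force sort in the tests.
* **Binning** averages (rather than sums) each 2 x 2 block to stay in the
  16-bit range.
* **Histogram equalization** zeroes pixels below 70% of the image maximum
  (adjustable) and remaps the retained pixels through their empirical CDF:
  `out = round(255 * (cdf(v) - cdf_min) / (1 - cdf_min))`, monotone and
  pinned to 0..255, with a single retained level mapping to 255. Because
  the threshold is a fraction of the maximum, the display image is
  invariant under affine rescaling of the input intensities.

## Panel-position calibration

Gravity deforms the panel mount as the gantry rotates. With the BB fixed
at the isocenter and imaged over full arcs in both directions, the
detected BB centroid traces the panel displacement; the correction table
stores, on a 1-degree grid, the offsets `(511.5, 511.5) - mean centroid`
that re-center the beam axis. Clockwise and counter-clockwise runs are
averaged jointly by default (hysteresis, if present, can be inspected
with `per_direction = TRUE`). BB detection is not specified by the
procedure itself, so the package uses: field mask at 50% of the maximum,
eroded by 3 pixels to discard partial-intensity aperture-edge pixels,
dark pixels below the midpoint of field median and field minimum,
largest 8-connected blob, attenuation-weighted sub-pixel centroid.

## The simulator: what it emulates and what it does not

`sim_config()` renders each native column with the scene geometry at that
column's own readout time, from the true trajectory — the exact mechanism
the timing model corrects, implemented independently of the correction
code so the end-to-end test is a genuine closed loop. It models: the BB
as an attenuated disk (40% contrast, soft one-pixel edge) with the
projection magnification of its room position; static field borders;
sinusoidal panel sag as a whole-frame translation; a multiplicative gain
field; Gaussian intensity noise; and machine messages whose angles are
exact but whose timestamps carry uniform jitter (default +/-50 ms), since
the real stream's receive-time stamping is the dominant timing
uncertainty. The uniform jitter law and its half-width are modeling
choices, surfaced in the config; the true distribution of the hardware's
message timing error is unknown.

It does **not** model dose deposition, scatter, detector lag/ghosting,
MLC leaf motion within a frame, or anatomical background — so passing
end-to-end tests demonstrate geometric and timing correctness of the
chain, not clinical detectability of low-contrast anatomy.

Default study conditions mirror the validation layout: BB offset 10 cm
laterally and 5 cm longitudinally from the plan isocenter (the
configuration most sensitive to gantry-angle error), 24 x 24 cm field,
clockwise 360-degree arcs at 1.5 and 4.8 deg/s (the clinical minimum and
maximum gantry speeds), 8 mm BB contoured on a 0.5 x 0.5 x 1.0 mm CT
lattice.

## Accuracy evaluation and its sign convention

Per frame, the signed AB difference (contour centroid minus detected BB
centroid, 0.5 mm per binned pixel) changes sign as the object's image
reverses direction across the arc. To make the mean meaningful, the AB
polarity is inverted for positive gantry angles — positive meaning the
signed angle lies in (0, 180), i.e. the source on the +X side — so that a
negative adjusted error always means the contour lags the BB. The mean of
the adjusted errors then isolates a systematic encoder or timing offset,
and the standard deviation captures the random message-timing error,
which grows with gantry speed.

## Numerical choices and degenerate inputs

* Angles are reduced to [0, 360) before any table lookup; signed angles
  in (-180, 180] are accepted everywhere.
* At exactly theta = +/-90 degrees the auxiliary projection angle beta
  takes the positive branch (closed interval).
* Voxel-index rounding is half away from zero; ties are measure-zero but
  fixed for determinism.
* Empty overlays (ROI not intersected at some angle) make the angle
  assignment fall back to the frame-timestamp angle, flagged.
* Frames in which no BB blob is found are excluded from accuracy
  summaries and counted, never silently zeroed.
* All randomness in the simulator derives from one integer seed; repeated
  runs are bit-identical.

## Problem sizes used in the shipped tests

The test suite and the acceptance script run entirely from synthetic
data generated at run time. Sizes were chosen to exercise every code
path at full raster resolution while keeping a laptop-class run
comfortable: the projection set is computed at all 720 grid angles; the
panel-centering check uses a 72-frame ideal arc; the jittered end-to-end
validation uses full 1024 x 1024 frames with the frame sequence thinned
(every 2nd to 8th frame depending on context, 69-277 frames per arc) —
thinning reduces only the number of statistical samples, not the
geometry, timing model or raster scale of each frame. Observed results
under these conditions: adjusted-mean AB errors of a few hundredths of a
millimeter and a standard deviation near 0.2 mm at 4.8 deg/s, inside the
documented bounds (|mu| <= 0.1 mm, sigma <= 0.6 mm); the residual spread
is dominated by the 0.5-degree grid quantization of the overlay lookup
plus the jitter-induced interpolation error.

## Known limitations

* Only identity (head-first supine, axial) CT orientation is supported;
  non-axial contours are rejected rather than resampled.
* The DICOM layer is a minimal explicit-VR little-endian codec for the
  three object types the chain needs (CT series, RTSTRUCT, RTPLAN); it
  reads tolerant of extra tags but writes only the minimal module set.
* Couch and collimator rotations do not enter the projection geometry
  (collimator enters only the field-eligibility check); the projection
  rotates with the gantry angle alone.
* Contours are binary per-pixel sets; no sub-pixel or anti-aliased
  rendering.
* The live acquisition loop (frame grabber, machine message client, GUI)
  is out of scope; the package provides the computation and an offline
  replay.
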