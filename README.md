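# cinemv

Intrafraction motion monitoring with the treatment beam itself. On a linac
with a flat-panel electronic portal imaging device (EPID), continuous
megavoltage imaging (cine-MV) sees the patient in the beam's-eye view at
no additional dose. `cinemv` implements the computation that turns those
frames into an interpretable display: planning regions of interest
(targets, fiducial markers, tolerance margins) from DICOM RTSTRUCT files
are projected onto a virtual EPID for every gantry angle ahead of the
first fraction, each acquired frame receives a time-corrected gantry
angle, and the matching precomputed contour is superimposed so a
therapist can see at once whether the anatomy has moved.

It is intended for medical physicists evaluating or commissioning
contour-overlay monitoring on Elekta-style geometry (source-axis distance
100 cm, panel at 160 cm, 1024 x 1024 pixels, 25.6 cm field of view at
isocenter), and for methodologists studying the timing behavior of
rolling-shutter portal imagers.

## What is computed

**Projection.** At gantry angle θ the source sits at
S(θ) = (SAD sin θ, SAD cos θ) in the lateral-vertical plane. A room point
O projects to the isocenter plane along the source ray; for O = (Ox, 0, 0)
the lateral (AB) coordinate is

    u(θ) = SAD · Ox · cos θ / (SAD − Ox · sin θ).

ROIs are voxelized on the planning-CT lattice and ray-cast onto the panel
at 2 x 2 detector-group resolution with a first-hit plane-crossing test,
at 0.5° intervals over 360° (720 overlays per ROI, computed once,
offline). A gantry-angle error ε displaces a projection by
P(θ+ε) − P(θ); for an object near the lateral panel edge (12.5 cm
off-axis) a 1° error costs up to 2.5 mm, which motivates the next part.

**Timing.** The panel is read column by column, outside-in, in two
synchronized halves over the 433 ms integration time: column c of a frame
stamped TS was actually read at

    t(c) = TS − 0.433 + α_c · 0.433/511,   α_c = c (c ≤ 511), 1023 − c (c ≥ 512).

Machine messages carry the gantry angle at ~4 Hz; the angle assigned to a
frame for a given ROI is interpolated at the readout time of the ROI's
projection centroid column, found iteratively.

**Pipeline and validation.** Frames are dark/flood corrected, re-centered
with a gantry-angle-indexed panel-sag table built from ball-bearing (BB)
arc acquisitions, median filtered, 2 x 2 binned, and contrast-enhanced by
histogram equalization above 70% of the image maximum. A full synthetic
acquisition simulator (rolling-shutter BB frames, jittered messages,
sag/gain/noise) closes the loop: contour-vs-BB errors are evaluated per
frame with a polarity convention that makes the mean error a direct probe
of systematic timing offsets.

## Worked example

End-to-end geometric validation on the standard layout: an 8 mm BB offset
10 cm laterally and 5 cm longitudinally from the isocenter — the
configuration most sensitive to gantry-angle error — imaged over a
clockwise 360° arc at the clinical maximum speed of 4.8°/s, with ±50 ms
uniform jitter on the machine-message timestamps.

```r
library(cinemv)

geom <- linac_geometry()
geom
#> <linac_geometry> SAD 100 cm, SDD 160 cm (mag 1.6), 1024x1024 panel,
#>   FOV 25.6 cm at iso (0.25 mm/px native, 0.5 mm binned),
#>   integration 0.433 s, projection step 0.5 deg

# sensitivity of the projection to a 1-degree gantry-angle error
sw <- error_sweep(room_point(12.5, 0, 0), epsilon_deg = 1)
max(abs(sw$error_mm))
#> 2.49 mm

# simulate the arc, write the matching DICOM fixtures, precompute contours
cfg  <- sim_preset("bb-validation", speed_dps = 4.8, seed = 42)
arc  <- simulate_arc(cfg, frame_stride = 4)
fx   <- sim_fixture_suite(cfg, tempfile("fixture"))
ct   <- read_ct_geometry(fx$ct)
rois <- read_structure_set(fx$rtstruct, ct)
plan <- read_plan(fx$rtplan)
set  <- precompute_set(rois, plan, ct, geom)

evaluate_accuracy(arc, set, sim_calibration(cfg))
#> <accuracy_report> 44 frames (0 excluded)
#>   AB: mu +0.026 mm, sigma 0.199 mm (polarity-adjusted)
#>   GT: mu -0.014 mm, sigma 0.074 mm
```

The polarity-adjusted mean AB error of +0.026 mm says the chain has
essentially no systematic timing offset (a constant encoder or clock bias
would shift it); the 0.199 mm standard deviation is the random error from
message-timestamp jitter plus the 0.5° quantization of the precomputed
overlay grid, and the sub-0.1 mm longitudinal (GT) figures confirm that
gantry-angle error barely couples into that axis.

A command-line wrapper around the same functions is installed at
`inst/cli/cinemv.R` (`precompute`, `check-field`, `simulate`, `calibrate`,
`replay`, `validate`); see `?cinemv_main`.

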