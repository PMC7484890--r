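Package: cinemv
Title: Beam's-Eye-View Contour Monitoring for Cine-MV Portal Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for intrafraction motion monitoring with the megavoltage
    treatment beam on a linac equipped with a flat-panel electronic portal
    imaging device (EPID). Planning regions of interest from DICOM RTSTRUCT
    files are voxelized on the planning-CT lattice, ray-cast onto a virtual
    EPID at 0.5 degree gantry-angle intervals, and stored as boundary-pixel
    contours. Cine-MV frames are dark/gain corrected, re-centred with a
    gantry-angle-indexed panel-position table, median filtered, binned and
    contrast enhanced by thresholded histogram equalization. Each frame is
    assigned a time-corrected gantry angle through a rolling-shutter
    column-readout model combined with interpolation of the machine message
    stream, and the matching precomputed contour is superimposed. A full
    synthetic acquisition simulator (ball-bearing phantom frames with
    per-column rolling-shutter geometry, jittered machine messages, panel
    sag, gain fields and noise) supports end-to-end geometric validation of
    the whole chain.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
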