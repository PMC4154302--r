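Package: cloudgait
Title: Markerless Motion-Capture Digitising and Kinematic Analysis of
    Photogrammetric Point-Cloud Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for measuring animal locomotion from per-frame dense 3D
    point clouds produced by multi-camera photogrammetric reconstruction.
    Reads PLY point clouds (including the PMVS dialect) and Bundler
    'bundle.out' camera files; fits points, lines and planes to declarative
    point selections; orients clouds into a gravity-aligned gait frame and
    calibrates scale from a known in-scene length or from tape-measured
    camera separations; places virtual markers on presumed joint centres and
    batch-digitises cloud sequences with explicit missing-frame handling;
    derives velocities by smoothing-spline differentiation, zero-phase
    Butterworth filtering and finite differences; computes projected segment
    angles, travel-direction realignment, and stance/swing gait events with
    stride summaries. Includes a ground-truthed synthetic locomotion scene
    generator (treadmill and overground walkers, climbing flyer) for
    end-to-end validation, and a scriptable pipeline with reproducible run
    manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
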