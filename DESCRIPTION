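Package: trajpacket
Title: Shareable Visualisation Packets for Large-Scale Trajectory Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for importing, enriching and packaging large-scale
    biological 3D(+t) trajectory data (cell tracks, animal paths, streamlines)
    for browser-based sharing. Reads generic CSV tables, biotracks
    frictionless data packages, TGMM per-timepoint XML and SVF linkage
    tables into a common vertex/segment model; derives per-vertex attributes
    (timestamps, turning angles, movement orientation); computes alternative
    geometry states via kernel-based edge bundling, oblique planar
    projection and spherical Mercator projection with adaptive axes;
    evaluates focus+context selections from attribute-range filters, cutting
    planes and refinable spatial regions; schedules timed presentation tours
    with a compact URL-safe serialization; renders deterministic raster
    previews on the CPU; and assembles everything into a self-contained,
    deterministic visualisation packet folder.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    xml2,
    grDevices,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
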