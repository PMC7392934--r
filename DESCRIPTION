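Package: ossimetrics
Title: Voxel-Based Inertial Properties and Transformer Acoustics of
    Middle-Ear Ossicles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes rigid-body mass properties (volume, mass, centre of
    mass, inertia tensor, principal moments and axes) of middle-ear
    ossicles from segmented micro-CT voxel masks, landmark- and mesh-based
    morphometry (characteristic lengths, articular-surface and footplate
    areas, anatomical frames, the hinge-like rotational axis and the
    ossicular lever arms), and the downstream ideal-transformer model of
    middle-ear impedance matching (area ratio, pressure gain,
    tympanic-membrane impedance, transmitted-energy fraction).  Includes a
    synthetic phantom generator with closed-form ground truth so the whole
    chain is testable without scan data, and a pipeline layer that
    aggregates per-specimen records into species comparison tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
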