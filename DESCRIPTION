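Package: facesym
Title: Facial Asymmetry Indices for Automated Facial Nerve Palsy Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes bilateral asymmetry indices of the forehead and mouth
    regions from 49-point facial landmark trajectories recorded while a
    subject rests, raises the eyebrows and smiles, and classifies facial
    nerve palsy against normal controls with linear discriminant analysis or
    a linear-kernel support vector machine under leave-one-out
    cross-validation. Both local-points-based (landmark centroid) and
    axis-based (inter-canthal reference line) geometries are provided, along
    with a synthetic cohort generator for end-to-end validation and a 3D
    head-orientation simulation that maps how roll, pitch and yaw affect the
    indices under orthographic projection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    jsonlite,
    graphics,
    stats,
    utils
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
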