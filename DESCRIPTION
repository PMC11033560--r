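Package: pcmfiber
Title: Fiber Counting in Phase-Contrast Micrographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Toolkit for automated fiber counting in phase-contrast
    microscope (PCM) images of airborne-dust filter samples. Provides
    post-processing of semantic and instance segmentation outputs into
    fiber pixel groups, rotated minimum-bounding-rectangle morphometry
    under two measurement conventions, the regulatory counting criteria
    (length >= 5 um, width < 3 um, aspect ratio >= 3), IoU-matched
    evaluation against expert LabelMe polygon annotations, conversion of
    per-field counts to airborne fiber concentration, and a synthetic
    PCM field-of-view simulator with pixel-exact ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    igraph,
    EBImage,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
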