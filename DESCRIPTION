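Package: prmixr
Title: Primary Region Mix Augmentation for Dense Brain Section Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Offline data augmentation for dense whole-brain segmentation of
    multi-channel fluorescence microscopy sections. Implements primary region
    mix (PRMix): hard-sample mining by mask-overlap similarity, anatomically
    grouped primary-region swapping between labeled images, and greedy
    overlap-aware affine placement of transplanted regions. Ships comparator
    mixers (MixUp, CutMix, CarveMix-style), a synthetic labeled-phantom
    generator, per-class segmentation metrics, and a reproducible offline
    augmentation pipeline with JSON manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
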