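Package: modOrigami
Title: Modular Polymorphic Design and Mechanics of Scaffolded DNA Origami Hinges
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for module-based polymorphic design of scaffolded DNA
    origami bundles. Builds a seam-partitioned 12-helix honeycomb reference
    design, derives hinge and adjuster variants by minimal staple
    replacement and accounts for replaced staples, predicts included angles
    and hinge torsional stiffness with a torsional-spring plus worm-like
    chain strain-energy model, and measures included angles and structural
    yield on (synthetic) AFM-like height maps.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    jsonlite,
    yaml,
    tiff,
    Biostrings,
    IRanges,
    EBImage
Suggests: testthat (>= 3.0.0), withr, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Software, StructuralPrediction
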