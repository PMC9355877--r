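Package: frcmech
Title: Quantification of Fibroblastic Reticular Cell Network Mechanics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Image- and trace-based quantification of lymph-node fibroblastic
    reticular cell (FRC) network mechanics: gap analysis of the stromal network
    by greedy maximal-circle packing on binary masks, T cell packing density by
    watershed nuclei segmentation, laser-ablation recoil kinetics and initial
    recoil velocity, optical-trap equipartition calibration and membrane-tether
    force, osmotic-swelling diameter-ratio kinetics, contractile-fiber scoring
    against stained channels, and stiffness-dependent division counting from
    nuclei time-lapse tracks. Includes seeded synthetic-data generators with
    ground truth for every input class so each stage is verifiable without raw
    microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    tiff,
    EBImage,
    minpack.lm,
    mgcv,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
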