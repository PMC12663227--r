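Package: sporetrack
Title: Segmentation, Tracking and Fitness Analytics for Endobacteria-Bearing Fungal Spores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative pipeline for time-lapse imaging of germinating fungal
    sporangiospores that carry intracellular bacteria. Integrates per-frame
    probability maps (whole cell, contour, spore body) from any segmentation
    backend into labeled spore objects, splits touching spores along contour
    ridges, filters elongated objects by roundness, links objects across frames
    by modal spatial overlap, and derives per-spore growth metrics: projected
    area, skeleton length, roundness, summed fluorescence (bacterial load),
    germination calls, and exponential doubling times (whole-series and
    maximum-growth-window). Includes serial-passaging fitness analytics
    (germination success with Wilson intervals, fitness index, median load
    gating, retention summaries, Kruskal-Wallis/Dunn and Mann-Whitney/BH group
    comparisons, enrichment fractions) and a seeded synthetic time-lapse
    generator with ground truth for end-to-end validation without microscope
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
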