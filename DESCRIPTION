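Package: vasquant
Title: Quantitative Image Analysis of Vascular Development and
    Endothelial Monolayer Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Image-analysis pipelines for studies of the developing
    vasculature and of endothelial cell monolayers: nematic coordination
    scoring of nuclei in confluent monolayers, vascular-plexus loop
    morphometry and regularity statistics, distance-resolved marker
    gradient profiling from the sprouting front, photoconversion (FLAP)
    turnover-curve analysis yielding immobile fractions and redistribution
    half-times, and a blinded patch-based scoring workflow for junction
    morphology and turnover. Includes synthetic-data generators with known
    ground truth for every pipeline, so all analyses can be validated
    end-to-end without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    png,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
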