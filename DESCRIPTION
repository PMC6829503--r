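Package: epiquant
Title: Quantification of Epileptiform Activity and Neural Circuit
    Composition in Larval Zebrafish
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection and quantification pipeline for zebrafish epilepsy
    models: calcium-transient event detection on drift-corrected
    delta-F/F0 traces, ictal-like event detection on local field
    potential recordings, cross-modal event matching and
    duration-duration correlation, synaptic puncta segmentation with a
    physical-area filter and density estimation, 3-D blob-based cell
    counting, classification and colocalization in anisotropic confocal
    volumes, movement quantification from frame sequences, and
    normality-gated two-group statistics. Includes synthetic-data
    generators with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    signal,
    igraph,
    EBImage,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
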