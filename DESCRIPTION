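Package: wormpcd
Title: Calcium Traces, Behavior Metrics and Mosaic Lineage Models for
    C. elegans Cell-Death Mutants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing how "undead" neurons in Caenorhabditis
    elegans programmed-cell-death mutants integrate into circuits and alter
    behavior. Implements sorted-voxel calcium-trace extraction from
    two-channel volumetric movies with a three-term multiplicative model
    (signal x double-exponential photobleaching x shared motion artifact,
    plus a constant noise floor), reversal-triggered averaging and pairwise
    trace correlation, reversal and dorsal-ventral turning-angle metrics
    from centroid tracks, and a lineage-based extrachromosomal-array
    transmission model with closed-form retention predictions and Monte
    Carlo validation. A synthetic-data module generates movies, event
    trains, worm tracks and mosaic populations with known ground truth for
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
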