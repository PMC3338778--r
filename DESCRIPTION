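Package: motanlage
Title: Motility, Adhesion and Expression Analytics for Migratory Muscle
    Progenitors
Version: 0.1.0
Authors@R:
    person("Analysis", "Pipeline", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitative pipeline for characterising the migratory
    behaviour of limb myogenic progenitor cells from time-lapse tracking
    data, together with the companion assays reported alongside such
    imaging: focal-adhesion puncta quantification with leading/trailing
    edge partitioning, flow-population percentages and DNA-content
    cell-cycle fractions, signed fold-change tables for candidate
    cytoskeletal genes, and the group-comparison statistics (mean +/- SEM,
    pooled t-tests, Dunnett many-to-one by Monte Carlo) these assays use.
    A synthetic-data module simulates every input - persistent
    run-and-pause random-walk tracks, rendered puncta scenes, replicated
    expression values and DNA-content histograms - with known ground truth
    so the whole pipeline is testable without raw microscopy or microarray
    data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
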