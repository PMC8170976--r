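Package: gutmotion
Title: Spatiotemporal Gut Motility Mapping and Enteric Biomarker Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for phenotyping gastrointestinal motility and early enteric
    molecular changes in alpha-synuclein mouse models of Parkinson's disease.
    Converts ex vivo gut-segment recordings (frame stacks or diameter traces)
    into baseline-corrected spatiotemporal motility maps; detects contraction
    cycles with a hysteresis-gated zero-crossing trigger and derives contraction
    rate, mean cycle interval and peristaltic wave velocity; implements an
    nCounter-style miRNA workflow (housekeeping normalization, expression
    filtering, differential expression, volcano tables) and downstream
    proteomics overlap and counter-regulation pairing; quantifies
    immunofluorescence images (percent-positive area, cell counts, marker
    ratios, percent reductions); and bundles the group-statistics layer
    (Shapiro-Wilk gate, Student's t, Cohen's d, two-way ANOVA). A synthetic-data
    module generates traces, rendered frame stacks, count matrices and
    fluorescence images with known ground truth so every stage is testable
    without raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    grDevices,
    graphics,
    jsonlite,
    png,
    stats,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
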