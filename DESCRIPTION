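Package: glycolect
Title: Lectin Microarray Glycopattern Analysis
Version: 0.1.0
Authors@R:
    person("Glycolect", "Developers", email = "glycolect@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for lectin-microarray glycomics: parsing of
    GenePix-style spot quantification tables, background subtraction,
    median-sum normalization to normalized fluorescence intensities (NFI),
    per-group aggregation over replicate blocks, differential glycan
    calling by fold change and Student's t-test, cross-disease-model
    comparison of call directions, glycan motif summarization,
    hierarchical-clustering heat maps, and a synthetic slide simulator
    with planted per-lectin fold changes for ground-truth validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
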