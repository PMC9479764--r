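Package: neocorr
Title: Correlative Analyses for Neoadjuvant Immunotherapy Trials
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for the correlative analyses that accompany a neoadjuvant
    immunotherapy trial in head and neck squamous cell carcinoma: pathologic
    tumor response (pTR) scoring and response classification, radiographic
    volume change, multiplex-immunofluorescence quantification (phenotype
    gating, compartment densities, H-scores, stromal immune fraction), spatial
    proximity statistics between proliferating T cells and regulatory T cells,
    ensemble somatic-variant consensus voting, 9-mer neoepitope candidate
    enumeration and selection, ELISpot response calling, and cohort-level
    association testing.  Includes a synthetic-cohort generator with planted
    effect structure so every stage of the pipeline runs and can be validated
    without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    vcfR,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
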