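Package: wntaffinity
Title: Linear Binding-Energy Models for Wnt-Frizzled CRD Affinity
    Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting Wnt binding affinities for Frizzled-type
    cysteine-rich domains (CRDs) from protein-protein and lipid-protein
    interface descriptors.  Implements linear binding-energy models over
    named interface scores, including published four-descriptor models;
    dissociation-constant thermodynamics (deltaG = RT ln Kd) and ordinal
    affinity-range classification; an exhaustive least-squares model
    search constrained so that the lipid-protein term contributes
    favourably, evaluated on a fixed training/test split; per-complex
    evaluation tables and between-model affinity-range agreement
    statistics; a synthetic descriptor and affinity generator for
    end-to-end testing; and CSV/TSV/JSON input-output with a small
    command-line interface over the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
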