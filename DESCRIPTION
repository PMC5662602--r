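Package: fbagea
Title: Gene Essentiality Screening of Constraint-Based Metabolic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Flux balance analysis (FBA) with gene-protein-reaction (GPR)
    boolean rules, and gene essentiality analysis built on it: single- and
    double-gene-deletion screens, synthetic-lethal pair enumeration,
    lethality-threshold sensitivity sweeps, and differential essentiality
    between biomass variants. Ships the model curation edits used to study
    polyamine biosynthesis in cancer metabolic models (augmenting the biomass
    reaction with putrescine, spermidine and spermine; removing the
    mis-annotated adenine-degrading activity of purine-nucleoside
    phosphorylase), a curated mini-model of the polyamine pathway, a seeded
    random-model generator with planted ground truth, and an independent
    hypergraph-reachability oracle for verifying lethality verdicts on small
    models. Models are read and written in a documented subset of the
    community COBRA JSON schema.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
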