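Package: graphddg
Title: Equivariant Graph Networks for Antibody-Antigen Binding Affinity Change Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Structure-based prediction of the change in antibody-antigen binding
    free energy (ddG) upon single-point mutation. Builds atomistic graphs from
    wild-type and mutant complex structures (non-hydrogen atoms as nodes, <4
    Angstrom interactions as edges) and feeds them through a Siamese E(n)-
    equivariant graph neural network. Includes affinity-table curation (Kd to
    delta-G conversion, SKEMPI-style filtering, duplicate resolution, reverse
    mutations), leakage-free cluster-disjoint train/validation/test splitting,
    dataset diversity and label-noise experiment machinery, simple baselines,
    and a deterministic synthetic complex generator with a FoldX-like ddG
    oracle so the full pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    pROC,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
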