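Package: shmclass
Title: Somatic Hypermutation Targeting Models and Classification of
    B-Cell Receptor Repertoires
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for stratifying clinical cohorts from adaptive immune
    receptor repertoire (AIRR-seq) data using somatic hypermutation (SHM)
    patterns. Reads AIRR Rearrangement tables of germline-aligned heavy-chain
    sequences, infers B-cell clones by single-linkage junction clustering,
    estimates per-repertoire 5-mer mutability/substitution/targeting models,
    classifies AID (WRC/GYW) and polymerase-eta (WA/TW) hotspot motifs,
    derives repertoire-level features (V and V-J gene usage, CDR3 amino-acid
    k-mers, sequence clusters, Hill diversity), and evaluates elastic-net
    logistic regression classifiers under leave-one-out cross-validation with
    per-fold t-test feature screening, shuffled-label null distributions and
    cross-cohort transfer. Includes a VDJ recombination and SHM simulator
    that generates AIRR-format cohorts with clonal expansion and
    context-dependent mutation under a configurable targeting model, so the
    whole pipeline can be exercised and validated without access to patient
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    glmnet,
    jsonlite,
    seqinr,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
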