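Package: wapdgkit
Title: Expression-Fingerprint Discrimination of KDM5C-Mutation Patients
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating a lymphoblastoid/blood gene
    expression fingerprint that discriminates carriers of pathogenic KDM5C
    mutations from controls. Implements tiered marker-gene selection from
    bead-array intensities (rank-invariant normalisation, empirical detection
    scores against negative-control probes, signed log-p differential
    expression scores), absolute QRT-PCR quantification from factor-2
    serial-dilution standard curves with triplicate quality control, one-way
    fixed-effect least-squares-mean group contrasts, and the WAPDG statistic
    (Weighted Accumulative Permutation analysis for Differentiation between
    Groups): grand-mean weighting, positive-truncated normal permutation
    draws per group, shared-value proportions per gene and combined across a
    marker panel, and a blind-sample classifier built on the combined
    permutation distributions. A seeded synthetic-data generator emulates the
    cohort structure of the underlying study design so every stage is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr
Config/testthat/edition: 3
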