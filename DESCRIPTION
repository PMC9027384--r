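Package: regpulse
Title: Transcriptional Network Response Analysis of Perturbation Time Courses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for time-resolved transcriptome responses to a
    sudden perturbation (e.g. a glucose pulse applied to a carbon-limited
    chemostat culture). Differentially expressed genes are clustered with a
    must-link constrained k-means algorithm that exploits transcription
    factor / sigma factor (TF/SF) target-gene background knowledge, the
    cluster number is selected by the silhouette validity index, clusters are
    tested for over-representation of GO biological-process categories and of
    TF/SF regulator combinations with Fisher's exact test under
    Holm-Bonferroni correction, and the important regulator combinations are
    organised into a co-regulation level hierarchy whose per-timepoint
    expression shifts are scored with one-sided two-sample t-tests. A
    deterministic synthetic-data generator with planted cluster archetypes,
    regulator combinations and GO categories makes every stage testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    cluster,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
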