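Package: gangliotype
Title: Transcriptomic and Functional Classification of Geniculate
    Ganglion Neurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Two-level classification of single-cell FPKM expression
    profiles by gene-filtered Pearson-correlation UPGMA clustering with
    principal-component cross-checks, as used to separate gustatory from
    somatosensory neurons of the geniculate ganglion and to resolve the
    gustatory sub-clusters T1-T3.  Includes marker ranking and small
    marker-panel classification, scoring of GCaMP calcium-imaging
    recordings (dF/F peaks, 5-s.d. response calls, GABA inhibition of
    KCl-evoked responses, functional clustering), delta-delta-Cq relative
    quantification and immunofluorescence ROI normalization, and a
    synthetic-data generator with planted ground truth so every stage of
    the pipeline can be exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    Matrix,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
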