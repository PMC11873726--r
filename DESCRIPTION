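Package: clonexpr
Title: Multiregion Tumor Transcriptome and Microenvironment Coevolution Analysis
Version: 0.1.0
Authors@R: person("TRACERx-style", "Analyst", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to quantify how the transcriptome and the tumor
    microenvironment (TME) of multiregion-sampled tumors coevolve with the
    clonal genotype. Implements intratumour expression distance (I-TED) and
    its covariate decomposition, phylogeny-aware clonal distances and
    clone-level expression profiles, a pairwise-difference gene-level
    mixed-effects regression framework for copy-number dosage and trans
    driver effects, single-sample gene set enrichment (ssGSEA) scoring with
    antitumor/immunosuppressive TME classification and directional
    transition enrichment, immune-repertoire overlap statistics
    (Morisita-Horn, Gini), and a synthetic multiregion cohort generator
    that provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    lme4,
    stats,
    utils,
    tools
Suggests:
    ape,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
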