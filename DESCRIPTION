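Package: egrinet
Title: Environment and Gene Regulatory Influence Network Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers environment and gene regulatory influence networks (EGRINs)
    from log-ratio expression compendia in three levels: coherence-tested gene
    modules with condition assignment, sparse elastic-net regulatory programs
    with condition-specific filtering and combination, and integration of six
    evidence streams (regression influence, deletion differential expression,
    bicluster shattering, promoter binding, known-motif and de-novo motif
    scanning) into a high-confidence gene-level network. Ships a synthetic-data
    generator that emulates the statistical structure of a yeast fatty-acid
    induction study (condition-coherent modules, linear regulator programs,
    two-tailed deletion responses, promoter-proximal binding, planted motif
    sites) plus the evaluation metrics (agreement, correlation, MCC, F1, AUC)
    used to benchmark cluster-level against gene-level prediction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    Biostrings,
    stats,
    utils,
    tools,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
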