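Package: neoprio
Title: Staged Presentation Modelling and Ranking of MHC-I/MHC-II Neoantigen Candidates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Prioritizes tumour neoantigen candidates from protein-level
    somatic variants by simulating the stages of T-cell epitope
    presentation: an expression gate on TPM, a proteasomal cleavage gate,
    a TAP transport score, the wild-type/mutant MHC binding-affinity
    ratio, and a partition-function TCR-recognition probability based on
    Smith-Waterman similarity to validated epitopes. Stage scores combine
    multiplicatively into a neoantigen probability score (NPS) used to
    rank 9-mer (MHC-I) and 15-mer (MHC-II) candidate cores. Also provides
    rank-benchmark statistics (rank coverage score, ranking score,
    sensitivity/specificity/balanced accuracy, AUC), a three-predictor
    peptide-CDR3 pair score with T-cell interaction score aggregation,
    deterministic surrogate predictor backends, and a seeded synthetic
    fixture generator so the full pipeline runs offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
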