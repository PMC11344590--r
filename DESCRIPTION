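Package: remhombench
Title: Zero-Shot Remote Homology Retrieval Benchmarks on SCOP-Style Hierarchies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds hardened remote-homology retrieval tasks from SCOP/SCOPe-style
    classified protein domain databases, scores per-protein vector representations
    (for example pooled protein language model embeddings) by cosine-similarity
    ranking, and evaluates them with per-query AUROC, AUPRC, Hit@1 and Hit@10 under
    weighted (per-Superfamily or per-Fold) and unweighted aggregation. Includes
    readers for Astral-style FASTA and TSV annotation tables, preprocessing
    filters, a toy greedy sequence-identity filter, a synthetic hierarchy and
    embedding generator with controllable structural signal, a uniform-random
    representation baseline, and Spearman rank-agreement analysis between models.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
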