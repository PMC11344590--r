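#!/usr/bin/env Rscript

# Stage 2: run the retrieval evaluation.
#
# Every domain queries the rest of the database at both task levels
# (superfamily: same superfamily / different family is a hit, own family
# excluded; fold: same fold / different superfamily is a hit, own superfamily
# excluded), candidates are ranked by cosine similarity, and per-query
# AUROC / AUPRC / Hit@1 / Hit@10 are aggregated under the weighted
# (per-group-first) and unweighted schemes. Outputs land in results/eval/.

suppressMessages(library(remhombench))

data_dir <- "results/data"
stopifnot(file.exists(file.path(data_dir, "domains.tsv")))

config <- list(
  databases = list(list(label = "toy30", path = file.path(data_dir, "domains.tsv"),
                        format = "tsv", threshold = 0.3)),
  models = list(
    list(name = "plm_strong", store = file.path(data_dir, "plm_strong.tsv")),
    list(name = "plm_weak", store = file.path(data_dir, "plm_weak.tsv")),
    list(name = "plm_residue", store = file.path(data_dir, "plm_residue.tsv")),
    list(name = "random", store = file.path(data_dir, "random.tsv"))),
  levels = c("superfamily", "fold"),
  schemes = c("weighted", "unweighted"),
  output_dir = "results/eval",
  seed = 2026L)

report <- run_evaluation(config)

cat("combination status:\n")
print(report$combinations[, c("model", "level", "status")], row.names = FALSE)
cat("\nweighted aggregates:\n")
agg <- report$aggregates
w <- agg[agg$scheme == "weighted", c("model", "level", "auroc", "auprc",
                                     "hit1", "hit10", "n_queries")]
w[, 3:6] <- round(w[, 3:6], 3)
print(w, row.names = FALSE)
cat("\nSignal-bearing embeddings should dominate the random baseline at the\n")
cat("superfamily level, while fold-level retrieval stays hard: the generator\n")
cat("puts no fold-level structure into these embeddings.\n")
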